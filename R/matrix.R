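#' Protein abundance matrix with TMT channel annotations
#'
#' The unit of data in a PISA screen is a proteins-by-channels matrix of
#' soluble protein abundances (summed reporter-ion intensities) together
#' with a per-channel sample annotation: which TMT plex the channel belongs
#' to, which treatment it carries, its replicate index, and whether it is a
#' vehicle (DMSO) control. Fold changes are always computed within a plex,
#' so every plex must carry at least two vehicle channels.
#'
#' @param values numeric matrix, proteins in rows (unique rownames = protein
#'   ids), channels in columns (colnames = channel ids). Values must be
#'   non-negative; \code{NA} marks a protein not quantified in a channel.
#' @param annotations data.frame with one row per channel: \code{channel_id},
#'   \code{plex_id}, \code{treatment_id}, \code{replicate},
#'   \code{is_vehicle} (logical); optional \code{dose}, \code{mode}.
#' @return An object of class \code{"pisa_matrix"}: a list with elements
#'   \code{values} and \code{annotations} (annotations reordered to match
#'   the columns).
#' @seealso [read_abundance_matrix()], [normalize_channel_sums()]
#' @export
pisa_matrix <- function(values, annotations) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("values must have unique protein ids as rownames")
  if (is.null(colnames(values))) stop("values must have channel ids as colnames")
  if (any(values < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  req <- c("channel_id", "plex_id", "treatment_id", "replicate", "is_vehicle")
  miss <- setdiff(req, names(annotations))
  if (length(miss)) stop("annotations lack columns: ", paste(miss, collapse = ", "))
  annotations$channel_id <- as.character(annotations$channel_id)
  annotations$is_vehicle <- as.logical(annotations$is_vehicle)
  extra <- setdiff(colnames(values), annotations$channel_id)
  if (length(extra))
    stop("matrix columns absent from annotations: ", paste(extra, collapse = ", "))
  extra <- setdiff(annotations$channel_id, colnames(values))
  if (length(extra))
    stop("annotated channels absent from matrix: ", paste(extra, collapse = ", "))
  if (anyDuplicated(annotations[c("plex_id", "channel_id")]))
    stop("duplicate (plex_id, channel_id) in annotations")
  annotations <- annotations[match(colnames(values), annotations$channel_id), , drop = FALSE]
  rownames(annotations) <- NULL
  nveh <- tapply(annotations$is_vehicle, annotations$plex_id, sum)
  if (any(nveh < 2))
    stop("every plex needs >= 2 vehicle channels; offending plex: ",
         paste(names(nveh)[nveh < 2], collapse = ", "))
  structure(list(values = values, annotations = annotations), class = "pisa_matrix")
}

#' @export
print.pisa_matrix <- function(x, ...) {
  a <- x$annotations
  cat(sprintf("PISA abundance matrix: %d proteins x %d channels (%d plexes)\n",
              nrow(x$values), ncol(x$values), length(unique(a$plex_id))))
  cat(sprintf("  treatments: %d non-vehicle, vehicle channels: %d, missing values: %d\n",
              length(unique(a$treatment_id[!a$is_vehicle])), sum(a$is_vehicle),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.pisa_matrix <- function(x) dim(x$values)

delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read / write an abundance matrix and its channel annotations
#'
#' Wide matrix format: first column \code{protein_id}, remaining columns one
#' per channel; annotations in a second table keyed by \code{channel_id}.
#' Delimiter is chosen by extension (.csv = comma, otherwise tab). Missing
#' cells stay missing; no imputation happens anywhere in the pipeline.
#'
#' @param matrix_path,annotation_path file paths.
#' @return [read_abundance_matrix()]: a [pisa_matrix()].
#' @export
read_abundance_matrix <- function(matrix_path, annotation_path) {
  mat <- utils::read.table(matrix_path, header = TRUE, sep = delim_for(matrix_path),
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!ncol(mat) >= 2) stop("matrix file needs a protein_id column plus channels")
  ids <- as.character(mat[[1]])
  if (anyDuplicated(ids)) stop("duplicate protein ids in ", matrix_path)
  values <- as.matrix(mat[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  ann <- utils::read.table(annotation_path, header = TRUE, sep = delim_for(annotation_path),
                           check.names = FALSE, stringsAsFactors = FALSE)
  pisa_matrix(values, ann)
}

#' @rdname read_abundance_matrix
#' @param x a [pisa_matrix()].
#' @export
write_abundance_matrix <- function(x, matrix_path, annotation_path) {
  stopifnot(inherits(x, "pisa_matrix"))
  df <- data.frame(protein_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = delim_for(matrix_path),
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$annotations, annotation_path, sep = delim_for(annotation_path),
                     quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Equalize summed protein quantities across TMT channels
#'
#' Corrects unequal protein loading: within each plex, every channel is
#' rescaled so its summed protein quantity equals the plex-wide mean of the
#' original channel sums. Sums are computed over proteins quantified in all
#' channels of the plex (so missingness cannot bias the scale factors), but
#' the resulting per-channel factor is applied to all values including rows
#' with missing entries. Relative abundances within a channel are unchanged
#' and the operation is idempotent.
#'
#' @param x a [pisa_matrix()].
#' @return a [pisa_matrix()] with equalized channel sums.
#' @export
normalize_channel_sums <- function(x) {
  stopifnot(inherits(x, "pisa_matrix"))
  values <- x$values
  for (p in unique(x$annotations$plex_id)) {
    cols <- which(x$annotations$plex_id == p)
    block <- values[, cols, drop = FALSE]
    complete <- stats::complete.cases(block)
    if (!any(complete))
      stop("plex ", p, ": no protein quantified in all channels; cannot normalize")
    sums <- colSums(block[complete, , drop = FALSE])
    if (any(sums == 0))
      stop("plex ", p, ": all-zero channel ",
           paste(colnames(block)[sums == 0], collapse = ", "))
    values[, cols] <- sweep(block, 2, mean(sums) / sums, `*`)
  }
  pisa_matrix(values, x$annotations)
}
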