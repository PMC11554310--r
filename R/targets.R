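#' Known compound-target annotations
#'
#' One row per (compound, target protein) pair; a compound with several
#' annotated targets (e.g. dual PLK1/BRD4 inhibitors) has several rows and
#' is counted once in per-compound bookkeeping.
#'
#' @param compound_id,target_protein_id identifiers.
#' @param target_class free-text class (kinase, HDAC, ...).
#' @return data.frame of annotations.
#' @export
target_annotations <- function(compound_id, target_protein_id,
                               target_class = NA_character_) {
  if (!length(compound_id)) stop("need at least one compound-target pair")
  data.frame(compound_id = as.character(compound_id),
             target_protein_id = as.character(target_protein_id),
             target_class = rep_len(as.character(target_class), length(compound_id)),
             stringsAsFactors = FALSE)
}

#' @rdname target_annotations
#' @param path TSV/CSV with columns compound_id, target_protein_id and
#'   optionally target_class.
#' @export
read_target_annotations <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                         stringsAsFactors = FALSE)
  target_annotations(d$compound_id, d$target_protein_id,
                     if ("target_class" %in% names(d)) d$target_class else NA)
}

hits_of <- function(x) {
  if (inherits(x, "pisa")) x$hits else x
}

#' Per-compound on-target status across cell and lysate screens
#'
#' Joins hit tables to the known-target annotation. A compound's target is
#' "quantified" in a mode if the compound was assayed there and at least
#' one annotated target protein was measured for it; the compound is
#' "on-target" in a mode if any annotated target is a hit. Compounds whose
#' targets were never quantified are retained in the table but excluded
#' from rate denominators by [hit_rate_summary()].
#'
#' @param cell,lysate \code{pisa} fits or [call_hits()] tables (either may
#'   be NULL for a single-mode screen).
#' @param targets a [target_annotations()] table.
#' @return data.frame with one row per annotated compound: quantified_cell,
#'   hit_cell, quantified_lysate, hit_lysate, quantified_both, hit_combined.
#' @export
on_target_table <- function(cell = NULL, lysate = NULL, targets) {
  if (is.null(cell) && is.null(lysate)) stop("supply at least one hit table")
  compounds <- unique(targets$compound_id)
  mode_status <- function(h) {
    if (is.null(h)) return(NULL)
    h <- hits_of(h)
    key <- paste(h$treatment_id, h$protein_id, sep = "\r")
    measured <- key[!is.na(h$mean_log2fc)]
    hit <- key[h$is_hit]
    tkey <- paste(targets$compound_id, targets$target_protein_id, sep = "\r")
    q <- tapply(tkey %in% measured, targets$compound_id, any)[compounds]
    s <- tapply(tkey %in% hit, targets$compound_id, any)[compounds]
    assayed <- compounds %in% h$treatment_id
    data.frame(quantified = ifelse(assayed, as.logical(q), FALSE),
               hit = ifelse(assayed, as.logical(s), FALSE))
  }
  cs <- mode_status(cell)
  ls <- mode_status(lysate)
  out <- data.frame(compound_id = compounds, stringsAsFactors = FALSE)
  out$quantified_cell <- if (is.null(cs)) NA else cs$quantified
  out$hit_cell <- if (is.null(cs)) NA else cs$hit
  out$quantified_lysate <- if (is.null(ls)) NA else ls$quantified
  out$hit_lysate <- if (is.null(ls)) NA else ls$hit
  out$quantified_both <- if (is.null(cs) || is.null(ls)) NA else
    out$quantified_cell & out$quantified_lysate
  out$hit_combined <- mapply(function(a, b) isTRUE(a) || isTRUE(b),
                             out$hit_cell, out$hit_lysate)
  out
}

#' On-target hit rates with numerators and denominators
#'
#' When both modes are present, rates are reported over the compounds whose
#' target was quantified in both screens (the directly comparable set), as
#' counts and proportions: per-mode rates and the combined
#' hit-in-either-mode rate, which can only be at least as large as either
#' single-mode rate. With a single mode, the denominator is that mode's
#' quantified set.
#'
#' @param tab output of [on_target_table()].
#' @return list of per-mode and combined \code{hits / denominator} counts
#'   and \code{rate} proportions (rate is NA with a warning on an empty
#'   denominator).
#' @export
hit_rate_summary <- function(tab) {
  both <- !is.na(tab$quantified_both[1])
  denom_set <- if (both) tab$quantified_both else
    (if (!is.na(tab$quantified_cell[1])) tab$quantified_cell else tab$quantified_lysate)
  n <- sum(denom_set)
  rate <- function(num) {
    if (n == 0) { warning("no compound with a quantified target"); return(NA_real_) }
    num / n
  }
  out <- list(n_quantified = n)
  if (!is.na(tab$hit_cell[1])) {
    out$cell <- list(hits = sum(tab$hit_cell & denom_set), denominator = n,
                     rate = rate(sum(tab$hit_cell & denom_set)))
  }
  if (!is.na(tab$hit_lysate[1])) {
    out$lysate <- list(hits = sum(tab$hit_lysate & denom_set), denominator = n,
                       rate = rate(sum(tab$hit_lysate & denom_set)))
  }
  out$combined <- list(hits = sum(tab$hit_combined & denom_set), denominator = n,
                       rate = rate(sum(tab$hit_combined & denom_set)))
  out
}

#' Do annotated targets shift more than non-targets?
#'
#' Two-sided Wilcoxon rank-sum test comparing the absolute mean log2 fold
#' changes of annotated (compound, target) pairs against all other measured
#' (compound, protein) pairs of the screen. Exact enumeration is used below
#' a combined group size of 30, the normal approximation with continuity
#' correction above.
#'
#' @param x a \code{pisa} fit or [call_hits()] table.
#' @param targets a [target_annotations()] table.
#' @return list: statistic (rank-sum W of the target group), p.value,
#'   n_target, n_other.
#' @export
target_separation_test <- function(x, targets) {
  h <- hits_of(x)
  h <- h[!is.na(h$mean_log2fc), , drop = FALSE]
  key <- paste(h$treatment_id, h$protein_id, sep = "\r")
  tkey <- unique(paste(targets$compound_id, targets$target_protein_id, sep = "\r"))
  is_target <- key %in% tkey
  xs <- abs(h$mean_log2fc[is_target])
  ys <- abs(h$mean_log2fc[!is_target])
  if (!length(xs) || !length(ys))
    stop("both target and non-target groups must be non-empty")
  wt <- stats::wilcox.test(xs, ys, alternative = "two.sided",
                           exact = (length(xs) + length(ys)) < 30,
                           correct = TRUE)
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n_target = length(xs), n_other = length(ys))
}
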