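#' Fit the PISA hit-calling model to a screen
#'
#' Implements the empirically derived dual-cutoff framework for calling
#' compound-induced protein solubility (thermal stability) changes in a
#' multiplexed PISA screen. With only duplicate treatments, conventional
#' tests (e.g. Welch's t-test) are underpowered, so hits are defined by the
#' combination of effect size and per-protein variability:
#'
#' 1. Every treated channel is expressed as a log2 fold change against the
#'    mean of the vehicle (DMSO) channels of its plex; each vehicle channel
#'    is likewise scored against the leave-one-out mean of the other
#'    vehicle channels, giving per-channel vehicle pseudo-treatments.
#' 2. For each protein, replicate fold changes are averaged per treatment
#'    and the trimmed mean and trimmed standard deviation of these
#'    treatment-level values are computed across all treatments (vehicle
#'    pseudo-treatments included). Trimming discards promiscuous extreme
#'    responses before estimating a protein's intrinsic variability.
#' 3. Each treatment's nSD is its distance from the protein's trimmed mean
#'    in units of the trimmed SD (a robust z-score).
#' 4. A protein is a hit for a treatment iff every replicate passes
#'    \code{|log2FC| >= fc_cutoff} (default 0.2) and the treatment passes
#'    \code{|nSD| >= nsd_cutoff} (default 3.5); the direction
#'    (stabilized / destabilized) follows the sign of the mean fold change.
#'
#' @param x a [pisa_matrix()], or a numeric matrix (then \code{annotations}
#'   must be supplied).
#' @param annotations channel annotation data.frame when \code{x} is a bare
#'   matrix.
#' @param fc_cutoff minimum absolute replicate log2 fold change (inclusive).
#' @param nsd_cutoff minimum absolute nSD (inclusive).
#' @param trim fraction trimmed from each tail of a protein's
#'   treatment-level fold changes (in [0, 0.5)).
#' @param normalize equalize channel sums first (see
#'   [normalize_channel_sums()]); set \code{FALSE} for pre-normalized data.
#' @return An object of class \code{"pisa"}: list with the normalized
#'   \code{matrix}, replicate-level \code{log2fc} table, per-protein
#'   \code{stats}, the \code{hits} table (one row per protein x treatment:
#'   replicate and mean log2FC, nSD, hit flag, direction) and the
#'   \code{cutoffs} used. Methods: \code{print}, \code{summary},
#'   \code{coef} (protein x treatment mean-log2FC matrix), \code{plot}.
#' @examples
#' sim <- benchmark_screen(n_compounds = 6, n_proteins = 150, seed = 42)
#' fit <- pisa(sim$matrix)
#' fit
#' head(subset(fit$hits, is_hit))
#' @export
pisa <- function(x, annotations = NULL, fc_cutoff = 0.2, nsd_cutoff = 3.5,
                 trim = 0.1, normalize = TRUE) {
  if (!inherits(x, "pisa_matrix")) x <- pisa_matrix(x, annotations)
  check_cutoffs(fc_cutoff, nsd_cutoff, trim)
  norm <- if (normalize) normalize_channel_sums(x) else x
  fc <- compute_log2fc(norm)
  stats <- protein_variability(fc, trim = trim)
  hits <- call_hits(fc, fc_cutoff = fc_cutoff, nsd_cutoff = nsd_cutoff,
                    trim = trim, stats = stats)
  structure(list(call = match.call(), matrix = norm, log2fc = fc,
                 stats = stats, hits = hits,
                 cutoffs = list(fc_cutoff = fc_cutoff, nsd_cutoff = nsd_cutoff,
                                trim = trim)),
            class = "pisa")
}

check_cutoffs <- function(fc_cutoff, nsd_cutoff, trim) {
  if (fc_cutoff < 0 || nsd_cutoff < 0) stop("cutoffs must be non-negative")
  if (trim < 0 || trim >= 0.5)
    stop("trim must lie in [0, 0.5); larger values trim away all values")
}

#' Replicate-level log2 fold changes versus vehicle
#'
#' For every protein and every non-vehicle channel,
#' \code{log2(abundance / mean vehicle abundance)} within the channel's
#' plex (vehicle mean over the vehicle channels where the protein was
#' quantified); missing where the protein is missing in the channel or in
#' all vehicle channels of the plex. Vehicle channels themselves are scored
#' against the leave-one-out mean of the remaining vehicle channels and
#' flagged \code{is_vehicle}, providing the null pseudo-treatments used by
#' the variability estimate.
#'
#' @param x a [pisa_matrix()] (normalize first; see
#'   [normalize_channel_sums()]).
#' @return long data.frame: protein_id, channel_id, plex_id, treatment_id,
#'   replicate, is_vehicle, log2fc (full protein x channel grid, NA where
#'   unmeasured).
#' @export
compute_log2fc <- function(x) {
  stopifnot(inherits(x, "pisa_matrix"))
  V <- x$values
  ann <- x$annotations
  L <- matrix(NA_real_, nrow(V), ncol(V), dimnames = dimnames(V))
  for (p in unique(ann$plex_id)) {
    cols <- which(ann$plex_id == p)
    veh <- cols[ann$is_vehicle[cols]]
    if (!length(veh)) stop("plex ", p, " has no vehicle channels")
    B <- V[, veh, drop = FALSE]
    ok <- !is.na(B)
    vsum <- rowSums(B, na.rm = TRUE)
    vcnt <- rowSums(ok)
    vmean <- ifelse(vcnt > 0, vsum / vcnt, NA_real_)
    for (j in cols) {
      if (ann$is_vehicle[j]) {
        o <- !is.na(V[, j])
        cnt <- vcnt - o
        loo <- ifelse(cnt > 0, (vsum - ifelse(o, V[, j], 0)) / cnt, NA_real_)
        L[, j] <- log2(V[, j] / loo)
      } else {
        L[, j] <- log2(V[, j] / vmean)
      }
    }
  }
  data.frame(
    protein_id = rep(rownames(V), times = ncol(V)),
    channel_id = rep(ann$channel_id, each = nrow(V)),
    plex_id = rep(ann$plex_id, each = nrow(V)),
    treatment_id = rep(ann$treatment_id, each = nrow(V)),
    replicate = rep(ann$replicate, each = nrow(V)),
    is_vehicle = rep(ann$is_vehicle, each = nrow(V)),
    log2fc = as.vector(L),
    stringsAsFactors = FALSE
  )
}

# long fold-change table -> wide matrix + channel info
fc_wide <- function(fc) {
  proteins <- unique(fc$protein_id)
  chans <- unique(fc$channel_id)
  L <- matrix(NA_real_, length(proteins), length(chans),
              dimnames = list(proteins, chans))
  L[cbind(match(fc$protein_id, proteins), match(fc$channel_id, chans))] <- fc$log2fc
  info <- fc[!duplicated(fc$channel_id),
             c("channel_id", "plex_id", "treatment_id", "replicate", "is_vehicle")]
  info <- info[match(chans, info$channel_id), , drop = FALSE]
  rownames(info) <- NULL
  list(L = L, info = info)
}

# average replicate log2FCs per treatment unit; vehicle channels are their
# own single-replicate pseudo-treatments
unit_means <- function(L, info) {
  unit <- ifelse(info$is_vehicle, paste0("DMSO.", info$channel_id),
                 info$treatment_id)
  uf <- factor(unit, levels = unique(unit))
  X <- t(L)
  sums <- rowsum(replace(X, is.na(X), 0), uf, reorder = FALSE)
  cnts <- rowsum((!is.na(X)) + 0, uf, reorder = FALSE)
  M <- t(sums / cnts)
  M[is.nan(M)] <- NA_real_
  ui <- match(levels(uf), unit)
  list(M = M,
       unit_info = data.frame(unit_id = levels(uf),
                              treatment_id = info$treatment_id[ui],
                              plex_id = info$plex_id[ui],
                              is_vehicle = info$is_vehicle[ui],
                              stringsAsFactors = FALSE))
}

#' Trimmed mean and standard deviation of a vector
#'
#' Sorts the finite values, removes \code{floor(n * trim)} values from each
#' tail, and returns the mean and SD of the retained values. This is the
#' robust variability statistic behind the nSD score: it discounts a small
#' number of genuine (or promiscuous) responses when estimating a protein's
#' baseline spread across treatments.
#'
#' @param x numeric vector.
#' @param trim fraction trimmed per tail (in [0, 0.5)).
#' @return named vector: \code{mean}, \code{sd}, \code{n} (finite values
#'   before trimming).
#' @export
trimmed_mean_sd <- function(x, trim = 0.1) {
  if (trim < 0 || trim >= 0.5) stop("trim must lie in [0, 0.5)")
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(c(mean = NA_real_, sd = NA_real_, n = n))
  k <- floor(n * trim)
  r <- sort(x)[(k + 1):(n - k)]
  c(mean = mean(r), sd = stats::sd(r), n = n)
}

#' Per-protein variability across all treatments
#'
#' Computes, for each protein, the trimmed mean and trimmed SD of its
#' treatment-level mean log2 fold changes across all treatments of the
#' screen, vehicle pseudo-treatments included. Proteins with fewer than 3
#' treatment-level values are flagged unusable (NA statistics) and can
#' never become hits.
#'
#' @param fc replicate-level table from [compute_log2fc()].
#' @param trim fraction trimmed per tail.
#' @return data.frame: protein_id, mean_log2fc_all_treatments, trimmed_sd,
#'   n_treatments.
#' @export
protein_variability <- function(fc, trim = 0.1) {
  w <- fc_wide(fc)
  um <- unit_means(w$L, w$info)
  st <- t(apply(um$M, 1, trimmed_mean_sd, trim = trim))
  data.frame(protein_id = rownames(um$M),
             mean_log2fc_all_treatments = st[, "mean"],
             trimmed_sd = st[, "sd"],
             n_treatments = as.integer(st[, "n"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Treatment-level nSD (robust z-score) per protein
#'
#' \code{nSD = (treatment mean log2FC - protein trimmed mean) / trimmed SD}.
#' Missing when the protein's statistics are unusable or its trimmed SD is
#' zero (constant protein).
#'
#' @inheritParams protein_variability
#' @param stats optional precomputed [protein_variability()] table.
#' @return data.frame: protein_id, unit_id, treatment_id, is_vehicle,
#'   mean_log2fc, nsd (one row per protein x treatment unit).
#' @export
compute_nsd <- function(fc, stats = NULL, trim = 0.1) {
  w <- fc_wide(fc)
  um <- unit_means(w$L, w$info)
  if (is.null(stats)) stats <- protein_variability(fc, trim = trim)
  i <- match(rownames(um$M), stats$protein_id)
  centre <- stats$mean_log2fc_all_treatments[i]
  sdv <- stats$trimmed_sd[i]
  sdv[!is.na(sdv) & sdv == 0] <- NA_real_
  N <- (um$M - centre) / sdv
  nu <- ncol(um$M)
  data.frame(
    protein_id = rep(rownames(um$M), times = nu),
    unit_id = rep(um$unit_info$unit_id, each = nrow(um$M)),
    treatment_id = rep(um$unit_info$treatment_id, each = nrow(um$M)),
    is_vehicle = rep(um$unit_info$is_vehicle, each = nrow(um$M)),
    mean_log2fc = as.vector(um$M),
    nsd = as.vector(N),
    stringsAsFactors = FALSE
  )
}

#' Call hits with the dual fold-change / nSD cutoff
#'
#' A (protein, treatment) pair is a hit iff every replicate satisfies
#' \code{|log2FC| >= fc_cutoff} and the treatment satisfies
#' \code{|nSD| >= nsd_cutoff} (both cutoffs inclusive); treatments with a
#' missing replicate measurement cannot be hits. Vehicle pseudo-treatments
#' are used for the variability estimate but excluded from the hit table.
#'
#' @inheritParams compute_nsd
#' @param fc_cutoff,nsd_cutoff inclusive thresholds (defaults 0.2 and 3.5).
#' @return data.frame with one row per protein x non-vehicle treatment:
#'   protein_id, treatment_id, rep<k>_log2fc columns, mean_log2fc, nsd,
#'   is_hit, direction ("stabilized", "destabilized" or "none").
#' @export
call_hits <- function(fc, fc_cutoff = 0.2, nsd_cutoff = 3.5, trim = 0.1,
                      stats = NULL) {
  check_cutoffs(fc_cutoff, nsd_cutoff, trim)
  w <- fc_wide(fc)
  um <- unit_means(w$L, w$info)
  if (is.null(stats)) stats <- protein_variability(fc, trim = trim)
  i <- match(rownames(um$M), stats$protein_id)
  centre <- stats$mean_log2fc_all_treatments[i]
  sdv <- stats$trimmed_sd[i]
  sdv[!is.na(sdv) & sdv == 0] <- NA_real_
  N <- (um$M - centre) / sdv

  tu <- which(!um$unit_info$is_vehicle)
  treatments <- um$unit_info$unit_id[tu]
  nP <- nrow(um$M); nT <- length(treatments)
  treated <- which(!w$info$is_vehicle)
  chan_by_t <- split(treated, factor(w$info$treatment_id[treated], levels = treatments))
  nreps <- lengths(chan_by_t)
  K <- max(nreps, 1L)
  pass_fc <- matrix(TRUE, nP, nT)
  repvals <- vector("list", K)
  for (r in seq_len(K)) {
    cidx <- vapply(chan_by_t, function(ch) if (length(ch) >= r) ch[order(w$info$replicate[ch])][r] else NA_integer_, integer(1))
    Vr <- matrix(NA_real_, nP, nT)
    sel <- !is.na(cidx)
    Vr[, sel] <- w$L[, cidx[sel], drop = FALSE]
    passr <- !is.na(Vr) & abs(Vr) >= fc_cutoff
    passr[, !sel] <- TRUE    # treatment has fewer than r replicates
    pass_fc <- pass_fc & passr
    repvals[[r]] <- Vr
  }
  Mt <- um$M[, tu, drop = FALSE]
  Nt <- N[, tu, drop = FALSE]
  is_hit <- pass_fc & !is.na(Nt) & abs(Nt) >= nsd_cutoff & !is.na(Mt)
  direction <- ifelse(is_hit & Mt > 0, "stabilized",
                      ifelse(is_hit & Mt < 0, "destabilized", "none"))
  out <- data.frame(protein_id = rep(rownames(um$M), times = nT),
                    treatment_id = rep(treatments, each = nP),
                    stringsAsFactors = FALSE)
  for (r in seq_len(K)) out[[sprintf("rep%d_log2fc", r)]] <- as.vector(repvals[[r]])
  out$mean_log2fc <- as.vector(Mt)
  out$nsd <- as.vector(Nt)
  out$is_hit <- as.vector(is_hit)
  out$direction <- as.vector(direction)
  out
}

#' Per-compound hit counts
#'
#' Tally of significant solubility changes per treatment, split by
#' direction, over every treatment present in the hit table (treatments
#' with no hits count zero). The screen-level median of the totals is
#' attached as attribute \code{median_total}.
#'
#' @param hits hit table from [call_hits()] or a \code{pisa} fit.
#' @return data.frame: treatment_id, n_stabilized, n_destabilized, n_total;
#'   attribute \code{median_total}.
#' @export
per_compound_hit_counts <- function(hits) {
  if (inherits(hits, "pisa")) hits <- hits$hits
  if (!nrow(hits)) {
    out <- data.frame(treatment_id = character(), n_stabilized = integer(),
                      n_destabilized = integer(), n_total = integer())
    attr(out, "median_total") <- 0
    return(out)
  }
  tf <- factor(hits$treatment_id, levels = unique(hits$treatment_id))
  up <- tapply(hits$direction == "stabilized", tf, sum)
  dn <- tapply(hits$direction == "destabilized", tf, sum)
  out <- data.frame(treatment_id = levels(tf),
                    n_stabilized = as.integer(up),
                    n_destabilized = as.integer(dn),
                    stringsAsFactors = FALSE)
  out$n_total <- out$n_stabilized + out$n_destabilized
  attr(out, "median_total") <- if (nrow(out)) stats::median(out$n_total) else 0
  out
}

#' Vehicle-based false-hit rate (n_DMSO-Hits)
#'
#' Estimates the hit-calling false positive rate by relabelling vehicle
#' channels as pseudo-compounds: within each plex the vehicle channels are
#' partitioned into disjoint pairs, and each pair in turn is scored as a
#' duplicate pseudo-compound against the remaining vehicle channels through
#' the full pipeline (fold change, trimmed-SD nSD, dual cutoff). The rate
#' is (pseudo-compound hits) / (measured protein x pseudo-compound pairs).
#' Requires at least 4 vehicle channels per plex so that two reference
#' channels always remain.
#'
#' @inheritParams pisa
#' @return list: \code{rate}, \code{n_hits}, \code{n_measurements}, and a
#'   \code{per_plex} breakdown data.frame.
#' @export
dmso_false_hit_rate <- function(x, fc_cutoff = 0.2, nsd_cutoff = 3.5,
                                trim = 0.1, normalize = TRUE) {
  stopifnot(inherits(x, "pisa_matrix"))
  norm <- if (normalize) normalize_channel_sums(x) else x
  ann <- norm$annotations
  nveh <- tapply(ann$is_vehicle, ann$plex_id, sum)
  if (any(nveh < 4))
    stop("false-hit calibration needs >= 4 vehicle channels per plex")
  n_pairs <- max(nveh %/% 2)
  tot_hits <- 0L; tot_meas <- 0L
  plex_acc <- list()
  for (i in seq_len(n_pairs)) {
    ann2 <- ann
    for (p in unique(ann$plex_id)) {
      veh <- which(ann$plex_id == p & ann$is_vehicle)
      veh <- veh[order(ann$channel_id[veh])]
      if (2 * i > length(veh)) next
      pair <- veh[c(2 * i - 1, 2 * i)]
      ann2$treatment_id[pair] <- sprintf("pseudoDMSO%d_%s", i, p)
      ann2$is_vehicle[pair] <- FALSE
      ann2$replicate[pair] <- 1:2
    }
    fit <- pisa(pisa_matrix(norm$values, ann2), fc_cutoff = fc_cutoff,
                nsd_cutoff = nsd_cutoff, trim = trim, normalize = FALSE)
    h <- fit$hits[startsWith(fit$hits$treatment_id, "pseudoDMSO"), , drop = FALSE]
    measured <- !is.na(h$mean_log2fc)
    tot_hits <- tot_hits + sum(h$is_hit)
    tot_meas <- tot_meas + sum(measured)
    plex_of <- sub("^pseudoDMSO\\d+_", "", h$treatment_id)
    plex_acc[[i]] <- data.frame(plex_id = plex_of, hit = h$is_hit,
                                measured = measured, stringsAsFactors = FALSE)
  }
  pp <- do.call(rbind, plex_acc)
  per_plex <- do.call(rbind, lapply(split(pp, pp$plex_id), function(d)
    data.frame(plex_id = d$plex_id[1], n_hits = sum(d$hit),
               n_measurements = sum(d$measured),
               rate = sum(d$hit) / max(1L, sum(d$measured)))))
  rownames(per_plex) <- NULL
  list(rate = tot_hits / max(1L, tot_meas), n_hits = tot_hits,
       n_measurements = tot_meas, per_plex = per_plex)
}

#' @export
print.pisa <- function(x, ...) {
  a <- x$matrix$annotations
  nt <- length(unique(a$treatment_id[!a$is_vehicle]))
  cat(sprintf("PISA screen fit: %d proteins, %d treatments, %d plexes\n",
              nrow(x$matrix$values), nt, length(unique(a$plex_id))))
  cat(sprintf("  cutoffs: |log2FC| >= %g (all replicates), |nSD| >= %g, trim = %g/tail\n",
              x$cutoffs$fc_cutoff, x$cutoffs$nsd_cutoff, x$cutoffs$trim))
  cat(sprintf("  hits: %d (%d stabilized, %d destabilized)\n",
              sum(x$hits$is_hit), sum(x$hits$direction == "stabilized"),
              sum(x$hits$direction == "destabilized")))
  invisible(x)
}

#' @export
summary.pisa <- function(object, ...) {
  counts <- per_compound_hit_counts(object$hits)
  structure(list(cutoffs = object$cutoffs,
                 n_proteins = nrow(object$matrix$values),
                 n_treatments = nrow(counts),
                 n_measurements = sum(!is.na(object$hits$mean_log2fc)),
                 n_hits = sum(object$hits$is_hit),
                 n_stabilized = sum(object$hits$direction == "stabilized"),
                 n_destabilized = sum(object$hits$direction == "destabilized"),
                 median_hits_per_compound = attr(counts, "median_total"),
                 per_compound = counts),
            class = "summary.pisa")
}

#' @export
print.summary.pisa <- function(x, ...) {
  cat(sprintf("PISA screen summary: %d proteins x %d treatments (%d measured pairs)\n",
              x$n_proteins, x$n_treatments, x$n_measurements))
  cat(sprintf("  hits: %d total (%d stabilized / %d destabilized), median %g per compound\n",
              x$n_hits, x$n_stabilized, x$n_destabilized, x$median_hits_per_compound))
  top <- x$per_compound[order(-x$per_compound$n_total), ][seq_len(min(5, nrow(x$per_compound))), ]
  cat("  most active compounds:\n")
  for (k in seq_len(nrow(top)))
    cat(sprintf("    %-12s %4d hits (%d up / %d down)\n", top$treatment_id[k],
                top$n_total[k], top$n_stabilized[k], top$n_destabilized[k]))
  invisible(x)
}

#' Extract the protein x treatment mean log2 fold-change matrix
#'
#' Replicates are averaged per treatment; vehicle pseudo-treatments are
#' excluded. Rows (proteins) and columns (treatments) are sorted for
#' determinism. This is the profile matrix consumed by the
#' solubility-correlation network.
#'
#' @param object a \code{pisa} fit.
#' @param ... unused.
#' @export
coef.pisa <- function(object, ...) {
  build_profile_matrix(object$hits)
}

#' Volcano-style plot of a treatment's solubility changes
#'
#' Mean log2 fold change against nSD for one treatment, hits highlighted.
#'
#' @param x a \code{pisa} fit.
#' @param treatment treatment id (default: the treatment with most hits).
#' @param ... passed to [graphics::plot()].
#' @export
plot.pisa <- function(x, treatment = NULL, ...) {
  h <- x$hits
  if (is.null(treatment)) {
    counts <- per_compound_hit_counts(h)
    treatment <- counts$treatment_id[which.max(counts$n_total)]
  }
  d <- h[h$treatment_id == treatment & !is.na(h$mean_log2fc) & !is.na(h$nsd), ]
  graphics::plot(d$mean_log2fc, d$nsd, pch = 16, cex = 0.5,
                 col = ifelse(d$is_hit, "firebrick", "grey60"),
                 xlab = expression(log[2] ~ "(compound / DMSO)"),
                 ylab = "nSD", main = treatment, ...)
  graphics::abline(v = c(-1, 1) * x$cutoffs$fc_cutoff, lty = 2, col = "grey40")
  graphics::abline(h = c(-1, 1) * x$cutoffs$nsd_cutoff, lty = 2, col = "grey40")
  invisible(x)
}
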