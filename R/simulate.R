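#' Compound effect and noise specifications for simulated screens
#'
#' [compound_effects()] builds the ground-truth table of ligand-induced
#' melting-temperature shifts: each row says that \code{compound_id} shifts
#' the Tm of \code{protein_id} by \code{delta_tm} degrees (positive =
#' stabilization, negative = destabilization). \code{effect_class}
#' distinguishes direct binding (\code{"primary"}) from secondary stability
#' changes (e.g. downstream phosphorylation loss); the simulator applies
#' both in cell mode and drops secondary effects in lysate mode.
#'
#' @param compound_id,protein_id identifiers.
#' @param delta_tm Tm shift in degrees C (signed).
#' @param effect_class \code{"primary"} or \code{"secondary"}.
#' @return data.frame of effects.
#' @export
compound_effects <- function(compound_id, protein_id, delta_tm,
                             effect_class = "primary") {
  out <- data.frame(compound_id = as.character(compound_id),
                    protein_id = as.character(protein_id),
                    delta_tm = as.numeric(delta_tm),
                    effect_class = rep_len(as.character(effect_class),
                                           length(compound_id)),
                    stringsAsFactors = FALSE)
  bad <- !out$effect_class %in% c("primary", "secondary")
  if (any(bad)) stop("effect_class must be 'primary' or 'secondary'")
  out
}

#' @rdname compound_effects
#' @param measurement_cv coefficient of variation of the multiplicative
#'   (log-normal) measurement noise on each matrix cell. The default 0.05
#'   reflects typical protein-level precision of summed TMT reporter-ion
#'   quantification.
#' @param loading_cv CV of per-channel loading factors (unequal total
#'   protein per channel, removed later by [normalize_channel_sums()]).
#' @export
noise_model <- function(measurement_cv = 0.05, loading_cv = 0.2) {
  if (measurement_cv < 0 || loading_cv < 0) stop("noise CVs must be >= 0")
  structure(list(measurement_cv = measurement_cv, loading_cv = loading_cv),
            class = "noise_model")
}

cv_to_sdlog <- function(cv) sqrt(log1p(cv^2))

#' Simulate a PISA screen with known ground truth
#'
#' Generates the soluble-abundance matrix a PISA screen would measure:
#' for every channel, each protein's abundance is
#' \code{loading_factor * S_M * exp(noise)}, where \code{S_M} is the
#' window-integrated soluble fraction of its melting curve after applying
#' the Tm shifts of the channel's treatment (secondary effects are dropped
#' in lysate mode), the loading factor is a per-channel log-normal scalar,
#' and the measurement noise is cell-wise log-normal. With both noise CVs
#' zero, channels are identical up to loading and every true log2 fold
#' change equals [expected_log2fc()] exactly.
#'
#' @param design a [screen_design()].
#' @param proteome melting-curve parameter data.frame
#'   (see [sample_proteome()]).
#' @param effects ground-truth [compound_effects()] table (NULL = null
#'   screen, no true shifts).
#' @param noise a [noise_model()].
#' @param seed integer seed driving loading and measurement noise.
#' @param intensity_scale arbitrary reporter-intensity unit scale.
#' @return list with elements \code{matrix} (a [pisa_matrix()]),
#'   \code{truth} (the effects table plus an \code{applied} flag recording
#'   mode-dependent suppression) and \code{design}.
#' @export
simulate_screen <- function(design, proteome, effects = NULL,
                            noise = noise_model(), seed = 1L,
                            intensity_scale = 1e6) {
  stopifnot(inherits(design, "screen_design"))
  proteome <- validate_melting_params(proteome)
  if (anyDuplicated(proteome$protein_id)) stop("duplicate protein ids in proteome")
  if (is.null(effects))
    effects <- compound_effects(character(0), character(0), numeric(0), character(0))
  if (nrow(effects)) {
    if (!all(effects$compound_id %in% design$compounds))
      stop("effects reference compounds absent from the design")
    if (!all(effects$protein_id %in% proteome$protein_id))
      stop("effects reference proteins absent from the proteome")
  }
  truth <- effects
  truth$applied <- rep(TRUE, nrow(truth))
  if (design$mode == "lysate" && nrow(truth))
    truth$applied <- truth$effect_class != "secondary"

  ann <- design$layout
  s0 <- integrate_window(proteome, design$window_low, design$window_high,
                         design$n_temperatures)
  names(s0) <- proteome$protein_id
  # per-treatment S_M vectors; only proteins touched by applied effects change
  s_for_treatment <- function(tr) {
    s <- s0
    eff <- truth[truth$compound_id == tr & truth$applied, , drop = FALSE]
    if (nrow(eff)) {
      idx <- match(eff$protein_id, proteome$protein_id)
      shifted <- proteome[idx, , drop = FALSE]
      shifted$tm <- shifted$tm + eff$delta_tm
      s[idx] <- integrate_window(shifted, design$window_low, design$window_high,
                                 design$n_temperatures)
    }
    s
  }
  treatments <- unique(ann$treatment_id[!ann$is_vehicle])
  s_table <- matrix(s0, nrow = nrow(proteome), ncol = length(treatments) + 1,
                    dimnames = list(proteome$protein_id, c("DMSO", treatments)))
  for (tr in treatments) s_table[, tr] <- s_for_treatment(tr)

  expected <- s_table[, ifelse(ann$is_vehicle, "DMSO", ann$treatment_id), drop = FALSE]
  colnames(expected) <- ann$channel_id

  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  loading <- stats::rlnorm(nrow(ann), meanlog = 0, sdlog = cv_to_sdlog(noise$loading_cv))
  eps <- matrix(stats::rnorm(length(expected), 0, cv_to_sdlog(noise$measurement_cv)),
                nrow = nrow(expected))
  values <- intensity_scale * sweep(expected, 2, loading, `*`) * exp(eps)
  list(matrix = pisa_matrix(values, ann), truth = truth, design = design)
}

#' Ready-made simulated screens for benchmarking the pipeline
#'
#' [benchmark_screen()] emulates the study conditions of a mid-size
#' cell-mode chemical screen: \code{n_compounds} compounds in duplicate,
#' each with one primary protein target whose Tm shift is drawn with random
#' sign and magnitude uniform on 0.5-6 degrees C (saturating ligand
#' engagement spans small to large shifts); a fifth of the compounds
#' additionally carry one secondary effect (|delta Tm| 1.5-3 C) that a
#' lysate-mode run suppresses. The proteome comes from [sample_proteome()];
#' target proteins are re-centred into the 50-54 C range so their melting
#' transition lies inside the thermal window.
#'
#' @param n_compounds,n_proteins screen size (defaults 50 and 2000).
#' @param mode \code{"cell"} or \code{"lysate"}.
#' @param noise a [noise_model()].
#' @param seed integer seed (drives proteome, effect draws and noise via
#'   fixed offsets, so any stage can be regenerated alone).
#' @return list: \code{matrix}, \code{truth}, \code{design},
#'   \code{proteome}, \code{targets} (a [target_annotations()] table of the
#'   primary effects).
#' @export
benchmark_screen <- function(n_compounds = 50, n_proteins = 2000,
                             mode = "cell", noise = noise_model(), seed = 1L) {
  proteome <- sample_proteome(n_proteins, seed = seed + 101L)
  design <- screen_design(n_compounds, mode = mode)
  old <- local_seed(seed + 202L)
  on.exit(restore_seed(old), add = TRUE)
  target_idx <- sample.int(n_proteins, n_compounds)
  # targets melt inside the window so that engagement is measurable
  proteome$tm[target_idx] <- stats::runif(n_compounds, 50, 54)
  eff <- compound_effects(
    compound_id = design$compounds,
    protein_id = proteome$protein_id[target_idx],
    delta_tm = sample(c(-1, 1), n_compounds, replace = TRUE) *
      stats::runif(n_compounds, 0.5, 6)
  )
  n_sec <- max(1L, n_compounds %/% 5)
  sec_idx <- sample(setdiff(seq_len(n_proteins), target_idx), n_sec)
  sec <- compound_effects(
    compound_id = design$compounds[seq_len(n_sec)],
    protein_id = proteome$protein_id[sec_idx],
    delta_tm = sample(c(-1, 1), n_sec, replace = TRUE) * stats::runif(n_sec, 1.5, 3),
    effect_class = "secondary"
  )
  proteome$tm[sec_idx] <- stats::runif(n_sec, 50, 54)
  effects <- rbind(eff, sec)
  sim <- simulate_screen(design, proteome, effects, noise, seed = seed + 303L)
  sim$proteome <- proteome
  sim$targets <- target_annotations(eff$compound_id, eff$protein_id)
  sim
}

#' @rdname benchmark_screen
#' @details [complex_screen()] plants a three-member protein complex whose
#' members share Tm-shift profiles across \code{n_shared_compounds}
#' compounds (mimicking co-regulated stability of complex subunits such as
#' RPS6KA1/2/3) among \code{n_background} unaffected proteins, for testing
#' solubility-correlation network recovery.
#' @param n_background background proteins without effects.
#' @param n_shared_compounds compounds engaging all three complex members.
#' @export
complex_screen <- function(n_background = 200, n_compounds = 40,
                           n_shared_compounds = 8, noise = noise_model(),
                           seed = 1L) {
  proteome <- sample_proteome(n_background + 3, seed = seed + 11L)
  members <- proteome$protein_id[1:3]
  old <- local_seed(seed + 22L)
  on.exit(restore_seed(old), add = TRUE)
  proteome$tm[1:3] <- stats::runif(3, 50, 54)
  design <- screen_design(n_compounds, mode = "cell")
  shared <- design$compounds[seq_len(n_shared_compounds)]
  base <- stats::runif(n_shared_compounds, 2.5, 5)
  eff <- compound_effects(
    compound_id = rep(shared, each = 3),
    protein_id = rep(members, times = n_shared_compounds),
    delta_tm = rep(base, each = 3) + stats::runif(3 * n_shared_compounds, -0.5, 0.5)
  )
  sim <- simulate_screen(design, proteome, eff, noise, seed = seed + 33L)
  sim$proteome <- proteome
  sim$members <- members
  sim
}

#' Write the ground-truth effect table of a simulated screen
#'
#' @param truth effects table from [simulate_screen()].
#' @param path output TSV path.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(truth)
}
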