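#' Two-state protein melting curves and thermal-window integration
#'
#' A PISA (proteome integral solubility alteration) experiment approximates
#' the area under a protein melting curve: aliquots of one sample are heated
#' across a thermal gradient, the soluble fractions are pooled in equal
#' volumes, and a single TMT reporter quantifies the pooled soluble protein.
#' These functions model the per-protein melting curve as a two-state
#' (folded/denatured) logistic in temperature with an optional
#' non-denaturing plateau, and compute the integrated soluble signal over a
#' thermal window.
#'
#' The soluble fraction at temperature T is
#' \deqn{f(T) = plateau + (1 - plateau) / (1 + exp((T - Tm)/slope))}
#' so that \code{f(Tm) = plateau + (1 - plateau)/2}, f is strictly
#' decreasing in T, and f tends to 1 as T decreases far below Tm.
#'
#' @param proteome data.frame with columns \code{tm} (melting temperature,
#'   degrees C), \code{slope} (transition scale, degrees C, > 0) and
#'   \code{plateau} (non-denaturing fraction in [0, 0.3]); typically from
#'   [sample_proteome()] or [melting_curve()].
#' @param temperature numeric vector of temperatures (degrees C). Recycled
#'   against the rows of \code{proteome} (one of the two must have length 1,
#'   or both equal length).
#' @return [soluble_fraction()]: numeric vector of soluble fractions in
#'   (0, 1].
#' @examples
#' p <- melting_curve(tm = 52, slope = 1.5, plateau = 0)
#' soluble_fraction(p, 52)             # 0.5 at the midpoint
#' integrate_window(p, 48, 58, 10)     # pooled soluble fraction, S_M
#' expected_log2fc(p, delta_tm = 2)    # stabilization -> positive log2 FC
#' @seealso [integrate_window()], [expected_log2fc()], [sample_proteome()]
#' @export
soluble_fraction <- function(proteome, temperature) {
  proteome <- validate_melting_params(proteome)
  plateau <- proteome$plateau
  plateau + (1 - plateau) / (1 + exp((temperature - proteome$tm) / proteome$slope))
}

#' Construct melting-curve parameters
#'
#' @param tm numeric vector of melting temperatures (degrees C).
#' @param slope numeric vector of transition scales (degrees C, > 0).
#' @param plateau numeric vector of non-denaturing fractions in [0, 0.3].
#' @param protein_id optional character vector of protein identifiers.
#' @return data.frame with one row per protein.
#' @export
melting_curve <- function(tm, slope, plateau = 0, protein_id = NULL) {
  n <- max(length(tm), length(slope), length(plateau))
  out <- data.frame(
    protein_id = if (is.null(protein_id)) sprintf("P%05d", seq_len(n)) else as.character(protein_id),
    tm = rep_len(as.numeric(tm), n),
    slope = rep_len(as.numeric(slope), n),
    plateau = rep_len(as.numeric(plateau), n),
    stringsAsFactors = FALSE
  )
  validate_melting_params(out)
}

validate_melting_params <- function(proteome) {
  if (!is.data.frame(proteome) || !all(c("tm", "slope", "plateau") %in% names(proteome)))
    stop("melting-curve parameters must be a data.frame with columns tm, slope, plateau")
  if (any(!is.finite(proteome$slope)) || any(proteome$slope <= 0))
    stop("melting-curve slope must be positive and finite")
  if (any(proteome$plateau < 0) || any(proteome$plateau > 0.3))
    stop("melting-curve plateau must lie in [0, 0.3]")
  proteome
}

#' Integrated soluble fraction over a thermal window (S_M)
#'
#' Equal-volume pooling of aliquots heated at \code{n_temperatures} equally
#' spaced points spanning \code{window_low} to \code{window_high} (endpoints
#' included) corresponds to the arithmetic mean of the soluble fraction over
#' that grid; the default 10 points mirrors splitting a culture into 10 PCR
#' tubes before the gradient.
#'
#' @inheritParams soluble_fraction
#' @param window_low,window_high thermal window bounds (degrees C),
#'   \code{window_low < window_high}. Defaults 48 and 58.
#' @param n_temperatures number of gradient points (>= 2), default 10.
#' @return numeric vector of mean soluble fractions, one per protein.
#' @export
integrate_window <- function(proteome, window_low = 48, window_high = 58,
                             n_temperatures = 10) {
  proteome <- validate_melting_params(proteome)
  if (!(window_low < window_high)) stop("window_low must be below window_high")
  if (n_temperatures < 2) stop("n_temperatures must be >= 2")
  temps <- seq(window_low, window_high, length.out = n_temperatures)
  acc <- numeric(nrow(proteome))
  for (t in temps) acc <- acc + soluble_fraction(proteome, t)
  acc / n_temperatures
}

#' Expected log2 fold change of pooled solubility for a Tm shift
#'
#' Ligand binding shifts the melting temperature by \code{delta_tm}; the
#' PISA readout is the change in integrated solubility,
#' \code{log2(S_M(tm + delta_tm) / S_M(tm))}. Its sign matches the sign of
#' \code{delta_tm} whenever the curve melts inside the window, and narrower
#' windows centred on the transition yield larger magnitudes.
#'
#' @inheritParams integrate_window
#' @param delta_tm melting-temperature shift (degrees C, signed; positive =
#'   stabilization).
#' @return numeric vector of expected log2 fold changes.
#' @export
expected_log2fc <- function(proteome, delta_tm, window_low = 48,
                            window_high = 58, n_temperatures = 10) {
  proteome <- validate_melting_params(proteome)
  shifted <- proteome
  shifted$tm <- shifted$tm + delta_tm
  log2(integrate_window(shifted, window_low, window_high, n_temperatures) /
         integrate_window(proteome, window_low, window_high, n_temperatures))
}

#' Sample a synthetic proteome of melting-curve parameters
#'
#' Melting temperatures are drawn from a normal distribution centred just
#' above the low edge of the default 48-58 degree window, so that the window
#' covers the back half of most melting curves and the pooled signal S_M is
#' informative (strictly between 0.05 and 0.95) for the large majority of
#' proteins. Transition scales and plateaus are drawn uniformly from ranges
#' typical of thermal proteome profiling fits.
#'
#' @param n_proteins number of proteins (>= 0).
#' @param tm_mean,tm_sd mean and SD of the Tm distribution (degrees C).
#' @param slope_range,plateau_range uniform sampling ranges for the
#'   transition scale and plateau.
#' @param seed integer seed; fixed seed gives identical output.
#' @return data.frame of melting-curve parameters (protein_id, tm, slope,
#'   plateau).
#' @export
sample_proteome <- function(n_proteins, tm_mean = 51, tm_sd = 4,
                            slope_range = c(1.2, 2.5),
                            plateau_range = c(0, 0.15), seed = 1L) {
  if (n_proteins < 0) stop("n_proteins must be non-negative")
  if (n_proteins == 0)
    return(melting_curve(tm = numeric(0), slope = numeric(0), plateau = numeric(0),
                         protein_id = character(0)))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  melting_curve(
    tm = stats::rnorm(n_proteins, tm_mean, tm_sd),
    slope = stats::runif(n_proteins, slope_range[1], slope_range[2]),
    plateau = stats::runif(n_proteins, plateau_range[1], plateau_range[2])
  )
}

# Save the RNG state, seed deterministically, and restore later so sampling
# helpers do not perturb the caller's random stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
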