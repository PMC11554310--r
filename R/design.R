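#' Lay out a multiplexed PISA screen across TMT plexes
#'
#' Packs compounds (each in \code{replicates} adjacent channels, so that
#' fold changes are always computed within a plex) plus vehicle control
#' channels into fixed-size TMT plexes. With a 16-plex, the cell-based
#' default of 4 vehicle channels per plex holds 6 compounds in duplicate
#' (96 compounds -> 16 plexes, 256 channels); the lysate default of 2
#' vehicle channels holds 7 (70 compounds -> 10 plexes, 160 channels).
#' Channels left over in the last plex are filled with extra vehicle
#' controls and reported via the \code{n_padding} attribute.
#'
#' @param compounds character vector of compound / treatment identifiers,
#'   or a single count (ids are then generated).
#' @param replicates replicate channels per compound (default 2).
#' @param plex_size channels per plex (default 16).
#' @param vehicle_per_plex vehicle (DMSO) channels per plex (>= 2).
#' @return data.frame annotation (one row per channel: \code{channel_id},
#'   \code{plex_id}, \code{treatment_id}, \code{replicate},
#'   \code{is_vehicle}) with attributes \code{n_plexes}, \code{n_channels},
#'   \code{n_padding}.
#' @examples
#' layout <- design_layout(96, replicates = 2, plex_size = 16, vehicle_per_plex = 4)
#' attr(layout, "n_plexes")    # 16
#' attr(layout, "n_channels")  # 256
#' @export
design_layout <- function(compounds, replicates = 2, plex_size = 16,
                          vehicle_per_plex = 4) {
  if (is.numeric(compounds) && length(compounds) == 1)
    compounds <- sprintf("cmpd%03d", seq_len(compounds))
  compounds <- as.character(compounds)
  if (anyDuplicated(compounds)) stop("duplicate compound ids")
  if (vehicle_per_plex < 2) stop("need >= 2 vehicle channels per plex")
  if (replicates < 1) stop("replicates must be >= 1")
  per_plex <- (plex_size - vehicle_per_plex) %/% replicates
  if (per_plex < 1)
    stop("infeasible layout: ", replicates, " replicate channels plus ",
         vehicle_per_plex, " vehicle channels do not fit a ", plex_size, "-plex")
  n_plexes <- max(1L, as.integer(ceiling(length(compounds) / per_plex)))
  rows <- vector("list", n_plexes)
  n_padding <- 0L
  for (p in seq_len(n_plexes)) {
    cmpds <- compounds[seq.int((p - 1) * per_plex + 1,
                               min(p * per_plex, length(compounds)))]
    cmpds <- cmpds[!is.na(cmpds)]
    treatment <- rep(cmpds, each = replicates)
    replicate <- rep(seq_len(replicates), times = length(cmpds))
    n_veh <- as.integer(plex_size - length(treatment))
    n_padding <- n_padding + as.integer(n_veh - vehicle_per_plex)
    ann <- data.frame(
      plex_id = sprintf("plex%02d", p),
      treatment_id = c(treatment, rep("DMSO", n_veh)),
      replicate = c(replicate, seq_len(n_veh)),
      is_vehicle = c(rep(FALSE, length(treatment)), rep(TRUE, n_veh)),
      stringsAsFactors = FALSE
    )
    ann$channel_id <- sprintf("plex%02d_ch%02d", p, seq_len(plex_size))
    rows[[p]] <- ann
  }
  out <- do.call(rbind, rows)
  out <- out[c("channel_id", "plex_id", "treatment_id", "replicate", "is_vehicle")]
  attr(out, "n_plexes") <- n_plexes
  attr(out, "n_channels") <- nrow(out)
  attr(out, "n_padding") <- n_padding
  out
}

#' Describe a PISA screen design
#'
#' Bundles the compound list, plex geometry, thermal window and assay mode.
#' In \code{"cell"} mode compound effects of both classes (direct binding
#' and secondary, e.g. signalling-driven, stability changes) are applied by
#' the simulator; in \code{"lysate"} mode secondary effects are suppressed,
#' mirroring the loss of cellular context in crude extracts.
#'
#' @inheritParams design_layout
#' @param window_low,window_high thermal gradient bounds (degrees C).
#' @param n_temperatures gradient points pooled per sample.
#' @param mode \code{"cell"} or \code{"lysate"}.
#' @return object of class \code{"screen_design"}.
#' @export
screen_design <- function(compounds, replicates = 2, plex_size = 16,
                          vehicle_per_plex = if (mode == "cell") 4 else 2,
                          window_low = 48, window_high = 58,
                          n_temperatures = 10, mode = c("cell", "lysate")) {
  mode <- match.arg(mode)
  if (is.numeric(compounds) && length(compounds) == 1)
    compounds <- sprintf("cmpd%03d", seq_len(compounds))
  layout <- design_layout(compounds, replicates, plex_size, vehicle_per_plex)
  layout$mode <- mode
  structure(list(
    compounds = as.character(compounds), replicates = replicates,
    plex_size = plex_size, vehicle_per_plex = vehicle_per_plex,
    window_low = window_low, window_high = window_high,
    n_temperatures = n_temperatures, mode = mode, layout = layout
  ), class = "screen_design")
}

#' @export
print.screen_design <- function(x, ...) {
  cat(sprintf("PISA screen design (%s mode): %d compounds x %d replicates\n",
              x$mode, length(x$compounds), x$replicates))
  cat(sprintf("  %d plexes of %d channels (%d total), window %g-%g C, %d gradient points\n",
              attr(x$layout, "n_plexes"), x$plex_size, attr(x$layout, "n_channels"),
              x$window_low, x$window_high, x$n_temperatures))
  invisible(x)
}
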