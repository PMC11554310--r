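# Small fixtures shared across test files; everything is built in code.

# one plex, one compound in duplicate, two vehicle channels
toy_annotations <- function() {
  data.frame(
    channel_id = c("c1", "c2", "c3", "c4"),
    plex_id = "plex01",
    treatment_id = c("drugA", "drugA", "DMSO", "DMSO"),
    replicate = c(1, 2, 1, 2),
    is_vehicle = c(FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

toy_matrix <- function(values = NULL) {
  if (is.null(values)) {
    values <- matrix(c(2, 2, 1, 1,
                       4, 4, 4, 4,
                       1, 3, 2, 2), nrow = 3, byrow = TRUE,
                     dimnames = list(c("P1", "P2", "P3"), c("c1", "c2", "c3", "c4")))
  }
  pisa_matrix(values, toy_annotations())
}

# a 16-channel single-plex annotation: 6 compounds x 2 + 4 vehicle
plex16_annotations <- function() {
  design_layout(sprintf("cmpd%03d", 1:6), replicates = 2, plex_size = 16,
                vehicle_per_plex = 4)
}

# independent oracle: trimmed mean/sd by literal sort-and-slice
oracle_trimmed <- function(x, trim) {
  x <- x[is.finite(x)]
  s <- sort(x)
  k <- floor(length(x) * trim)
  kept <- s[seq(k + 1, length(s) - k)]
  c(mean = mean(kept), sd = stats::sd(kept))
}

# independent oracle: Spearman rho by per-pair ranking then Pearson
oracle_spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  stats::cor(rank(x[ok]), rank(y[ok]))
}
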