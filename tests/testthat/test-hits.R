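test_that("log2 fold changes are taken against the within-plex vehicle mean", {
  m <- toy_matrix()  # P1: treated 2,2 vs vehicle 1,1; P2 flat; P3 treated 1,3 vs 2,2
  fc <- compute_log2fc(m)
  p1 <- fc[fc$protein_id == "P1" & !fc$is_vehicle, ]
  expect_equal(p1$log2fc, c(1, 1))
  p2 <- fc[fc$protein_id == "P2" & !fc$is_vehicle, ]
  expect_equal(p2$log2fc, c(0, 0))
  p3 <- fc[fc$protein_id == "P3" & !fc$is_vehicle, ]
  expect_equal(p3$log2fc, c(-1, log2(3 / 2)))
  # vehicle channels are scored leave-one-out: both vehicles equal -> 0
  expect_equal(fc$log2fc[fc$protein_id == "P2" & fc$is_vehicle], c(0, 0))
  # missing treated value stays missing
  m2 <- toy_matrix()
  m2$values["P1", "c1"] <- NA
  fc2 <- compute_log2fc(m2)
  expect_true(is.na(fc2$log2fc[fc2$protein_id == "P1" & fc2$channel_id == "c1"]))
})

test_that("trimmed SD matches the sort-and-slice oracle and shrinks outliers", {
  expect_equal(unname(trimmed_mean_sd(rep(0.3, 10), 0.1)[c("mean", "sd")]), c(0.3, 0))
  x <- c(0, 0, 0, 0, 10)
  expect_lt(trimmed_mean_sd(x, 0.2)["sd"], sd(x))
  v <- c(-0.3, -0.1, 0, 0.1, 0.3, 2.0)
  got <- trimmed_mean_sd(v, 1 / 6)
  want <- oracle_trimmed(v, 1 / 6)      # retains {-0.1, 0, 0.1, 0.3}
  expect_equal(unname(got["mean"]), unname(want["mean"]))
  expect_equal(unname(got["sd"]), unname(want["sd"]))
  expect_equal(unname(want["mean"]), mean(c(-0.1, 0, 0.1, 0.3)))
  expect_error(trimmed_mean_sd(v, 0.5), "trim")
  # trimmed SD never exceeds the untrimmed SD on unimodal draws
  set.seed(1)
  for (i in 1:20) {
    z <- rnorm(sample(5:50, 1))
    expect_lte(trimmed_mean_sd(z, 0.1)["sd"], sd(z) + 1e-12)
  }
})

test_that("nSD is the distance from the protein trimmed mean in trimmed-SD units", {
  # pure arithmetic: centre 0, sd 0.1, treatment at -0.35 -> nSD = -3.5
  fcdf <- data.frame(protein_id = "P", channel_id = "c9", plex_id = "p",
                     treatment_id = "t9", replicate = 1, is_vehicle = FALSE,
                     log2fc = -0.35)
  st <- data.frame(protein_id = "P", mean_log2fc_all_treatments = 0,
                   trimmed_sd = 0.1, n_treatments = 10)
  nd <- compute_nsd(fcdf, stats = st)
  expect_equal(nd$nsd, -3.5)
  # screen-level fixture agrees with an independent group-by/z-score oracle
  sim <- benchmark_screen(n_compounds = 6, n_proteins = 60, seed = 21)
  fc <- compute_log2fc(normalize_channel_sums(sim$matrix))
  nd2 <- compute_nsd(fc, trim = 0.1)
  fc$unit <- ifelse(fc$is_vehicle, paste0("DMSO.", fc$channel_id), fc$treatment_id)
  for (p in unique(fc$protein_id)[1:10]) {
    rows <- fc[fc$protein_id == p, ]
    tmeans <- tapply(rows$log2fc, rows$unit, mean, na.rm = TRUE)
    o <- oracle_trimmed(tmeans, 0.1)
    for (u in names(tmeans)) {
      got <- nd2$nsd[nd2$protein_id == p & nd2$unit_id == u]
      if (is.na(tmeans[u]) || o["sd"] == 0) expect_true(is.na(got)) else
        expect_equal(got, unname((tmeans[u] - o["mean"]) / o["sd"]), tolerance = 1e-12)
    }
  }
})

test_that("nSD is invariant to rescaling a protein's fold changes", {
  sim <- benchmark_screen(n_compounds = 5, n_proteins = 40, seed = 31)
  fc <- compute_log2fc(normalize_channel_sums(sim$matrix))
  nd1 <- compute_nsd(fc)
  fc2 <- fc
  sel <- fc2$protein_id == fc2$protein_id[1]
  fc2$log2fc[sel] <- fc2$log2fc[sel] * 7
  nd2 <- compute_nsd(fc2)
  i <- nd1$protein_id == fc$protein_id[1]
  expect_equal(nd1$nsd[i], nd2$nsd[i], tolerance = 1e-12)
})

test_that("the dual cutoff reproduces published example calls", {
  # MELK under OTS167 and KDM1A under GSK-LSD1, plus the two failure modes
  fcdf <- data.frame(
    protein_id = rep(c("MELK", "KDM1A", "X1", "X2"), each = 2),
    channel_id = paste0("c", 1:8), plex_id = "p",
    treatment_id = rep(c("OTS167", "GSK-LSD1", "tA", "tB"), each = 2),
    replicate = rep(1:2, 4), is_vehicle = FALSE,
    log2fc = c(-0.84, -0.84, 1.726, 1.726, 0.5, 0.5, 0.15, 0.15))
  st <- data.frame(
    protein_id = c("MELK", "KDM1A", "X1", "X2"),
    mean_log2fc_all_treatments = 0,
    trimmed_sd = c(0.84 / 5.688, 1.726 / 26.825, 0.25, 0.15 / 8),
    n_treatments = 50)
  hits <- call_hits(fcdf, fc_cutoff = 0.2, nsd_cutoff = 3.5, stats = st)
  melk <- hits[hits$protein_id == "MELK" & hits$treatment_id == "OTS167", ]
  expect_equal(melk$mean_log2fc, -0.84)
  expect_equal(melk$nsd, -5.688, tolerance = 1e-12)
  expect_true(melk$is_hit); expect_identical(melk$direction, "destabilized")
  kdm <- hits[hits$protein_id == "KDM1A" & hits$treatment_id == "GSK-LSD1", ]
  expect_equal(kdm$nsd, 26.825, tolerance = 1e-12)
  expect_true(kdm$is_hit); expect_identical(kdm$direction, "stabilized")
  x1 <- hits[hits$protein_id == "X1" & hits$treatment_id == "tA", ]
  expect_false(x1$is_hit)   # |nSD| = 2 fails the z-score cutoff
  x2 <- hits[hits$protein_id == "X2" & hits$treatment_id == "tB", ]
  expect_false(x2$is_hit)   # |log2FC| = 0.15 fails the fold-change cutoff
  expect_identical(x2$nsd, 8)
})

test_that("both replicates must pass the fold-change cutoff", {
  fcdf <- data.frame(protein_id = "P", channel_id = c("c1", "c2"), plex_id = "p",
                     treatment_id = "t", replicate = 1:2, is_vehicle = FALSE,
                     log2fc = c(0.5, 0.1))
  st <- data.frame(protein_id = "P", mean_log2fc_all_treatments = 0,
                   trimmed_sd = 0.05, n_treatments = 50)
  expect_false(call_hits(fcdf, stats = st)$is_hit)
  fcdf$log2fc <- c(0.5, NA)  # a missing replicate can never be a hit
  expect_false(call_hits(fcdf, stats = st)$is_hit)
})

test_that("raising either cutoff never increases hit counts", {
  sim <- benchmark_screen(n_compounds = 8, n_proteins = 120, seed = 41)
  fc <- compute_log2fc(normalize_channel_sums(sim$matrix))
  st <- protein_variability(fc)
  n_fc <- vapply(c(0.1, 0.2, 0.3, 0.5), function(v)
    sum(call_hits(fc, fc_cutoff = v, stats = st)$is_hit), 1)
  expect_true(all(diff(n_fc) <= 0))
  n_nsd <- vapply(c(2, 3, 3.5, 4, 5), function(v)
    sum(call_hits(fc, nsd_cutoff = v, stats = st)$is_hit), 1)
  expect_true(all(diff(n_nsd) <= 0))
})

test_that("null screens show monotonically falling hit rates as nSD cutoff grows", {
  for (seed in c(101, 202)) {
    pr <- sample_proteome(300, seed = seed)
    sim <- simulate_screen(screen_design(6), pr, NULL, noise_model(), seed = seed)
    fc <- compute_log2fc(normalize_channel_sums(sim$matrix))
    st <- protein_variability(fc)
    n <- vapply(2:5, function(v)
      sum(call_hits(fc, nsd_cutoff = v, stats = st)$is_hit), 1)
    expect_true(all(diff(n) <= 0))
  }
})

test_that("per-compound counts match a brute-force tally", {
  empty <- data.frame(protein_id = character(), treatment_id = character(),
                      mean_log2fc = numeric(), nsd = numeric(),
                      is_hit = logical(), direction = character())
  cc0 <- per_compound_hit_counts(empty)
  expect_identical(nrow(cc0), 0L)
  expect_identical(attr(cc0, "median_total"), 0)

  sim <- benchmark_screen(n_compounds = 10, n_proteins = 150, seed = 51)
  fit <- pisa(sim$matrix)
  counts <- per_compound_hit_counts(fit)
  for (tr in counts$treatment_id) {            # independent tally
    rows <- fit$hits[fit$hits$treatment_id == tr, ]
    expect_identical(counts$n_stabilized[counts$treatment_id == tr],
                     sum(rows$direction == "stabilized"))
    expect_identical(counts$n_destabilized[counts$treatment_id == tr],
                     sum(rows$direction == "destabilized"))
  }
  expect_identical(attr(counts, "median_total"), median(counts$n_total))
  # zero-noise screen with known effects: counts equal the injected counts
  pr <- sample_proteome(50, seed = 52)
  pr$tm[1:4] <- 52
  eff <- compound_effects(c("cmpd001", "cmpd001", "cmpd002", "cmpd003"),
                          pr$protein_id[1:4], c(4, 3, -4, 4))
  sim0 <- simulate_screen(screen_design(3), pr, eff, noise_model(0, 0), seed = 1)
  cnt0 <- per_compound_hit_counts(pisa(sim0$matrix))
  expect_identical(cnt0$n_total, c(2L, 1L, 1L))
  expect_identical(cnt0$n_destabilized, c(0L, 1L, 0L))
})

test_that("DMSO pseudo-compound calibration behaves on null and spiked screens", {
  # zero-noise null screen: exact zeros, rate 0
  pr <- sample_proteome(60, seed = 61)
  sim <- simulate_screen(screen_design(6), pr, NULL, noise_model(0, 0), seed = 1)
  fhr <- dmso_false_hit_rate(sim$matrix, normalize = FALSE)
  expect_identical(fhr$n_hits, 0L)
  expect_identical(fhr$rate, 0)
  # fewer than 4 vehicle channels per plex is an error
  sim2 <- simulate_screen(screen_design(7, mode = "lysate"), pr, NULL,
                          noise_model(0, 0), seed = 1)
  expect_error(dmso_false_hit_rate(sim2$matrix), "vehicle")
  # injection recovery: shift one vehicle channel +1 log2 for 50 proteins in a
  # multi-plex screen; pseudo-compounds referenced against the contaminated
  # channel flag predominantly the injected proteins
  pr3 <- sample_proteome(300, seed = 62)
  sim3 <- simulate_screen(screen_design(48), pr3, NULL, noise_model(), seed = 63)
  m3 <- sim3$matrix
  veh <- which(m3$annotations$is_vehicle & m3$annotations$plex_id == "plex01")[1]
  spiked <- rownames(m3$values)[1:50]
  m3$values[spiked, veh] <- m3$values[spiked, veh] * 2
  fhr3 <- dmso_false_hit_rate(m3)
  expect_gt(fhr3$n_hits, 20)
  # recompute the flagged set via the same partition to compare to the injection
  norm3 <- normalize_channel_sums(m3)
  hit_proteins <- character(0)
  for (i in 1:2) {
    ann2 <- norm3$annotations
    for (p in unique(ann2$plex_id)) {
      vehix <- which(ann2$plex_id == p & ann2$is_vehicle)
      vehix <- vehix[order(ann2$channel_id[vehix])]
      pair <- vehix[c(2 * i - 1, 2 * i)]
      ann2$treatment_id[pair] <- paste0("pseudo_", p)
      ann2$is_vehicle[pair] <- FALSE
      ann2$replicate[pair] <- 1:2
    }
    f <- pisa(pisa_matrix(norm3$values, ann2), normalize = FALSE)
    h <- f$hits[startsWith(f$hits$treatment_id, "pseudo_") & f$hits$is_hit, ]
    hit_proteins <- union(hit_proteins, h$protein_id)
  }
  expect_gt(length(hit_proteins), 0)
  expect_gt(mean(hit_proteins %in% spiked), 0.8)
})
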