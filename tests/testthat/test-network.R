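test_that("profile matrix averages replicates and preserves missingness", {
  h <- data.frame(protein_id = c("P1", "P1", "P2"),
                  treatment_id = c("tA", "tB", "tA"),
                  mean_log2fc = c(0.3, -0.1, NA))
  pm <- build_profile_matrix(h)
  expect_identical(dim(pm), c(2L, 2L))
  expect_equal(pm["P1", "tA"], 0.3)
  expect_true(is.na(pm["P2", "tA"]))
  expect_true(is.na(pm["P2", "tB"]))
  # replicate averaging upstream: 0.2 and 0.4 -> 0.3 in the fit's coef matrix
  fcdf <- data.frame(protein_id = "P", channel_id = c("c1", "c2"), plex_id = "p",
                     treatment_id = "t", replicate = 1:2, is_vehicle = FALSE,
                     log2fc = c(0.2, 0.4))
  st <- data.frame(protein_id = "P", mean_log2fc_all_treatments = 0,
                   trimmed_sd = 1, n_treatments = 9)
  expect_equal(call_hits(fcdf, stats = st)$mean_log2fc, 0.3)
  # pivot oracle on a random fixture
  set.seed(5)
  hh <- expand.grid(protein_id = paste0("P", 1:4), treatment_id = paste0("t", 1:3),
                    stringsAsFactors = FALSE)
  hh$mean_log2fc <- rnorm(12)
  pm2 <- build_profile_matrix(hh)
  for (r in 1:12)
    expect_equal(pm2[hh$protein_id[r], hh$treatment_id[r]], hh$mean_log2fc[r])
})

test_that("Spearman edges agree with a rank-then-Pearson oracle, ties included", {
  set.seed(17)
  m <- matrix(rnorm(48), 6, 8, dimnames = list(paste0("P", 1:6), paste0("t", 1:8)))
  m[sample(48, 6)] <- NA
  m[2, ] <- round(m[2, ] * 2) / 2          # introduce ties
  e <- all_by_all_spearman(m, min_pairs = 3)
  expect_equal(nrow(e), choose(6, 2))
  for (k in seq_len(nrow(e))) {
    want <- oracle_spearman(m[e$protein_a[k], ], m[e$protein_b[k], ])
    expect_equal(e$rho[k], want, tolerance = 1e-12)
    expect_identical(e$n_pairs[k],
                     sum(!is.na(m[e$protein_a[k], ]) & !is.na(m[e$protein_b[k], ])))
  }
  # monotone increasing vs decreasing -> rho -1; identical profile -> +1
  m2 <- rbind(a = 1:6, b = 6:1, c = (1:6)^3)
  colnames(m2) <- paste0("t", 1:6)
  e2 <- all_by_all_spearman(m2, min_pairs = 3)
  expect_equal(e2$rho[e2$protein_a == "a" & e2$protein_b == "b"], -1)
  expect_equal(e2$rho[e2$protein_a == "a" & e2$protein_b == "c"], 1)
  expect_error(all_by_all_spearman(m2[1, , drop = FALSE]), "2 protein")
  # comparison count follows the P^2 convention
  expect_identical(attr(e, "n_comparisons"), 36)
  expect_identical(n_binary_comparisons(8390), 70392100)
})

test_that("Spearman is invariant to monotone transforms and row order", {
  set.seed(23)
  m <- matrix(rnorm(60), 5, 12, dimnames = list(paste0("P", 1:5), paste0("t", 1:12)))
  e1 <- all_by_all_spearman(m, min_pairs = 3)
  m2 <- m; m2[1, ] <- exp(3 * m2[1, ]) - 0.5    # strictly monotone transform
  e2 <- all_by_all_spearman(m2, min_pairs = 3)
  expect_equal(e1$rho, e2$rho, tolerance = 1e-12)
  m3 <- m[sample(5), ]                          # row shuffle
  e3 <- all_by_all_spearman(m3, min_pairs = 3)
  key <- function(e) {
    k <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "|"),
                e$protein_a, e$protein_b)
    stats::setNames(e$rho, k)
  }
  k1 <- key(e1); k3 <- key(e3)
  expect_equal(k1[sort(names(k1))], k3[sort(names(k1))], tolerance = 1e-12)
})

test_that("edge filtering supports threshold and exact-quantile modes", {
  e <- data.frame(protein_a = "a", protein_b = paste0("b", 1:4),
                  rho = c(0.1, -0.2, 0.3, -0.34), n_pairs = 10, passes_filter = NA)
  ef <- filter_edges(e, "threshold", 0.35)
  expect_identical(sum(ef$passes_filter), 0L)
  e$rho <- c(0.5, -0.4, 0.3, 0.36)
  ef2 <- filter_edges(e, "threshold", 0.35)
  expect_identical(ef2$passes_filter, abs(e$rho) > 0.35)  # brute-force filter
  expect_equal(attr(ef2, "fraction_kept"), 0.75)
  # quantile mode keeps exactly the top fraction
  set.seed(3)
  big <- data.frame(protein_a = "a", protein_b = paste0("b", 1:1000),
                    rho = runif(1000, -1, 1), n_pairs = 10, passes_filter = NA)
  eq <- filter_edges(big, "quantile", 0.05)
  expect_identical(sum(eq$passes_filter), 50L)
  expect_gte(min(abs(eq$rho[eq$passes_filter])), max(abs(eq$rho[!eq$passes_filter])))
  expect_error(filter_edges(big, "quantile", 1.2), "quantile")
})

test_that("network construction, annotation and subgraphs match brute force", {
  e <- data.frame(protein_a = c("A", "A", "B", "C"),
                  protein_b = c("B", "C", "C", "D"),
                  rho = c(0.9, 0.8, 0.7, 0.1), n_pairs = 10, passes_filter = NA)
  ef <- filter_edges(e, "threshold", 0.35)
  ann <- kinase_annotations(c("A", "B", "C"), c("AGC", "AGC", "CMGC"))
  g <- build_network(ef, annotations = ann)
  expect_identical(sort(igraph::V(g)$name), c("A", "B", "C", "D"))
  expect_identical(igraph::V(g)$group[igraph::V(g)$name == "D"], "unknown")
  # D has no passing edge: isolated node
  expect_identical(igraph::degree(g)[["D"]], 0)
  # degree sequence equals a brute-force adjacency tally
  pass <- ef[ef$passes_filter, ]
  brute <- table(c(pass$protein_a, pass$protein_b))
  for (v in names(brute))
    expect_identical(igraph::degree(g)[[v]], as.numeric(brute[[v]]))
  # three mutually correlated proteins form a triangle
  expect_identical(igraph::ecount(extract_subgraph(g, nodes = c("A", "B", "C"))), 3)
  # selecting all nodes preserves the graph
  gall <- extract_subgraph(g, nodes = igraph::V(g)$name)
  expect_identical(igraph::ecount(gall), igraph::ecount(g))
  # group restriction keeps only AGC nodes and AGC-AGC edges (brute-force pair scan)
  gagc <- extract_subgraph(g, group = "AGC")
  expect_identical(sort(igraph::V(gagc)$name), c("A", "B"))
  expect_identical(igraph::ecount(gagc),
                   as.numeric(sum(pass$protein_a %in% c("A", "B") &
                                    pass$protein_b %in% c("A", "B"))))
  expect_warning(extract_subgraph(g, nodes = character(0)), "empty")
  expect_error(kinase_annotations("X", "NotAGroup"), "kinome")
  # no passing edges at all: isolated nodes only
  e0 <- filter_edges(e, "threshold", 0.95)
  g0 <- build_network(e0)
  expect_identical(igraph::ecount(g0), 0)
  expect_identical(igraph::vcount(g0), 4)
})

test_that("graph and edge exports are readable text artefacts", {
  e <- filter_edges(data.frame(protein_a = "A", protein_b = "B", rho = 0.9,
                               n_pairs = 10, passes_filter = NA), "threshold", 0.35)
  g <- build_network(e)
  gp <- file.path(tempdir(), "net.graphml")
  ep <- file.path(tempdir(), "edges.tsv")
  write_network_graphml(g, gp)
  write_edge_table(e, ep)
  g2 <- igraph::read_graph(gp, format = "graphml")
  expect_identical(igraph::vcount(g2), 2)
  expect_identical(nrow(utils::read.delim(ep)), 1L)
})
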