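#' Kinome group vocabulary
#'
#' Standard kinase family classification used to annotate network nodes.
#' @export
kinome_groups <- c("AGC", "Atypical", "CAMK", "CK1", "CMGC", "STE", "TK",
                   "TKL", "Other", "non-protein kinase")

#' Kinase (kinome-group) node annotations
#'
#' @param protein_id identifiers.
#' @param group one of [kinome_groups].
#' @return data.frame of annotations.
#' @export
kinase_annotations <- function(protein_id, group) {
  group <- as.character(group)
  bad <- !group %in% kinome_groups
  if (any(bad))
    stop("unknown kinome group(s): ", paste(unique(group[bad]), collapse = ", "))
  data.frame(protein_id = as.character(protein_id), group = group,
             stringsAsFactors = FALSE)
}

#' Assemble the protein x treatment solubility profile matrix
#'
#' Averages replicate log2 fold changes per (protein, treatment) and pivots
#' to a wide matrix with deterministically (alphabetically) ordered rows
#' and columns. Proteins unmeasured under a treatment stay missing, never
#' zero.
#'
#' @param x a \code{pisa} fit or a [call_hits()] table (columns protein_id,
#'   treatment_id, mean_log2fc).
#' @return numeric matrix, proteins x treatments.
#' @export
build_profile_matrix <- function(x) {
  h <- hits_of(x)
  proteins <- sort(unique(h$protein_id))
  treatments <- sort(unique(h$treatment_id))
  m <- matrix(NA_real_, length(proteins), length(treatments),
              dimnames = list(proteins, treatments))
  v <- tapply(h$mean_log2fc,
              list(factor(h$protein_id, proteins), factor(h$treatment_id, treatments)),
              mean, na.rm = TRUE)
  m[] <- v
  m[is.nan(m)] <- NA_real_
  m
}

#' Total number of binary comparisons for an all-by-all correlation map
#'
#' Reported with the P^2 convention (self-pairs and both orders counted)
#' for a matrix of P proteins; the edge list itself stores each unordered
#' pair once.
#'
#' @param n_proteins number of proteins P.
#' @return numeric count P^2.
#' @export
n_binary_comparisons <- function(n_proteins) as.numeric(n_proteins)^2

#' All-by-all Spearman correlation of solubility profiles
#'
#' Rank-based Spearman's rho (average ranks for ties, pairwise-complete
#' treatments) between every unordered pair of protein profiles with at
#' least \code{min_pairs} jointly measured treatments. Rank correlation is
#' used to damp the influence of single extreme thermal stability
#' responses.
#'
#' @param profiles protein x treatment matrix from
#'   [build_profile_matrix()].
#' @param min_pairs minimum jointly complete treatments per pair
#'   (default 10, >= 3).
#' @return data.frame of edges (protein_a, protein_b, rho, n_pairs,
#'   passes_filter = NA until [filter_edges()]) with attribute
#'   \code{n_comparisons} = P^2.
#' @export
all_by_all_spearman <- function(profiles, min_pairs = 10) {
  if (nrow(profiles) < 2) stop("need at least 2 protein profiles")
  if (min_pairs < 3) stop("min_pairs must be >= 3")
  R <- suppressWarnings(
    stats::cor(t(profiles), method = "spearman", use = "pairwise.complete.obs"))
  np <- crossprod(!is.na(t(profiles)))
  iu <- which(upper.tri(R), arr.ind = TRUE)
  edges <- data.frame(protein_a = rownames(profiles)[iu[, 1]],
                      protein_b = rownames(profiles)[iu[, 2]],
                      rho = R[iu],
                      n_pairs = as.integer(np[iu]),
                      passes_filter = NA,
                      stringsAsFactors = FALSE)
  edges <- edges[edges$n_pairs >= min_pairs & !is.na(edges$rho), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "n_comparisons") <- n_binary_comparisons(nrow(profiles))
  edges
}

#' Flag edges passing the correlation filter
#'
#' Threshold mode keeps \code{|rho| > value} (default 0.35, which on the
#' published cell-based screen corresponds to roughly the top 5 percent of
#' absolute correlations); quantile mode keeps exactly the top
#' \code{value} fraction by |rho| with deterministic tie-breaking (by
#' |rho| descending, then protein ids). The complementary statistic is
#' attached: the fraction kept (threshold mode) or the implied threshold
#' (quantile mode).
#'
#' @param edges edge table from [all_by_all_spearman()].
#' @param mode \code{"threshold"} or \code{"quantile"}.
#' @param value threshold on |rho|, or fraction in (0, 1).
#' @return edges with \code{passes_filter} set; attributes
#'   \code{fraction_kept} and \code{implied_threshold}.
#' @export
filter_edges <- function(edges, mode = c("threshold", "quantile"), value = 0.35) {
  mode <- match.arg(mode)
  n <- nrow(edges)
  if (mode == "threshold") {
    edges$passes_filter <- abs(edges$rho) > value
  } else {
    if (value <= 0 || value >= 1) stop("quantile must lie in (0, 1)")
    k <- floor(value * n + 1e-9)
    ord <- order(-abs(edges$rho), edges$protein_a, edges$protein_b)
    edges$passes_filter <- FALSE
    edges$passes_filter[ord[seq_len(k)]] <- TRUE
  }
  kept <- sum(edges$passes_filter)
  attr(edges, "fraction_kept") <- if (n) kept / n else 0
  attr(edges, "implied_threshold") <-
    if (kept) min(abs(edges$rho[edges$passes_filter])) else NA_real_
  edges
}

#' Build the solubility correlation network
#'
#' Undirected graph over protein nodes with the filtered correlation edges
#' (edge weight = rho). Nodes carry a kinome \code{group} attribute
#' ("unknown" when unannotated). \code{nodes} restricts the network to an
#' annotated subset, e.g. the quantified human kinases.
#'
#' @param edges filtered edge table from [filter_edges()].
#' @param annotations optional [kinase_annotations()] table.
#' @param nodes optional character vector of node ids to keep (default:
#'   every protein occurring in \code{edges}, including proteins whose
#'   edges were all filtered away, which become isolated nodes).
#' @return an [igraph::igraph] graph.
#' @export
build_network <- function(edges, annotations = NULL, nodes = NULL) {
  all_nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  if (is.null(nodes)) nodes <- all_nodes
  keep <- !is.na(edges$passes_filter) & edges$passes_filter &
    edges$protein_a %in% nodes & edges$protein_b %in% nodes
  e <- edges[keep, c("protein_a", "protein_b", "rho", "n_pairs"), drop = FALSE]
  names(e)[3] <- "weight"
  vert <- data.frame(name = nodes, stringsAsFactors = FALSE)
  vert$group <- if (is.null(annotations)) rep("unknown", nrow(vert)) else {
    g <- annotations$group[match(nodes, annotations$protein_id)]
    ifelse(is.na(g), "unknown", g)
  }
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = vert)
}

#' Induced subgraph by node set or kinome group
#'
#' @param graph an igraph network from [build_network()].
#' @param nodes character vector of node names to keep.
#' @param group keep only nodes annotated with this kinome group.
#' @return induced subgraph preserving edge weights and node annotations.
#' @export
extract_subgraph <- function(graph, nodes = NULL, group = NULL) {
  keep <- igraph::V(graph)$name
  if (!is.null(group)) keep <- keep[igraph::V(graph)$group %in% group]
  if (!is.null(nodes)) keep <- intersect(keep, nodes)
  if (!length(keep)) warning("empty node selection; returning empty graph")
  igraph::induced_subgraph(graph, keep)
}

#' Export network artefacts
#'
#' @param edges edge table.
#' @param graph igraph network.
#' @param path output path (TSV for edges, GraphML for the graph).
#' @export
write_edge_table <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edges)
}

#' @rdname write_edge_table
#' @export
write_network_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(graph)
}
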