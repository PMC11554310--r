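#' Configure an end-to-end screen analysis
#'
#' A pipeline run either simulates a screen (simulation block) or reads a
#' measured one (input block: matrix + annotation paths, optional target
#' annotation path); exactly one of the two must be given. Cutoffs default
#' to the screening framework's values.
#'
#' @param input list(matrix, annotations, targets = NULL) of file paths, or
#'   NULL.
#' @param simulation list(n_compounds, n_proteins, mode, measurement_cv,
#'   loading_cv), or NULL; missing fields take [benchmark_screen()]
#'   defaults.
#' @param fc_cutoff,nsd_cutoff,trim hit-calling parameters.
#' @param correlation_threshold,min_pairs network edge filter parameters.
#' @return object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL, fc_cutoff = 0.2,
                            nsd_cutoff = 3.5, trim = 0.1,
                            correlation_threshold = 0.35, min_pairs = 10) {
  if (is.null(input) == is.null(simulation))
    stop("exactly one of input / simulation must be given")
  check_cutoffs(fc_cutoff, nsd_cutoff, trim)
  if (correlation_threshold <= 0) stop("correlation_threshold must be positive")
  structure(list(input = input, simulation = simulation, fc_cutoff = fc_cutoff,
                 nsd_cutoff = nsd_cutoff, trim = trim,
                 correlation_threshold = correlation_threshold,
                 min_pairs = min_pairs),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML config file with the same fields.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full PISA screen pipeline
#'
#' simulate-or-read, normalize, call hits, assess known targets (when
#' annotations are available), build the solubility-correlation network,
#' and write every stage output plus a run log and summary into
#' \code{out_dir}. Fully deterministic for a fixed seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @param seed integer seed for any simulation.
#' @return (invisibly) the summary list, also written to
#'   \code{summary.yaml}.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  targets <- NULL
  if (!is.null(config$simulation)) {
    sim <- stage("simulate", {
      s <- config$simulation
      args <- list(seed = seed)
      for (f in c("n_compounds", "n_proteins", "mode")) if (!is.null(s[[f]])) args[[f]] <- s[[f]]
      nm <- noise_model(
        measurement_cv = if (is.null(s$measurement_cv)) 0.05 else s$measurement_cv,
        loading_cv = if (is.null(s$loading_cv)) 0.2 else s$loading_cv)
      args$noise <- nm
      do.call(benchmark_screen, args)
    })
    mat <- sim$matrix
    targets <- sim$targets
    write_ground_truth(sim$truth, file.path(out_dir, "ground_truth.tsv"))
  } else {
    mat <- stage("read", read_abundance_matrix(config$input$matrix,
                                               config$input$annotations))
    if (!is.null(config$input$targets))
      targets <- read_target_annotations(config$input$targets)
  }
  norm <- stage("normalize", normalize_channel_sums(mat))
  write_abundance_matrix(norm, file.path(out_dir, "normalized_matrix.tsv"),
                         file.path(out_dir, "annotations.tsv"))
  fit <- stage("call_hits", pisa(norm, fc_cutoff = config$fc_cutoff,
                                 nsd_cutoff = config$nsd_cutoff,
                                 trim = config$trim, normalize = FALSE))
  utils::write.table(fit$hits, file.path(out_dir, "hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts <- per_compound_hit_counts(fit)
  utils::write.table(counts, file.path(out_dir, "hit_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  nveh <- tapply(norm$annotations$is_vehicle, norm$annotations$plex_id, sum)
  fhr <- if (all(nveh >= 4))
    stage("false_hit_rate",
          dmso_false_hit_rate(norm, config$fc_cutoff, config$nsd_cutoff,
                              config$trim, normalize = FALSE))
  else list(rate = NA_real_, n_hits = NA_integer_, n_measurements = NA_integer_)

  target_rates <- NULL
  if (!is.null(targets)) {
    tab <- stage("assess_targets", on_target_table(cell = fit, targets = targets))
    utils::write.table(tab, file.path(out_dir, "on_target.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    target_rates <- hit_rate_summary(tab)
  }

  net <- stage("network", {
    profiles <- build_profile_matrix(fit)
    edges <- all_by_all_spearman(profiles, min_pairs = config$min_pairs)
    edges <- filter_edges(edges, "threshold", config$correlation_threshold)
    g <- build_network(edges)
    write_edge_table(edges, file.path(out_dir, "edges.tsv"))
    write_network_graphml(g, file.path(out_dir, "network.graphml"))
    list(n_edges = nrow(edges), n_passing = sum(edges$passes_filter),
         n_comparisons = attr(edges, "n_comparisons"),
         fraction_kept = attr(edges, "fraction_kept"))
  })

  summary <- list(
    seed = seed,
    cutoffs = list(fc_cutoff = config$fc_cutoff, nsd_cutoff = config$nsd_cutoff,
                   trim = config$trim,
                   correlation_threshold = config$correlation_threshold,
                   min_pairs = config$min_pairs),
    n_proteins = nrow(norm$values),
    n_channels = ncol(norm$values),
    n_plexes = length(unique(norm$annotations$plex_id)),
    n_hits = sum(fit$hits$is_hit),
    n_stabilized = sum(fit$hits$direction == "stabilized"),
    n_destabilized = sum(fit$hits$direction == "destabilized"),
    median_hits_per_compound = attr(counts, "median_total"),
    dmso_false_hit_rate = fhr$rate,
    on_target = target_rates,
    network = net
  )
  yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  log_lines <- c(
    sprintf("pisascreen %s", as.character(utils::packageVersion("pisascreen"))),
    sprintf("seed: %d", seed),
    sprintf("cutoffs: |log2FC| >= %g, |nSD| >= %g, trim %g/tail, |rho| > %g, min_pairs %d",
            config$fc_cutoff, config$nsd_cutoff, config$trim,
            config$correlation_threshold, config$min_pairs),
    sprintf("matrix: %d proteins x %d channels in %d plexes",
            summary$n_proteins, summary$n_channels, summary$n_plexes),
    sprintf("hits: %d (%d stabilized / %d destabilized), median %g per compound",
            summary$n_hits, summary$n_stabilized, summary$n_destabilized,
            summary$median_hits_per_compound),
    sprintf("DMSO false-hit rate: %s",
            ifelse(is.na(fhr$rate), "not computed (<4 vehicle channels/plex)",
                   sprintf("%.4f (%d / %d)", fhr$rate, fhr$n_hits, fhr$n_measurements))),
    sprintf("network: %d edges, %d passing filter (fraction %.4f)",
            net$n_edges, net$n_passing, net$fraction_kept))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(summary)
}
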