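#' Configuration for a reproducible pipeline run
#'
#' Collects every knob of the end-to-end workflow with the package
#' defaults: 100 bootstrap iterations, correlation threshold 0.8, top 20
#' nodes. A seed is always recorded — if none is supplied one is drawn and
#' stored so the run log suffices to replay the analysis exactly.
#'
#' @param input A feature table (tibble) or path to a CSV readable by
#'   [read_feature_table()].
#' @param input2 Optional second table/path for a two-project comparison.
#' @param drop_columns Metadata columns to drop when reading from CSV.
#' @param clr Apply [clr_transform()] after reading (default `FALSE`; the
#'   transform is never implicit).
#' @param pseudocount clr pseudocount (default 1).
#' @param iterations Bootstrap replicates per table (default 100).
#' @param threshold Correlation threshold (default 0.8).
#' @param mode Edge mode (default `"both"`).
#' @param seed Integer seed; auto-generated and recorded when `NULL`.
#' @param top_k Top-node count for reports (default 20).
#' @param max_degree Optional degree cap for an extra filtered rendering.
#' @param out_dir Output directory (created if needed).
#' @return A validated `run_config` list.
#' @export
run_config <- function(input, input2 = NULL, drop_columns = character(),
                       clr = FALSE, pseudocount = 1, iterations = 100,
                       threshold = 0.8, mode = c("both", "positive", "negative"),
                       seed = NULL, top_k = 20, max_degree = NULL,
                       out_dir = tempfile("netboot_run_")) {
  mode <- match.arg(mode)
  iterations <- assert_count(iterations, "iterations")
  assert_scalar_number(threshold, "threshold")
  if (threshold <= 0 || threshold > 1) {
    abort("`threshold` must lie in (0, 1].")
  }
  top_k <- assert_count(top_k, "top_k")
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
  }
  seed <- assert_count(seed, "seed", lower = 0L)
  structure(
    list(input = input, input2 = input2, drop_columns = drop_columns,
         clr = isTRUE(clr), pseudocount = pseudocount, iterations = iterations,
         threshold = threshold, mode = mode, seed = seed, top_k = top_k,
         max_degree = max_degree, out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the single-table bootstrap network workflow
#'
#' Reads (or accepts) one feature table, standardizes feature names,
#' optionally clr-transforms, bootstraps, correlates, computes per-replicate
#' network statistics, and writes into the output directory:
#' `replicate_stats.csv`, `network_stats_summary.csv`, `network.svg`
#' (average-correlation network), `top_nodes.csv`, `name_map.csv` and a
#' machine-readable `run_log.json` carrying the full configuration, seed
#' and degeneracy events — enough to reproduce the run byte-for-byte.
#'
#' @param config A [run_config()] with a single input.
#' @return Invisibly, a list with the computed objects (`stats`, `summary`,
#'   `average_matrix`, `graph`, `top_nodes`, `name_map`) and `out_dir`.
#' @export
run_single <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$input2)) {
    abort("run_single() takes one input table; use run_compare() for two.")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- run_one_table(config$input, config, seed = config$seed,
                       out_dir = config$out_dir)
  summary <- analyze_network_statistics(list(project = res$stats),
                                        out_dir = NULL)
  write_table(summary, file.path(config$out_dir, "network_stats_summary.csv"))
  write_run_log(config, list(project = res), file.path(config$out_dir, "run_log.json"))
  invisible(c(res, list(summary = summary, out_dir = config$out_dir)))
}

#' Run the two-project comparison workflow
#'
#' Everything [run_single()] writes, once per project (subdirectories `A/`
#' and `B/`), plus the seven cross-project box plots, the combined summary
#' and `comparison.csv` with the replicate-paired binomial test for every
#' metric. The two projects use equal iteration counts (required by the
#' pairing rule) and distinct seeds derived from the configured seed.
#'
#' @param config A [run_config()] with `input` and `input2` set.
#' @return Invisibly, a list with per-project results (`A`, `B`),
#'   `summary`, `comparison` and `out_dir`.
#' @export
run_compare <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$input2)) {
    abort("run_compare() needs `input2`; use run_single() for one table.")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  # distinct per-project streams, both reproducible from the one config seed
  res_a <- run_one_table(config$input, config, seed = config$seed,
                         out_dir = file.path(config$out_dir, "A"))
  res_b <- run_one_table(config$input2, config, seed = config$seed + 1L,
                         out_dir = file.path(config$out_dir, "B"))
  projects <- list(A = res_a$stats, B = res_b$stats)
  summary <- analyze_network_statistics(projects, out_dir = config$out_dir)
  comparison <- net_stat_binomial_test(res_a$stats, res_b$stats)
  write_table(tidy(comparison), file.path(config$out_dir, "comparison.csv"))
  write_run_log(config, list(A = res_a, B = res_b),
                file.path(config$out_dir, "run_log.json"))
  invisible(list(A = res_a, B = res_b, summary = summary,
                 comparison = comparison, out_dir = config$out_dir))
}

# --- internals --------------------------------------------------------------

run_one_table <- function(input, config, seed, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  table <- if (is.character(input)) {
    read_feature_table(input, drop_columns = config$drop_columns)
  } else {
    input
  }
  mapped <- map_columns(table)
  table <- mapped$table
  if (config$clr) {
    table <- clr_transform(table, pseudocount = config$pseudocount)
  }
  reps <- bootstrap_replicates(table, iterations = config$iterations, seed = seed)
  mats <- correlation_matrix(reps)
  stats <- calculate_network_statistics(mats, threshold = config$threshold,
                                        mode = config$mode)
  graph <- build_network_graph(mats, threshold = config$threshold,
                               mode = config$mode, max_degree = config$max_degree,
                               path = file.path(out_dir, "network.svg"))
  top <- top_nodes(graph, config$top_k)

  write_table(stats, file.path(out_dir, "replicate_stats.csv"))
  write_table(top, file.path(out_dir, "top_nodes.csv"))
  write_table(mapped$name_map, file.path(out_dir, "name_map.csv"))
  list(stats = stats, average_matrix = average_correlation(mats), graph = graph,
       top_nodes = top, name_map = mapped$name_map,
       degeneracies = attr(mats, "degeneracies"), seed = seed)
}

write_run_log <- function(config, results, path) {
  log <- list(
    config = list(
      drop_columns = config$drop_columns, clr = config$clr,
      pseudocount = config$pseudocount, iterations = config$iterations,
      threshold = config$threshold, mode = config$mode, seed = config$seed,
      top_k = config$top_k,
      max_degree = if (is.null(config$max_degree)) NA else config$max_degree
    ),
    projects = lapply(results, function(r) {
      list(seed = r$seed,
           n_degeneracy_events = nrow(r$degeneracies),
           degeneracies = r$degeneracies)
    })
  )
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
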