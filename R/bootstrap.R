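#' Bootstrap replicates of a feature table
#'
#' Generates `iterations` bootstrap replicates by drawing `n` sample rows
#' uniformly with replacement from the input table. Every replicate has the
#' same shape, feature names and feature order as the source, and every
#' replicate row is an exact copy of some source row. One seeded generator
#' stream drives all replicates, so identical `(table, iterations, seed)`
#' reproduce the replicate set exactly.
#'
#' @param table A feature table (first column `sample_id`).
#' @param iterations Number of bootstrap replicates (default 100).
#' @param seed Optional integer seed. `NULL` draws from the current RNG
#'   state; the workflow functions always record the seed they used.
#' @return A `replicate_set`: a tibble with columns `replicate` (integer)
#'   and `table` (list of feature tables), carrying attributes
#'   `source_shape`, `feature_ids` and `seed`.
#' @examples
#' ft <- generate_feature_table(synthetic_design(n_samples = 6, seed = 1))
#' bootstrap_replicates(ft, iterations = 3, seed = 42)
#' @export
bootstrap_replicates <- function(table, iterations = 100, seed = NULL) {
  iterations <- assert_count(iterations, "iterations")
  m <- feature_matrix(table)
  n <- nrow(m)
  if (n < 2L) {
    abort("Bootstrapping needs at least 2 samples; resampling a single row is degenerate.")
  }
  idx <- with_seed(seed, {
    lapply(seq_len(iterations), function(i) sample.int(n, n, replace = TRUE))
  })
  feats <- feature_ids(table)
  reps <- lapply(idx, function(i) {
    out <- table[i, , drop = FALSE]
    out$sample_id <- table$sample_id[i]
    out
  })
  structure(
    tibble(replicate = seq_len(iterations), table = reps),
    source_shape = c(n = n, p = length(feats)),
    feature_ids = feats,
    seed = seed,
    class = c("replicate_set", class(tibble()))
  )
}

#' @export
print.replicate_set <- function(x, ...) {
  shp <- attr(x, "source_shape")
  cat(sprintf("<replicate_set> %d bootstrap replicates of a %d x %d feature table\n",
              nrow(x), shp[["n"]], shp[["p"]]))
  seed <- attr(x, "seed")
  if (!is.null(seed)) cat(sprintf("  seed: %s\n", format(seed)))
  invisible(x)
}
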