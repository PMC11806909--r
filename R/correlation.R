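#' Spearman rank correlation of two vectors
#'
#' The tie-corrected Spearman coefficient: Pearson correlation of average
#' (fractional) ranks. Returns `NA` when either vector is constant, where
#' the coefficient is undefined.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return A number in \[-1, 1\], or `NA` for a constant input.
#' @examples
#' spearman_cor(c(1, 2, 2, 3), c(1, 3, 2, 4))
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) {
    abort(sprintf("Vectors must have equal length (got %d and %d).",
                  length(x), length(y)))
  }
  if (length(x) < 2L) {
    abort("Need at least two observations.")
  }
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Spearman correlation matrices for a replicate set
#'
#' Computes a symmetric p-by-p Spearman matrix for every bootstrap
#' replicate. Bootstrap resampling of sparse count data often produces
#' constant columns, for which the coefficient is undefined: such pairs are
#' stored as 0 (so they can never form edges downstream) and every event is
#' recorded in the `degeneracies` attribute rather than propagated as a
#' missing value.
#'
#' @param replicates A `replicate_set` from [bootstrap_replicates()], or a
#'   plain list of feature tables sharing the same features.
#' @return A list of correlation matrices (dimnames = feature ids, unit
#'   diagonal, entries in \[-1, 1\]) with attribute `degeneracies`: a tibble
#'   of `(replicate, feature)` rows naming the constant columns seen.
#' @export
correlation_matrix <- function(replicates) {
  tables <- if (inherits(replicates, "replicate_set")) replicates$table else replicates
  if (!is.list(tables) || length(tables) == 0L) {
    abort("`replicates` must be a non-empty replicate set or list of feature tables.")
  }
  degen <- list()
  mats <- vector("list", length(tables))
  for (b in seq_along(tables)) {
    m <- feature_matrix(tables[[b]])
    if (ncol(m) < 2L) {
      abort("Correlation needs at least 2 features.")
    }
    cm <- suppressWarnings(stats::cor(m, method = "spearman"))
    constant <- colnames(m)[apply(m, 2L, function(v) length(unique(v)) < 2L)]
    if (length(constant) > 0L) {
      degen[[length(degen) + 1L]] <- tibble(replicate = b, feature = constant)
    }
    cm[is.na(cm)] <- 0
    diag(cm) <- 1
    mats[[b]] <- cm
  }
  attr(mats, "degeneracies") <-
    if (length(degen) > 0L) dplyr::bind_rows(degen) else
      tibble(replicate = integer(), feature = character())
  mats
}

#' Average a list of correlation matrices
#'
#' Element-wise arithmetic mean of the replicate correlation matrices,
#' giving the single consolidated matrix used for network rendering.
#'
#' @param matrices A list of correlation matrices with identical feature
#'   ids and ordering (e.g. the output of [correlation_matrix()]).
#' @return One correlation matrix.
#' @export
average_correlation <- function(matrices) {
  if (is.matrix(matrices)) {
    return(matrices)
  }
  if (!is.list(matrices) || length(matrices) == 0L) {
    abort("`matrices` must be a non-empty list of correlation matrices.")
  }
  ref <- colnames(matrices[[1L]])
  for (m in matrices) {
    if (!identical(colnames(m), ref) || !identical(rownames(m), ref)) {
      abort("All correlation matrices must share the same features in the same order.")
    }
  }
  Reduce(`+`, matrices) / length(matrices)
}

#' Bootstrap and return the average correlation matrix
#'
#' Convenience composition: resample, correlate each replicate, average.
#'
#' @inheritParams bootstrap_replicates
#' @inheritParams threshold_graph
#' @return The average Spearman correlation matrix across replicates.
#' @export
bootstrap_average_correlation <- function(table, iterations = 100, seed = NULL) {
  average_correlation(correlation_matrix(bootstrap_replicates(table, iterations, seed)))
}

#' Write a correlation matrix as labelled square CSV
#'
#' @param matrix A correlation matrix with feature dimnames.
#' @param path Output path.
#' @export
write_correlation_matrix <- function(matrix, path) {
  df <- as_tibble(matrix, rownames = "feature")
  write_table(df, path)
}
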