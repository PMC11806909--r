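METRIC_NAMES <- c("n_edges", "n_nodes", "avg_degree_centrality", "transitivity",
                  "avg_closeness", "avg_betweenness", "density")

#' Summarize bootstrapped network statistics across projects
#'
#' For each project and each of the seven network statistics, reports the
#' bootstrap mean and the "standard error using standard deviation" — the
#' sample standard deviation (denominator n - 1) of the replicate metric
#' values. Optionally writes the summary CSV and one box-and-whisker SVG per
#' metric comparing the projects.
#'
#' @param projects Named list of replicate statistics tibbles, each the
#'   output of [calculate_network_statistics()] with at least 2 replicates.
#' @param out_dir Optional directory; when given, `network_stats_summary.csv`
#'   and `boxplot_<metric>.svg` files are written into it.
#' @return A tibble with columns `project`, `metric`, `mean`, `std_error`,
#'   `B` (replicate count), 7 rows per project.
#' @export
analyze_network_statistics <- function(projects, out_dir = NULL) {
  if (!is.list(projects) || length(projects) == 0L || is.null(names(projects)) ||
      any(names(projects) == "")) {
    abort("`projects` must be a non-empty named list of replicate statistics tibbles.")
  }
  for (nm in names(projects)) {
    if (!is.data.frame(projects[[nm]]) || nrow(projects[[nm]]) < 2L) {
      abort(sprintf("Project '%s' needs at least 2 replicates to summarize.", nm))
    }
  }
  long <- stats_long(projects)
  summary <- long |>
    dplyr::group_by(.data$project, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      std_error = stats::sd(.data$value),
      B = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(metric = factor(.data$metric, levels = METRIC_NAMES)) |>
    dplyr::arrange(.data$project, .data$metric) |>
    dplyr::mutate(metric = as.character(.data$metric))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(summary, file.path(out_dir, "network_stats_summary.csv"))
    for (m in METRIC_NAMES) {
      save_svg_plot(plot_metric_boxplot(projects, m),
                    file.path(out_dir, paste0("boxplot_", m, ".svg")))
    }
  }
  summary
}

#' Exact two-tailed binomial p-value at success probability 1/2
#'
#' `p = min(1, 2 * min(P(X <= k), P(X >= k)))` for `X ~ Binomial(n, 1/2)`.
#' Tail sums are accumulated in log space, so `log10_p` stays finite even
#' when the p-value underflows double precision (e.g. 500 wins out of 500
#' gives p = (1/2)^499, log10 p of about -150.2).
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of (non-tied) trials, `n >= 1`.
#' @return List with `p_value` (in \[0, 1\], possibly 0 by underflow) and
#'   `log10_p` (always finite).
#' @examples
#' exact_binomial_pvalue(0, 10)   # 2 * (1/2)^10 = 1/512
#' exact_binomial_pvalue(500, 500)
#' @export
exact_binomial_pvalue <- function(k, n) {
  n <- assert_count(n, "n")
  k <- assert_count(k, "k", lower = 0L)
  if (k > n) {
    abort(sprintf("`k` must be between 0 and n = %d, got %d.", n, k))
  }
  log_lower <- log_sum_exp(stats::dbinom(0:k, n, 0.5, log = TRUE))
  log_upper <- log_sum_exp(stats::dbinom(k:n, n, 0.5, log = TRUE))
  log_p <- min(0, log(2) + min(log_lower, log_upper))
  list(p_value = exp(log_p), log10_p = log_p / log(10))
}

#' Replicate-paired binomial comparison of two bootstrapped networks
#'
#' For each of the seven network statistics, pairs replicate i of project A
#' with replicate i of project B, drops exact ties (sign-test convention: a
#' tie is evidence for neither direction, and the integer-valued metrics tie
#' often), counts `k` = pairs where A's value exceeds B's, and evaluates the
#' exact two-tailed binomial test at p = 1/2 on the remaining
#' `n_effective` pairs. No multiple-testing correction is applied; all seven
#' raw p-values are reported.
#'
#' @param stats_a,stats_b Replicate statistics tibbles from
#'   [calculate_network_statistics()], equal length >= 10.
#' @param alpha Two-tailed significance level for the `direction` call
#'   (default 0.05).
#' @return A `netboot_comparison` tibble with one row per metric: `metric`,
#'   `n_effective`, `k_successes`, `statistic` (= k/n_effective), `p_value`,
#'   `log10_p`, `direction` (`"A-greater"`, `"B-greater"`, `"none"`, or
#'   `"untestable"` when every pair tied, with `statistic`/`p_value` `NA`).
#' @export
net_stat_binomial_test <- function(stats_a, stats_b, alpha = 0.05) {
  if (!is.data.frame(stats_a) || !is.data.frame(stats_b)) {
    abort("Inputs must be replicate statistics tibbles.")
  }
  if (nrow(stats_a) != nrow(stats_b)) {
    abort(sprintf("Replicate counts differ (%d vs %d); the test pairs replicate i with replicate i.",
                  nrow(stats_a), nrow(stats_b)))
  }
  if (nrow(stats_a) < 10L) {
    abort("Need at least 10 paired replicates for the binomial comparison.")
  }
  rows <- purrr::map(METRIC_NAMES, function(m) {
    a <- stats_a[[m]]
    b <- stats_b[[m]]
    untied <- a != b
    n_eff <- sum(untied)
    if (n_eff == 0L) {
      return(tibble(metric = m, n_effective = 0L, k_successes = 0L,
                    statistic = NA_real_, p_value = NA_real_,
                    log10_p = NA_real_, direction = "untestable"))
    }
    k <- sum(a[untied] > b[untied])
    p <- exact_binomial_pvalue(k, n_eff)
    direction <- if (p$p_value < alpha) {
      if (k > n_eff / 2) "A-greater" else "B-greater"
    } else "none"
    tibble(metric = m, n_effective = as.integer(n_eff), k_successes = as.integer(k),
           statistic = k / n_eff, p_value = p$p_value, log10_p = p$log10_p,
           direction = direction)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "B") <- nrow(stats_a)
  attr(out, "alpha") <- alpha
  class(out) <- c("netboot_comparison", class(tibble()))
  out
}

#' @export
print.netboot_comparison <- function(x, ...) {
  cat(sprintf("Replicate-paired binomial comparison (B = %d, alpha = %s)\n",
              attr(x, "B"), format(attr(x, "alpha"))))
  underflow <- !is.na(x$p_value) & x$p_value == 0
  NextMethod()
  if (any(underflow)) {
    cat("* p-value below the representable double-precision minimum; see log10_p.\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a network metric comparison
#'
#' @param x A `netboot_comparison`.
#' @param ... Unused.
#' @return The comparison as a plain tibble, one row per metric.
#' @method tidy netboot_comparison
#' @export
tidy.netboot_comparison <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  attr(out, "B") <- NULL
  attr(out, "alpha") <- NULL
  out
}

#' One-row summary of a network metric comparison
#'
#' @param x A `netboot_comparison`.
#' @param ... Unused.
#' @return Tibble with `B`, `n_metrics`, `n_significant` (at the comparison
#'   alpha) and `min_p_value`.
#' @method glance netboot_comparison
#' @export
glance.netboot_comparison <- function(x, ...) {
  tibble(
    B = attr(x, "B"),
    n_metrics = nrow(x),
    n_significant = sum(x$direction %in% c("A-greater", "B-greater")),
    min_p_value = if (all(is.na(x$p_value))) NA_real_ else min(x$p_value, na.rm = TRUE)
  )
}

# --- internals --------------------------------------------------------------

stats_long <- function(projects) {
  purrr::imap(projects, function(df, nm) {
    df |>
      dplyr::select(dplyr::any_of(c("replicate", METRIC_NAMES))) |>
      tidyr::pivot_longer(dplyr::all_of(METRIC_NAMES),
                          names_to = "metric", values_to = "value") |>
      dplyr::mutate(project = nm, .before = 1L)
  }) |>
    dplyr::bind_rows()
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
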