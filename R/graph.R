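#' Build a thresholded signed network from a correlation matrix
#'
#' Forms an undirected signed graph whose nodes are features and whose
#' edges are correlations passing the (inclusive) magnitude threshold:
#' `mode = "both"` keeps |r| >= threshold, `"positive"` keeps
#' r >= threshold, `"negative"` keeps r <= -threshold. The node set is the
#' union of edge endpoints — isolated features are excluded, so the node
#' count is itself an informative bootstrapped statistic rather than the
#' constant feature count.
#'
#' @param matrix A symmetric correlation matrix with feature dimnames.
#' @param threshold Correlation magnitude cutoff in (0, 1]; default 0.8.
#' @param mode Which edge signs to keep: `"both"` (default), `"positive"`,
#'   or `"negative"`.
#' @return A `corr_network`: list with `nodes` (character), `edges` (tibble
#'   `from`, `to`, `weight` with signed correlation weights), `threshold`
#'   and `mode`.
#' @examples
#' m <- diag(3); dimnames(m) <- list(c("a", "b", "c"), c("a", "b", "c"))
#' m["a", "b"] <- m["b", "a"] <- 0.9
#' m["b", "c"] <- m["c", "b"] <- -0.85
#' threshold_graph(m, 0.8)
#' @export
threshold_graph <- function(matrix, threshold = 0.8, mode = c("both", "positive", "negative")) {
  mode <- match.arg(mode)
  assert_scalar_number(threshold, "threshold")
  if (threshold <= 0 || threshold > 1) {
    abort("`threshold` must lie in (0, 1].")
  }
  features <- colnames(matrix)
  if (is.null(features)) {
    features <- paste0("X", seq_len(ncol(matrix)))
  }
  p <- ncol(matrix)
  keep_from <- integer()
  keep_to <- integer()
  if (p >= 2L) {
    ut <- upper.tri(matrix)
    pass <- switch(mode,
      both = abs(matrix) >= threshold,
      positive = matrix >= threshold,
      negative = matrix <= -threshold
    ) & ut
    idx <- which(pass, arr.ind = TRUE)
    keep_from <- idx[, 1L]
    keep_to <- idx[, 2L]
  }
  ord <- order(keep_from, keep_to)
  edges <- tibble(
    from = features[keep_from][ord],
    to = features[keep_to][ord],
    weight = matrix[cbind(keep_from, keep_to)][ord]
  )
  nodes <- features[sort(unique(c(keep_from, keep_to)))]
  structure(
    list(nodes = nodes, edges = edges, threshold = threshold, mode = mode),
    class = "corr_network"
  )
}

#' @export
print.corr_network <- function(x, ...) {
  cat(sprintf("<corr_network> %d nodes, %d edges (threshold %s, mode %s)\n",
              length(x$nodes), nrow(x$edges), format(x$threshold), x$mode))
  invisible(x)
}

#' Node degrees of a network
#'
#' @param graph A `corr_network`.
#' @return Named integer vector of degrees over `graph$nodes`.
#' @export
node_degrees <- function(graph) {
  deg <- stats::setNames(integer(length(graph$nodes)), graph$nodes)
  if (nrow(graph$edges) > 0L) {
    tab <- table(c(graph$edges$from, graph$edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' The seven network statistics of a signed network
#'
#' Computes, from first principles on the unweighted graph skeleton
#' (correlation sign and magnitude decide edge existence, never path
#' length):
#' \itemize{
#'   \item `n_nodes`, `n_edges` — counts;
#'   \item `avg_degree_centrality` — mean of degree/(N-1), identically
#'     equal to density;
#'   \item `transitivity` — 3 x triangles / connected triples;
#'   \item `avg_closeness` — per node u, with k_u the size of u's connected
#'     component and d unweighted shortest-path length,
#'     ((k_u - 1)/(N - 1)) * ((k_u - 1) / sum of d(u, v)); the
#'     Wasserman–Faust component correction, averaged over nodes;
#'   \item `avg_betweenness` — Brandes accumulation per source, pair counts
#'     halved for undirectedness, normalized by (N-1)(N-2)/2, averaged;
#'   \item `density` — 2E / (N(N-1)).
#' }
#' Degenerate denominators (empty graph, N <= 2 for betweenness, no
#' connected triples) yield 0 so bootstrap summaries never hit undefined
#' divisions.
#'
#' @param graph A `corr_network`.
#' @return One-row tibble with columns `n_nodes`, `n_edges`,
#'   `avg_degree_centrality`, `transitivity`, `avg_closeness`,
#'   `avg_betweenness`, `density`.
#' @export
graph_metrics <- function(graph) {
  n <- length(graph$nodes)
  e <- nrow(graph$edges)
  if (n <= 1L) {
    return(tibble(
      n_nodes = n, n_edges = e, avg_degree_centrality = 0, transitivity = 0,
      avg_closeness = 0, avg_betweenness = 0, density = 0
    ))
  }
  adj <- adjacency_list(graph)
  deg <- lengths(adj)

  density <- 2 * e / (n * (n - 1))
  # sum(deg) = 2E by the handshake lemma, so this mean equals density to the
  # last bit — both are the same integer ratio
  avg_degree_centrality <- sum(deg) / (n * (n - 1))

  triples <- sum(deg * (deg - 1)) / 2
  transitivity <- if (triples > 0) 3 * count_triangles(adj) / triples else 0

  sp <- all_shortest_path_stats(adj, n)
  avg_closeness <- mean(sp$closeness)
  avg_betweenness <- if (n > 2L) {
    mean(sp$betweenness / ((n - 1) * (n - 2) / 2))
  } else 0

  tibble(
    n_nodes = n, n_edges = e,
    avg_degree_centrality = avg_degree_centrality,
    transitivity = transitivity,
    avg_closeness = avg_closeness,
    avg_betweenness = avg_betweenness,
    density = density
  )
}

#' Network statistics for every replicate correlation matrix
#'
#' Thresholds each matrix into a signed network and computes the seven
#' statistics, one row per replicate in input order.
#'
#' @param matrices List of correlation matrices (see
#'   [correlation_matrix()]).
#' @inheritParams threshold_graph
#' @return A tibble with a `replicate` index column plus the seven metric
#'   columns of [graph_metrics()].
#' @examples
#' ft <- generate_feature_table(synthetic_design(seed = 7))
#' mats <- correlation_matrix(bootstrap_replicates(ft, iterations = 5, seed = 7))
#' calculate_network_statistics(mats)
#' @export
calculate_network_statistics <- function(matrices, threshold = 0.8,
                                         mode = c("both", "positive", "negative")) {
  mode <- match.arg(mode)
  if (is.matrix(matrices)) {
    matrices <- list(matrices)
  }
  if (!is.list(matrices) || length(matrices) == 0L) {
    abort("`matrices` must be a non-empty list of correlation matrices.")
  }
  rows <- lapply(matrices, function(m) {
    graph_metrics(threshold_graph(m, threshold = threshold, mode = mode))
  })
  out <- dplyr::bind_cols(tibble(replicate = seq_along(matrices)),
                          dplyr::bind_rows(rows))
  class(out) <- c("netboot_stats", class(tibble()))
  out
}

# --- internal graph algorithms ---------------------------------------------
# All metrics are computed from scratch on an integer adjacency list; no
# graph library is used outside the test oracles.

adjacency_list <- function(graph) {
  n <- length(graph$nodes)
  idx <- stats::setNames(seq_len(n), graph$nodes)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  if (nrow(graph$edges) > 0L) {
    f <- idx[graph$edges$from]
    t <- idx[graph$edges$to]
    for (k in seq_along(f)) {
      adj[[f[k]]] <- c(adj[[f[k]]], t[k])
      adj[[t[k]]] <- c(adj[[t[k]]], f[k])
    }
  }
  adj
}

count_triangles <- function(adj) {
  n <- length(adj)
  tri <- 0L
  for (u in seq_len(n)) {
    nb <- adj[[u]]
    nb <- nb[nb > u]
    if (length(nb) < 2L) next
    for (a in seq_len(length(nb) - 1L)) {
      v <- nb[a]
      w <- nb[(a + 1L):length(nb)]
      tri <- tri + sum(w %in% adj[[v]] & w > v)
    }
  }
  tri
}

# One BFS per source: shortest-path distances and path counts feed both the
# component-corrected closeness and the Brandes betweenness accumulation.
all_shortest_path_stats <- function(adj, n) {
  betweenness <- numeric(n)
  closeness <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep.int(-1L, n)
    sigma <- numeric(n)
    preds <- vector("list", n)
    order_visited <- integer(n)
    dist[s] <- 0L
    sigma[s] <- 1
    queue <- integer(n)
    queue[1L] <- s
    head <- 1L; tail <- 1L; visited <- 0L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      visited <- visited + 1L
      order_visited[visited] <- v
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    reach <- which(dist >= 0L)
    k <- length(reach)
    if (k > 1L && n > 1L) {
      total_dist <- sum(dist[reach])
      closeness[s] <- ((k - 1) / (n - 1)) * ((k - 1) / total_dist)
    }
    # Brandes dependency accumulation in reverse BFS order.
    delta <- numeric(n)
    for (i in rev(seq_len(visited))) {
      w <- order_visited[i]
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) {
        betweenness[w] <- betweenness[w] + delta[w]
      }
    }
  }
  list(betweenness = betweenness / 2, closeness = closeness)
}
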