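# Independent oracles used across the suite. Deliberately naive: explicit
# rank assignment, Floyd-Warshall distances, exhaustive shortest-path
# enumeration, and bit-level outcome enumeration. None of them share code
# with the package internals they check.

# Average (fractional) ranks assigned by hand, then textbook Pearson by
# direct summation.
naive_rank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

naive_spearman <- function(x, y) {
  rx <- naive_rank(x)
  ry <- naive_rank(y)
  n <- length(x)
  sx <- sum(rx); sy <- sum(ry)
  sxx <- sum(rx^2); syy <- sum(ry^2); sxy <- sum(rx * ry)
  num <- n * sxy - sx * sy
  den <- sqrt(n * sxx - sx^2) * sqrt(n * syy - sy^2)
  num / den
}

# Adjacency matrix of a corr_network, in node order.
graph_adjacency <- function(graph) {
  n <- length(graph$nodes)
  a <- matrix(0L, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges) > 0L) {
    a[cbind(graph$edges$from, graph$edges$to)] <- 1L
    a[cbind(graph$edges$to, graph$edges$from)] <- 1L
  }
  a
}

# All-pairs unweighted distances by Floyd-Warshall.
brute_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1L] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

brute_transitivity <- function(a) {
  n <- nrow(a)
  closed <- 0L
  open_or_closed <- 0L
  for (center in seq_len(n)) {
    nb <- which(a[center, ] == 1L)
    if (length(nb) < 2L) next
    pairs <- utils::combn(nb, 2L)
    for (q in seq_len(ncol(pairs))) {
      open_or_closed <- open_or_closed + 1L
      if (a[pairs[1L, q], pairs[2L, q]] == 1L) closed <- closed + 1L
    }
  }
  if (open_or_closed == 0L) return(0)
  closed / open_or_closed
}

brute_closeness <- function(a) {
  n <- nrow(a)
  d <- brute_distances(a)
  vapply(seq_len(n), function(u) {
    reach <- which(is.finite(d[u, ]))
    k <- length(reach)
    if (k <= 1L || n <= 1L) return(0)
    ((k - 1) / (n - 1)) * ((k - 1) / sum(d[u, reach]))
  }, numeric(1L))
}

# Enumerate every shortest path between every unordered pair and count the
# interior appearances of each node.
brute_betweenness <- function(a) {
  n <- nrow(a)
  bc <- numeric(n)
  if (n <= 2L) return(bc)
  d <- brute_distances(a)
  all_paths <- function(s, t) {
    # all shortest s->t node sequences, walking down the distance gradient
    extend <- function(path) {
      v <- path[length(path)]
      if (v == t) return(list(path))
      nexts <- which(a[v, ] == 1L & d[, t] == d[v, t] - 1)
      out <- list()
      for (w in nexts) out <- c(out, extend(c(path, w)))
      out
    }
    extend(s)
  }
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      if (!is.finite(d[s, t]) || d[s, t] == 0) next
      paths <- all_paths(s, t)
      np <- length(paths)
      for (p in paths) {
        interior <- p[-c(1L, length(p))]
        for (v in interior) bc[v] <- bc[v] + 1 / np
      }
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

# Two-tailed binomial p at 1/2 by enumerating all 2^n outcomes bitwise.
brute_binomial_pvalue <- function(k, n) {
  stopifnot(n <= 16)
  wins <- vapply(0:(2^n - 1), function(o) sum(bitwAnd(o, 2^(0:(n - 1))) > 0), numeric(1L))
  lower <- sum(wins <= k) / 2^n
  upper <- sum(wins >= k) / 2^n
  min(1, 2 * min(lower, upper))
}

# Naive linear-space tail summation (underflows where p < ~1e-300).
naive_binomial_pvalue <- function(k, n) {
  lower <- sum(choose(n, 0:k) * 0.5^n)
  upper <- sum(choose(n, k:n) * 0.5^n)
  min(1, 2 * min(lower, upper))
}

# Random corr_network on up to max_nodes features: each pair gets an edge
# with probability prob and a random signed weight above the threshold.
random_graph <- function(seed, max_nodes = 8L, prob = 0.4, threshold = 0.5) {
  set.seed(seed)
  p <- sample(2:max_nodes, 1L)
  feats <- sprintf("f%02d", seq_len(p))
  m <- diag(p)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      if (stats::runif(1) < prob) {
        m[i, j] <- m[j, i] <- sample(c(-1, 1), 1L) * stats::runif(1, threshold, 1)
      }
    }
  }
  dimnames(m) <- list(feats, feats)
  threshold_graph(m, threshold = threshold)
}

# Small labelled correlation matrix from an edge list (weights past 0.8).
corr_from_edges <- function(features, edges) {
  p <- length(features)
  m <- diag(p)
  dimnames(m) <- list(features, features)
  for (e in edges) {
    m[e[[1L]], e[[2L]]] <- m[e[[2L]], e[[1L]]] <- e[[3L]]
  }
  m
}
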