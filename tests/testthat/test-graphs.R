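three_feature_matrix <- function() {
  corr_from_edges(c("f1", "f2", "f3"),
                  list(list("f1", "f2", 0.9), list("f1", "f3", 0.5),
                       list("f2", "f3", -0.85)))
}

test_that("thresholding keeps strong correlations per mode, inclusively", {
  m <- three_feature_matrix()
  both <- threshold_graph(m, 0.8)
  expect_equal(nrow(both$edges), 2L)
  expect_setequal(paste(both$edges$from, both$edges$to), c("f1 f2", "f2 f3"))
  expect_equal(length(both$nodes), 3L)

  pos <- threshold_graph(m, 0.8, mode = "positive")
  expect_equal(nrow(pos$edges), 1L)
  expect_equal(pos$nodes, c("f1", "f2"))

  neg <- threshold_graph(m, 0.8, mode = "negative")
  expect_equal(paste(neg$edges$from, neg$edges$to), "f2 f3")
  expect_lt(neg$edges$weight, 0)

  # boundary values form edges ("0.8 or higher" / "-0.8 or lower")
  b <- corr_from_edges(c("x", "y", "z"), list(list("x", "y", 0.8), list("y", "z", -0.8)))
  expect_equal(nrow(threshold_graph(b, 0.8)$edges), 2L)

  weak <- corr_from_edges(c("x", "y"), list(list("x", "y", 0.79)))
  empty <- threshold_graph(weak, 0.8)
  expect_equal(length(empty$nodes), 0L)
  expect_equal(nrow(empty$edges), 0L)

  expect_error(threshold_graph(m, 0), "threshold")
  expect_error(threshold_graph(m, 1.2), "threshold")
})

test_that("metrics on a triangle, a path and disjoint edges match hand enumeration", {
  k3 <- corr_from_edges(letters[1:3],
                        list(list("a", "b", 0.9), list("a", "c", 0.9), list("b", "c", 0.9)))
  m <- graph_metrics(threshold_graph(k3, 0.8))
  expect_equal(m$n_edges, 3L)
  expect_equal(m$n_nodes, 3L)
  expect_equal(m$avg_degree_centrality, 1)
  expect_equal(m$transitivity, 1)
  expect_equal(m$density, 1)
  expect_equal(m$avg_betweenness, 0)
  expect_equal(m$avg_closeness, 1)

  path <- corr_from_edges(letters[1:3],
                          list(list("a", "b", 0.9), list("b", "c", 0.9)))
  m <- graph_metrics(threshold_graph(path, 0.8))
  expect_equal(m$n_edges, 2L)
  expect_equal(m$density, 2 / 3)
  expect_equal(m$avg_degree_centrality, 2 / 3)
  expect_equal(m$transitivity, 0)
  expect_equal(m$avg_betweenness, 1 / 3)
  expect_equal(m$avg_closeness, 7 / 9)

  two <- corr_from_edges(letters[1:4],
                         list(list("a", "b", 0.9), list("c", "d", 0.9)))
  m <- graph_metrics(threshold_graph(two, 0.8))
  expect_equal(m$n_nodes, 4L)
  expect_equal(m$avg_closeness, 1 / 3)
  expect_equal(m$avg_betweenness, 0)
  expect_equal(m$transitivity, 0)
})

test_that("an empty graph yields all-zero metrics", {
  weak <- corr_from_edges(c("x", "y"), list(list("x", "y", 0.5)))
  m <- graph_metrics(threshold_graph(weak, 0.8))
  expect_equal(unlist(m), c(n_nodes = 0, n_edges = 0, avg_degree_centrality = 0,
                            transitivity = 0, avg_closeness = 0,
                            avg_betweenness = 0, density = 0))
})

test_that("metrics agree with brute-force enumeration and igraph on random graphs", {
  skip_if_not_installed("igraph")
  for (seed in 1:60) {
    g <- random_graph(seed)
    if (length(g$nodes) == 0L) next
    a <- graph_adjacency(g)
    m <- graph_metrics(g)
    expect_equal(m$transitivity, brute_transitivity(a), tolerance = 1e-10)
    expect_equal(m$avg_closeness, mean(brute_closeness(a)), tolerance = 1e-10)
    expect_equal(m$avg_betweenness, mean(brute_betweenness(a)), tolerance = 1e-10)
    # independent library cross-check
    ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    if (nrow(a) > 2) {
      expect_equal(m$avg_betweenness,
                   mean(igraph::betweenness(ig, normalized = TRUE)),
                   tolerance = 1e-10)
    }
    if (igraph::ecount(ig) > 0) {
      it <- igraph::transitivity(ig, type = "global")
      expect_equal(m$transitivity, ifelse(is.nan(it), 0, it), tolerance = 1e-10)
    }
  }
})

test_that("metrics are invariant under node relabeling", {
  g <- random_graph(101, max_nodes = 8L)
  perm <- sample(seq_along(g$nodes))
  relabeled <- g
  newnames <- stats::setNames(sprintf("z%02d", perm), g$nodes)
  relabeled$nodes <- sort(unname(newnames[g$nodes]))
  relabeled$edges$from <- unname(newnames[g$edges$from])
  relabeled$edges$to <- unname(newnames[g$edges$to])
  swap <- relabeled$edges$from > relabeled$edges$to
  tmp <- relabeled$edges$from[swap]
  relabeled$edges$from[swap] <- relabeled$edges$to[swap]
  relabeled$edges$to[swap] <- tmp
  expect_equal(graph_metrics(relabeled), graph_metrics(g), tolerance = 1e-12)
})

test_that("replicate statistics compose threshold_graph and graph_metrics in order", {
  ft <- generate_feature_table(synthetic_design(seed = 31))
  mats <- correlation_matrix(bootstrap_replicates(ft, iterations = 5, seed = 2))
  stats <- calculate_network_statistics(mats, threshold = 0.8)
  expect_equal(nrow(stats), 5L)
  expect_equal(stats$replicate, 1:5)
  expect_identical(
    unlist(stats[3, -1]),
    unlist(graph_metrics(threshold_graph(mats[[3]], 0.8)))
  )
})

test_that("edge and node counts fall (weakly) as the threshold rises; modes partition", {
  ft <- generate_feature_table(synthetic_design(seed = 32))
  mats <- correlation_matrix(bootstrap_replicates(ft, iterations = 10, seed = 3))
  s08 <- calculate_network_statistics(mats, threshold = 0.8)
  s09 <- calculate_network_statistics(mats, threshold = 0.9)
  expect_true(all(s09$n_edges <= s08$n_edges))
  expect_true(all(s09$n_nodes <= s08$n_nodes))

  for (m in mats[1:3]) {
    both <- threshold_graph(m, 0.8)
    pos <- threshold_graph(m, 0.8, mode = "positive")
    neg <- threshold_graph(m, 0.8, mode = "negative")
    key <- function(g) paste(g$edges$from, g$edges$to)
    expect_setequal(c(key(pos), key(neg)), key(both))
    expect_length(intersect(key(pos), key(neg)), 0L)
  }
})

test_that("average degree centrality equals density and metrics stay in range", {
  for (seed in 200:230) {
    m <- graph_metrics(random_graph(seed))
    expect_identical(m$avg_degree_centrality, m$density)
    expect_true(all(unlist(m[c("avg_degree_centrality", "transitivity",
                               "avg_closeness", "avg_betweenness", "density")]) >= 0))
    expect_true(all(unlist(m[c("avg_degree_centrality", "transitivity",
                               "avg_closeness", "avg_betweenness", "density")]) <= 1))
    expect_lte(m$n_edges, m$n_nodes * (m$n_nodes - 1) / 2)
  }
})
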