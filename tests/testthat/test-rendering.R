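three_feature_matrix <- function() {
  corr_from_edges(c("f1", "f2", "f3"),
                  list(list("f1", "f2", 0.9), list("f1", "f3", 0.5),
                       list("f2", "f3", -0.85)))
}

star_matrix <- function() {
  corr_from_edges(c("h", "l1", "l2", "l3", "l4"),
                  list(list("h", "l1", 0.9), list("h", "l2", 0.85),
                       list("h", "l3", 0.95), list("h", "l4", 0.82)))
}

svg_counts <- function(path) {
  skip_if_not_installed("xml2")
  doc <- xml2::read_xml(path)
  groups <- xml2::xml_find_all(doc, "//*[local-name()='g']")
  cls <- xml2::xml_attr(groups, "class")
  list(
    edges = length(xml2::xml_find_all(groups[cls == "edges"], ".//*[local-name()='line']")),
    nodes = length(xml2::xml_find_all(groups[cls == "nodes"], ".//*[local-name()='circle']")),
    legend = length(xml2::xml_find_all(groups[cls == "legend"], ".//*[local-name()='text']"))
  )
}

test_that("building from a list equals thresholding the average matrix", {
  m1 <- three_feature_matrix()
  m2 <- three_feature_matrix()
  g_list <- build_network_graph(list(m1, m2), threshold = 0.8)
  g_avg <- threshold_graph(average_correlation(list(m1, m2)), 0.8)
  expect_equal(g_list$edges, g_avg$edges)
  expect_equal(g_list$nodes, g_avg$nodes)
})

test_that("negative mode draws the single anticorrelated pair in red", {
  path <- withr::local_tempfile(fileext = ".svg")
  g <- build_network_graph(three_feature_matrix(), threshold = 0.8,
                           mode = "negative", path = path)
  expect_equal(nrow(g$edges), 1L)
  skip_if_not_installed("xml2")
  doc <- xml2::read_xml(path)
  lines <- xml2::xml_find_all(doc, "//*[local-name()='g'][@class='edges']/*[local-name()='line']")
  expect_length(lines, 1L)
  expect_equal(xml2::xml_attr(lines, "stroke"), "red")
})

test_that("a degree cap removes hubs and then newly isolated nodes", {
  path_m <- corr_from_edges(c("a", "b", "c"),
                            list(list("a", "b", 0.9), list("b", "c", 0.9)))
  g <- build_network_graph(path_m, threshold = 0.8, max_degree = 1)
  expect_length(g$nodes, 0L)
  expect_equal(nrow(g$edges), 0L)

  svg <- withr::local_tempfile(fileext = ".svg")
  build_network_graph(path_m, threshold = 0.8, max_degree = 1, path = svg)
  counts <- svg_counts(svg)
  expect_equal(counts$edges, 0L)
  expect_equal(counts$nodes, 0L)
  expect_equal(counts$legend, 2L)
})

test_that("rendered element counts match the graph and rendering is byte-stable", {
  ft <- generate_feature_table(synthetic_design(seed = 77))
  mats <- correlation_matrix(bootstrap_replicates(ft, iterations = 10, seed = 6))
  p1 <- withr::local_tempfile(fileext = ".svg")
  p2 <- withr::local_tempfile(fileext = ".svg")
  g <- build_network_graph(mats, threshold = 0.8, path = p1)
  build_network_graph(mats, threshold = 0.8, path = p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))
  counts <- svg_counts(p1)
  expect_equal(counts$edges, nrow(g$edges))
  expect_equal(counts$nodes, length(g$nodes))

  p3 <- withr::local_tempfile(fileext = ".svg")
  build_network_graph(mats, threshold = 0.8, path = p3,
                      spec = render_spec(layout_seed = 7L))
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("top_nodes ranks by degree with a label tie-break and truncates", {
  g <- threshold_graph(star_matrix(), 0.8)
  top2 <- top_nodes(g, 2)
  expect_equal(top2$node, c("h", "l1"))
  expect_equal(top2$degree, c(4L, 1L))
  expect_equal(nrow(top_nodes(g, 50)), 5L)

  empty <- threshold_graph(corr_from_edges(c("x", "y"), list(list("x", "y", 0.1))), 0.8)
  expect_equal(nrow(top_nodes(empty, 3)), 0L)
})

test_that("most_connected_nodes returns the hub and breaks ties lexicographically", {
  g <- threshold_graph(star_matrix(), 0.8)
  expect_equal(most_connected_nodes(g), tibble::tibble(node = "h", degree = 4L))

  pair <- threshold_graph(corr_from_edges(c("b", "a"), list(list("b", "a", 0.9))), 0.8)
  expect_equal(most_connected_nodes(pair)$node, "a")

  empty <- threshold_graph(corr_from_edges(c("x", "y"), list(list("x", "y", 0.1))), 0.8)
  expect_error(most_connected_nodes(empty), "no nodes")
})

test_that("nodes_edges_table satisfies the handshake lemma", {
  tri <- corr_from_edges(letters[1:3],
                         list(list("a", "b", 0.9), list("a", "c", 0.9), list("b", "c", 0.9)))
  g <- threshold_graph(tri, 0.8)
  tab <- nodes_edges_table(g)
  expect_equal(tab$n_edges, c(2L, 2L, 2L))
  expect_equal(sum(tab$n_edges), 2L * nrow(g$edges))

  path_g <- threshold_graph(corr_from_edges(letters[1:3],
                            list(list("a", "b", 0.9), list("b", "c", 0.9))), 0.8)
  expect_equal(nodes_edges_table(path_g)$n_edges, c(1L, 2L, 1L))

  empty <- threshold_graph(corr_from_edges(c("x", "y"), list(list("x", "y", 0.1))), 0.8)
  expect_equal(nrow(nodes_edges_table(empty)), 0L)
})

test_that("the top-k subnetwork is the induced subgraph on the top nodes", {
  m <- star_matrix()
  full <- threshold_graph(m, 0.8)
  all_kept <- top_nodes_network_graph(m, threshold = 0.8, k = 10)
  expect_equal(all_kept$edges, full$edges)

  only_hub <- top_nodes_network_graph(m, threshold = 0.8, k = 1)
  expect_equal(only_hub$nodes, "h")
  expect_equal(nrow(only_hub$edges), 0L)

  hub_and_leaf <- top_nodes_network_graph(m, threshold = 0.8, k = 2)
  expect_equal(nrow(hub_and_leaf$edges), 1L)
  expect_setequal(c(hub_and_leaf$edges$from, hub_and_leaf$edges$to), c("h", "l1"))
})

test_that("plot builders return ggplot objects", {
  set.seed(9)
  ft <- generate_feature_table(synthetic_design(seed = 9))
  stats <- calculate_network_statistics(
    correlation_matrix(bootstrap_replicates(ft, iterations = 12, seed = 2)))
  expect_s3_class(ggplot2::autoplot(stats), "ggplot")
  expect_s3_class(plot_metric_boxplot(list(a = stats, b = stats), "n_edges"), "ggplot")
  expect_error(plot_metric_boxplot(list(a = stats), "nope"), "Unknown metric")
  cmp <- net_stat_binomial_test(stats, stats[sample(nrow(stats)), ])
  expect_s3_class(ggplot2::autoplot(cmp), "ggplot")
})
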