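#' Rendering specification for signed-network drawings
#'
#' Colors follow the package convention: sky-blue nodes, blue positive
#' edges, red negative edges. Edge width grows linearly with the
#' correlation magnitude from `width_range[1]` at |r| = threshold to
#' `width_range[2]` at |r| = 1. The force-directed layout is seeded so a
#' given (graph, spec) pair always produces identical geometry.
#'
#' @param node_color,positive_edge_color,negative_edge_color CSS colors.
#' @param width_range Length-2 numeric: minimum and maximum edge stroke
#'   width in px.
#' @param layout_seed Integer seed for the layout (default 42).
#' @param width,height Canvas size in px.
#' @return A `render_spec` list.
#' @export
render_spec <- function(node_color = "skyblue",
                        positive_edge_color = "blue",
                        negative_edge_color = "red",
                        width_range = c(0.5, 4),
                        layout_seed = 42L,
                        width = 640, height = 640) {
  structure(
    list(node_color = node_color, positive_edge_color = positive_edge_color,
         negative_edge_color = negative_edge_color, width_range = width_range,
         layout_seed = as.integer(layout_seed), width = width, height = height),
    class = "render_spec"
  )
}

#' Build (and optionally render) a thresholded network
#'
#' Averages the correlation matrices if several are given, thresholds at
#' the requested mode, optionally removes hub nodes whose degree (computed
#' on the unfiltered graph) exceeds `max_degree` — dropping any nodes left
#' isolated by that pruning — and writes a signed SVG drawing with a
#' positive/negative legend.
#'
#' @param matrices One correlation matrix or a list of them (averaged
#'   first).
#' @inheritParams threshold_graph
#' @param max_degree Optional degree cap: nodes with pre-filter degree
#'   above it are removed, then newly isolated nodes are dropped.
#' @param path Optional output SVG path; no file is written when `NULL`.
#' @param spec A [render_spec()].
#' @return The `corr_network` that was (or would be) drawn, invisibly when
#'   a file is written.
#' @export
build_network_graph <- function(matrices, threshold = 0.8,
                                mode = c("both", "positive", "negative"),
                                max_degree = NULL, path = NULL,
                                spec = render_spec()) {
  mode <- match.arg(mode)
  graph <- threshold_graph(average_correlation(matrices), threshold = threshold, mode = mode)
  if (!is.null(max_degree)) {
    max_degree <- assert_count(max_degree, "max_degree", lower = 0L)
    deg <- node_degrees(graph)
    keep <- names(deg)[deg <= max_degree]
    graph <- induced_subgraph(graph, keep, drop_isolated = TRUE)
  }
  if (!is.null(path)) {
    write_network_svg(graph, path, spec)
    return(invisible(graph))
  }
  graph
}

#' Highest-degree nodes of a network
#'
#' @param graph A `corr_network`.
#' @param k Maximum number of nodes to return (default 20).
#' @return Tibble `(node, degree)` sorted by degree descending, ties broken
#'   by node label ascending; fewer than `k` rows if the graph is small.
#' @export
top_nodes <- function(graph, k = 20) {
  k <- assert_count(k, "k")
  deg <- node_degrees(graph)
  out <- tibble(node = names(deg), degree = as.integer(deg)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$node)
  utils::head(out, k)
}

#' The single most connected node
#'
#' @param graph A non-empty `corr_network`.
#' @return One-row tibble `(node, degree)`; degree ties resolve to the
#'   lexicographically smallest label.
#' @export
most_connected_nodes <- function(graph) {
  if (length(graph$nodes) == 0L) {
    abort("The graph has no nodes.")
  }
  top_nodes(graph, 1L)
}

#' Per-node edge counts
#'
#' @param graph A `corr_network`.
#' @return Tibble `(node, n_edges)` in node order; the degrees sum to twice
#'   the edge count (handshake lemma).
#' @export
nodes_edges_table <- function(graph) {
  deg <- node_degrees(graph)
  tibble(node = names(deg), n_edges = as.integer(deg))
}

#' Render the subnetwork induced by the highest-degree nodes
#'
#' Builds the full thresholded network, selects its top-`k` nodes by degree
#' (label-ascending tie-break) and draws the subgraph induced on that node
#' set. Selected nodes are kept even if the restriction leaves them
#' without edges.
#'
#' @inheritParams build_network_graph
#' @param k How many top nodes to keep (default 20).
#' @return The induced `corr_network`, invisibly when a file is written.
#' @export
top_nodes_network_graph <- function(matrices, threshold = 0.8, k = 20,
                                    mode = c("both", "positive", "negative"),
                                    path = NULL, spec = render_spec()) {
  mode <- match.arg(mode)
  full <- threshold_graph(average_correlation(matrices), threshold = threshold, mode = mode)
  keep <- top_nodes(full, k)$node
  graph <- induced_subgraph(full, keep, drop_isolated = FALSE)
  if (!is.null(path)) {
    write_network_svg(graph, path, spec)
    return(invisible(graph))
  }
  graph
}

#' Write a signed network as an SVG drawing
#'
#' Deterministic: node positions come from a seeded force-directed layout,
#' coordinates are rounded to fixed precision, and elements are emitted in
#' a fixed order, so identical (graph, spec) input yields byte-identical
#' output. Nodes are circles, edges lines colored by correlation sign with
#' stroke width proportional to |r|, plus a legend.
#'
#' @param graph A `corr_network`.
#' @param path Output path.
#' @param spec A [render_spec()].
#' @return `path`, invisibly.
#' @export
write_network_svg <- function(graph, path, spec = render_spec()) {
  n <- length(graph$nodes)
  w <- spec$width
  h <- spec$height
  margin <- 50
  pos <- fr_layout(graph, seed = spec$layout_seed)
  if (n > 0L) {
    # map layout coordinates into the canvas minus margins
    rng <- apply(pos, 2L, range)
    span <- pmax(rng[2L, ] - rng[1L, ], 1e-9)
    pos[, 1L] <- margin + (pos[, 1L] - rng[1L, 1L]) / span[1L] * (w - 2 * margin)
    pos[, 2L] <- margin + (pos[, 2L] - rng[1L, 2L]) / span[2L] * (h - 2 * margin)
  }
  fmt <- function(x) formatC(round(x, 2), format = "f", digits = 2)

  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            w, h, w, h),
    sprintf('<rect width="%d" height="%d" fill="white"/>', w, h),
    '<g class="edges">'
  )
  if (nrow(graph$edges) > 0L) {
    idx <- stats::setNames(seq_len(n), graph$nodes)
    wr <- spec$width_range
    thr <- graph$threshold
    for (i in seq_len(nrow(graph$edges))) {
      e <- graph$edges[i, ]
      width <- if (thr < 1) {
        wr[1L] + (wr[2L] - wr[1L]) * (abs(e$weight) - thr) / (1 - thr)
      } else wr[2L]
      col <- if (e$weight >= 0) spec$positive_edge_color else spec$negative_edge_color
      a <- pos[idx[[e$from]], ]
      b <- pos[idx[[e$to]], ]
      lines <- c(lines, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
        fmt(a[1L]), fmt(a[2L]), fmt(b[1L]), fmt(b[2L]), col, fmt(width)))
    }
  }
  lines <- c(lines, '</g>', '<g class="nodes">')
  if (n > 0L) {
    for (i in seq_len(n)) {
      lines <- c(lines, sprintf(
        '<circle cx="%s" cy="%s" r="9" fill="%s" stroke="black" stroke-width="0.5"/>',
        fmt(pos[i, 1L]), fmt(pos[i, 2L]), spec$node_color))
    }
  }
  lines <- c(lines, '</g>', '<g class="labels">')
  if (n > 0L) {
    for (i in seq_len(n)) {
      lines <- c(lines, sprintf(
        '<text x="%s" y="%s" font-size="8" text-anchor="middle" dy="2.5">%s</text>',
        fmt(pos[i, 1L]), fmt(pos[i, 2L]), xml_escape(graph$nodes[i])))
    }
  }
  lines <- c(lines,
    '</g>',
    '<g class="legend">',
    sprintf('<line x1="12" y1="14" x2="40" y2="14" stroke="%s" stroke-width="2"/>',
            spec$positive_edge_color),
    '<text x="46" y="17" font-size="11">positive correlation</text>',
    sprintf('<line x1="12" y1="30" x2="40" y2="30" stroke="%s" stroke-width="2"/>',
            spec$negative_edge_color),
    '<text x="46" y="33" font-size="11">negative correlation</text>',
    '</g>',
    '</svg>'
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Box plot of one bootstrapped network statistic across projects
#'
#' @param projects Named list of replicate statistics tibbles.
#' @param metric One of the seven metric names.
#' @return A ggplot object.
#' @export
plot_metric_boxplot <- function(projects, metric) {
  if (!metric %in% METRIC_NAMES) {
    abort(sprintf("Unknown metric '%s'. Choose one of: %s.",
                  metric, paste(METRIC_NAMES, collapse = ", ")))
  }
  long <- stats_long(projects) |> dplyr::filter(.data$metric == !!metric)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$project, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "skyblue") +
    ggplot2::labs(x = NULL, y = metric,
                  title = paste("Bootstrapped", metric)) +
    ggplot2::theme_minimal()
}

#' Box plots of all seven statistics across projects
#'
#' @param projects Named list of replicate statistics tibbles (as passed to
#'   [analyze_network_statistics()]).
#' @return A faceted ggplot object.
#' @export
plot_metric_boxplots <- function(projects) {
  long <- stats_long(projects) |>
    dplyr::mutate(metric = factor(.data$metric, levels = METRIC_NAMES))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$project, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "skyblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bootstrap distributions of the seven statistics for one run
#'
#' @param object A `netboot_stats` tibble from
#'   [calculate_network_statistics()].
#' @param ... Unused.
#' @return A faceted ggplot of the replicate metric distributions.
#' @method autoplot netboot_stats
#' @export
autoplot.netboot_stats <- function(object, ...) {
  plot_metric_boxplots(list(bootstrap = object))
}

#' Evidence plot for a network metric comparison
#'
#' Bars of -log10 p per metric, colored by the direction call.
#'
#' @param object A `netboot_comparison` from [net_stat_binomial_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot netboot_comparison
#' @export
autoplot.netboot_comparison <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(metric = factor(.data$metric, levels = rev(METRIC_NAMES)))
  ggplot2::ggplot(df, ggplot2::aes(x = -.data$log10_p, y = .data$metric,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(attr(object, "alpha")), linetype = 2) +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL, fill = "direction") +
    ggplot2::theme_minimal()
}

# --- internals --------------------------------------------------------------

induced_subgraph <- function(graph, keep, drop_isolated) {
  edges <- graph$edges |>
    dplyr::filter(.data$from %in% keep & .data$to %in% keep)
  nodes <- if (drop_isolated) {
    graph$nodes[graph$nodes %in% unique(c(edges$from, edges$to))]
  } else {
    graph$nodes[graph$nodes %in% keep]
  }
  structure(
    list(nodes = nodes, edges = edges, threshold = graph$threshold, mode = graph$mode),
    class = "corr_network"
  )
}

# Seeded Fruchterman–Reingold layout on the unweighted skeleton. Small
# graphs only need a modest number of sweeps; determinism matters more than
# aesthetics here.
fr_layout <- function(graph, seed = 42L, n_iter = 150L) {
  n <- length(graph$nodes)
  if (n == 0L) {
    return(matrix(numeric(), ncol = 2L))
  }
  pos <- with_seed(seed, matrix(stats::runif(2L * n, -1, 1), ncol = 2L))
  if (n == 1L) {
    return(pos)
  }
  idx <- stats::setNames(seq_len(n), graph$nodes)
  ef <- idx[graph$edges$from]
  et <- idx[graph$edges$to]
  k <- sqrt(4 / n)  # ideal spring length on a [-1,1]^2 canvas
  temp <- 0.3
  for (it in seq_len(n_iter)) {
    disp <- matrix(0, n, 2L)
    # repulsion between every pair
    dx <- outer(pos[, 1L], pos[, 1L], "-")
    dy <- outer(pos[, 2L], pos[, 2L], "-")
    d2 <- pmax(dx^2 + dy^2, 1e-8)
    rep_f <- k^2 / d2
    diag(rep_f) <- 0
    disp[, 1L] <- rowSums(dx * rep_f)
    disp[, 2L] <- rowSums(dy * rep_f)
    # attraction along edges
    if (length(ef) > 0L) {
      ex <- pos[ef, 1L] - pos[et, 1L]
      ey <- pos[ef, 2L] - pos[et, 2L]
      ed <- pmax(sqrt(ex^2 + ey^2), 1e-8)
      att <- ed / k
      fx <- ex / ed * att * ed
      fy <- ey / ed * att * ed
      for (j in seq_along(ef)) {
        disp[ef[j], ] <- disp[ef[j], ] - c(fx[j], fy[j])
        disp[et[j], ] <- disp[et[j], ] + c(fx[j], fy[j])
      }
    }
    len <- pmax(sqrt(rowSums(disp^2)), 1e-8)
    step <- pmin(len, temp)
    pos <- pos + disp / len * step
    temp <- temp * 0.97
  }
  pos
}

save_svg_plot <- function(plot, path, width = 6, height = 4) {
  grDevices::svg(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(plot)
  invisible(path)
}
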