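#' Plot mean attribute trajectories
#'
#' Group-mean course of every attribute over the assessment waves with
#' one-SE ribbons.
#'
#' @param trajectories output of [trajectory_summary()] (or a `dtw_network`
#'   fit, whose stored summary is used).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories) {
  if (inherits(trajectories, "dtw_network")) {
    trajectories <- trajectories$trajectories
  }
  ggplot2::ggplot(trajectories,
                  ggplot2::aes(x = .data$time, y = .data$mean,
                               color = .data$attribute,
                               fill = .data$attribute)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.15, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Assessment wave", y = "Group mean",
                  color = "Attribute", fill = "Attribute") +
    ggplot2::theme_minimal()
}

#' Plot the attribute dendrogram
#'
#' @param clusters a `warpnet_clusters` object (or a `dtw_network` fit).
#' @return A ggplot object.
#' @export
plot_dendrogram <- function(clusters) {
  if (inherits(clusters, "dtw_network")) clusters <- clusters$clusters
  tree <- clusters$hclust
  dend <- stats::as.dendrogram(tree)
  seg <- dendrogram_segments(dend)
  labs <- tibble::tibble(label = tree$labels[tree$order],
                         x = seq_along(tree$order))
  labs <- dplyr::left_join(labs, clusters$labels,
                           by = c(label = "attribute"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = .data$x, y = -0.02, label = .data$label,
                                    color = factor(.data$cluster)),
                       angle = 90, hjust = 1, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.35, 0.05))) +
    ggplot2::labs(y = "Merge height", x = NULL, color = "Dimension") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

# flatten a dendrogram into plottable line segments
dendrogram_segments <- function(dend) {
  segs <- list()
  walk <- function(node) {
    if (stats::is.leaf(node)) {
      return(list(x = attr(node, "x_pos"), y = 0))
    }
    kids <- lapply(seq_along(node), function(i) walk(node[[i]]))
    h <- attr(node, "height")
    xs <- vapply(kids, `[[`, numeric(1), "x")
    ys <- vapply(kids, `[[`, numeric(1), "y")
    for (i in seq_along(kids)) {
      segs[[length(segs) + 1]] <<- data.frame(x = xs[i], y = ys[i],
                                              xend = xs[i], yend = h)
    }
    segs[[length(segs) + 1]] <<- data.frame(x = min(xs), y = h,
                                            xend = max(xs), yend = h)
    list(x = mean(range(xs)), y = h)
  }
  # assign leaf positions in plotting order
  counter <- 0
  dend <- stats::dendrapply(dend, function(node) {
    if (stats::is.leaf(node)) {
      counter <<- counter + 1
      attr(node, "x_pos") <- counter
    }
    node
  })
  walk(dend)
  dplyr::bind_rows(segs)
}

#' Plot the undirected co-occurrence network
#'
#' Nodes on a circle, colored by dimension; edge width scales with the
#' similarity weight, edge color encodes valence agreement (green = same
#' valence, red = opposite).
#'
#' @param edges undirected edge tibble (or a `dtw_network` fit).
#' @param min_weight hide edges below this similarity weight (declutters
#'   dense networks; default 0 shows all).
#' @return A ggplot object.
#' @export
plot_network <- function(edges, min_weight = 0) {
  if (inherits(edges, "dtw_network")) edges <- edges$edges
  nodes <- tibble::tibble(
    name = unique(c(edges$from, edges$to))
  )
  cl <- dplyr::bind_rows(
    tibble::tibble(name = edges$from, cluster = edges$cluster_from),
    tibble::tibble(name = edges$to, cluster = edges$cluster_to)
  )
  nodes <- dplyr::left_join(nodes, dplyr::distinct(cl), by = "name")
  k <- nrow(nodes)
  nodes$angle <- 2 * pi * (seq_len(k) - 1) / k
  nodes$x <- cos(nodes$angle)
  nodes$y <- sin(nodes$angle)
  pos <- stats::setNames(seq_len(k), nodes$name)
  e <- dplyr::filter(edges, .data$weight >= min_weight)
  e$x <- nodes$x[pos[e$from]]; e$y <- nodes$y[pos[e$from]]
  e$xend <- nodes$x[pos[e$to]]; e$yend <- nodes$y[pos[e$to]]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = e,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$weight,
                                       color = .data$edge_color),
                          alpha = 0.7) +
    ggplot2::scale_color_identity() +
    ggplot2::scale_linewidth(range = c(0.1, 2)) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = factor(.data$cluster)),
                        size = 8, shape = 21) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = 1.18 * .data$x, y = 1.18 * .data$y,
                                    label = .data$name), size = 3) +
    ggplot2::coord_equal(xlim = c(-1.45, 1.45), ylim = c(-1.45, 1.45)) +
    ggplot2::labs(fill = "Dimension", linewidth = "Similarity") +
    ggplot2::theme_void()
}

#' Plot the directed temporal-precedence network
#'
#' Significant directed edges as arrows from leading to lagging attribute;
#' arrow width scales with the mean lead-lag contrast.
#'
#' @param directed_edges tibble from [test_directed_edges()] (or a
#'   `dtw_network` fit).
#' @param significant_only show only significant edges (default TRUE).
#' @return A ggplot object.
#' @export
plot_directed_network <- function(directed_edges, significant_only = TRUE) {
  if (inherits(directed_edges, "dtw_network")) {
    directed_edges <- directed_edges$directed_edges
  }
  e <- if (significant_only)
    dplyr::filter(directed_edges, .data$significant) else directed_edges
  nodes <- tibble::tibble(name = unique(c(directed_edges$from,
                                          directed_edges$to)))
  k <- nrow(nodes)
  nodes$angle <- 2 * pi * (seq_len(k) - 1) / k
  nodes$x <- cos(nodes$angle); nodes$y <- sin(nodes$angle)
  pos <- stats::setNames(seq_len(k), nodes$name)
  p <- ggplot2::ggplot()
  if (nrow(e) > 0) {
    e$x <- nodes$x[pos[e$from]]; e$y <- nodes$y[pos[e$from]]
    e$xend <- nodes$x[pos[e$to]]; e$yend <- nodes$y[pos[e$to]]
    # pull arrow tips short of the node marker
    e$xend <- e$x + 0.88 * (e$xend - e$x)
    e$yend <- e$y + 0.88 * (e$yend - e$y)
    p <- p + ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend,
                   linewidth = .data$mean_delta),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.18, "cm")),
      alpha = 0.8, color = "grey30")
  }
  p +
    ggplot2::scale_linewidth(range = c(0.3, 1.6)) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        size = 8, shape = 21, fill = "grey85") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = 1.18 * .data$x, y = 1.18 * .data$y,
                                    label = .data$name), size = 3) +
    ggplot2::coord_equal(xlim = c(-1.45, 1.45), ylim = c(-1.45, 1.45)) +
    ggplot2::labs(linewidth = "Mean lead-lag") +
    ggplot2::theme_void()
}

#' Forest plot of standardized strength centralities
#'
#' Point estimates with 95% confidence intervals per node, out-strength and
#' in-strength side by side; intervals wholly above zero are the
#' significant ones.
#'
#' @param strengths tibble from [strength_centrality()] (or a `dtw_network`
#'   fit).
#' @return A ggplot object.
#' @export
plot_strengths <- function(strengths) {
  if (inherits(strengths, "dtw_network")) strengths <- strengths$strengths
  ggplot2::ggplot(strengths,
                  ggplot2::aes(x = .data$estimate, y = .data$node,
                               color = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::facet_wrap(~kind) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick",
                                           `FALSE` = "grey40")) +
    ggplot2::labs(x = "Standardized strength (95% CI)", y = NULL,
                  color = "Significant") +
    ggplot2::theme_minimal()
}

#' Autoplot a fitted DTW network
#'
#' @param object a `dtw_network` fit.
#' @param type which figure to draw.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot dtw_network
#' @export
autoplot.dtw_network <- function(object,
                                 type = c("network", "dendrogram",
                                          "directed", "strengths",
                                          "trajectories"), ...) {
  type <- match.arg(type)
  switch(type,
    network = plot_network(object),
    dendrogram = plot_dendrogram(object),
    directed = plot_directed_network(object),
    strengths = plot_strengths(object),
    trajectories = plot_trajectories(object)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
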