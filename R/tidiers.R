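#' Tidy a network into an edge tibble
#'
#' @param x A `netpsy_network`.
#' @param ... Unused.
#' @return Tibble with `node_i`, `node_j`, `weight` (nonzero edges only).
#' @method tidy netpsy_network
#' @export
tidy.netpsy_network <- function(x, ...) {
  tidy_network_edges(x$weights)
}

#' One-row summary of a network
#'
#' @param x A `netpsy_network`.
#' @param ... Unused.
#' @return Tibble with node/edge counts, density, chosen penalty and EBIC
#'   hyperparameter, and the correlation method used.
#' @method glance netpsy_network
#' @export
glance.netpsy_network <- function(x, ...) {
  p <- length(x$node_ids)
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  tibble::tibble(n_nodes = p, n_edges = ne,
                 density = ne / (p * (p - 1) / 2),
                 lambda = x$lambda, gamma = x$gamma, n = x$n,
                 correlation = x$correlation)
}

#' @method tidy netpsy_partition
#' @export
tidy.netpsy_partition <- function(x, ...) {
  tibble::tibble(item = names(x$assignment),
                 community = as.integer(x$assignment))
}

#' @method glance netpsy_partition
#' @export
glance.netpsy_partition <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$assignment),
                 n_communities = length(unique(x$assignment)),
                 energy = x$energy, method = x$method, seed = x$seed)
}

#' @method tidy netpsy_loadings
#' @export
tidy.netpsy_loadings <- function(x, ...) {
  out <- tibble::as_tibble(x$standardized, rownames = "item")
  tidyr::pivot_longer(out, -"item", names_to = "community",
                      values_to = "loading")
}

#' @method tidy netpsy_uva_report
#' @export
tidy.netpsy_uva_report <- function(x, ...) {
  uva_merge_table(x)
}

#' @method glance netpsy_uva_report
#' @export
glance.netpsy_uva_report <- function(x, ...) {
  tibble::tibble(n_items_in = x$n_items_in, n_items_out = x$n_items_out,
                 n_composites = length(x$merge_map), n_rounds = x$n_rounds)
}

#' @method tidy netpsy_boot
#' @export
tidy.netpsy_boot <- function(x, ...) {
  item_stability(x)
}

#' @method glance netpsy_boot
#' @export
glance.netpsy_boot <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(B = x$B, n_items = length(x$node_ids),
                                  n_redrawn = x$n_redrawn),
                   ncomm_distribution(x))
}

#' Plot a network as a force-directed graph
#'
#' Green edges are positive partial correlations, red negative; width is
#' proportional to magnitude. Node color encodes the partition when one is
#' supplied.
#'
#' @param object A `netpsy_network`.
#' @param partition Optional partition for node coloring.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot netpsy_network
#' @export
autoplot.netpsy_network <- function(object, partition = NULL, seed = 1,
                                    ...) {
  w <- object$weights
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(item = object$node_ids, x = xy[, 1], y = xy[, 2])
  if (!is.null(partition)) {
    lab <- partition_labels(partition)
    nodes$community <- factor(lab[nodes$item])
  }
  edges <- tidy_network_edges(w)
  edges <- dplyr::mutate(edges,
    x = nodes$x[match(.data$node_i, nodes$item)],
    y = nodes$y[match(.data$node_i, nodes$item)],
    xend = nodes$x[match(.data$node_j, nodes$item)],
    yend = nodes$y[match(.data$node_j, nodes$item)],
    sign = ifelse(.data$weight > 0, "positive", "negative"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = abs(.data$weight),
                   color = .data$sign), alpha = 0.6) +
    ggplot2::scale_color_manual(values = c(positive = "#2a9d36",
                                           negative = "#d62828")) +
    ggplot2::scale_linewidth_continuous(range = c(0.2, 1.6), guide = "none")
  p <- if (is.null(partition)) {
    p + ggplot2::geom_point(data = nodes,
                            ggplot2::aes(x = .data$x, y = .data$y), size = 6,
                            color = "grey30")
  } else {
    p + ggplot2::geom_point(data = nodes,
                            ggplot2::aes(x = .data$x, y = .data$y,
                                         fill = .data$community),
                            size = 6, shape = 21, color = "grey20")
  }
  p + ggplot2::geom_text(data = nodes,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      label = .data$item), size = 2.5) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "edge sign", fill = "community")
}

#' Plot item stability
#'
#' Bar chart of per-item stability, colored by empirical community, with a
#' reference line at the conventional 0.70 threshold.
#'
#' @param object A `netpsy_boot`.
#' @param threshold Reference line position.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot netpsy_boot
#' @export
autoplot.netpsy_boot <- function(object, threshold = 0.7, ...) {
  stab <- item_stability(object)
  ggplot2::ggplot(stab,
                  ggplot2::aes(x = stats::reorder(.data$item, .data$stability),
                               y = .data$stability,
                               fill = factor(.data$empirical_community))) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "replication proportion",
                  fill = "community") +
    ggplot2::theme_minimal()
}

#' Plot a centrality metric across items
#'
#' Lollipop plot in ranked order, highlighting the `k` strongest and
#' weakest nodes.
#'
#' @param table A centrality tibble.
#' @param metric Column to plot.
#' @param k Number of nodes to highlight at each end.
#' @return A ggplot.
#' @export
plot_centrality <- function(table, metric = "strength", k = 5) {
  tb <- top_bottom_nodes(table, metric = metric, k = k)
  df <- dplyr::mutate(table, group = dplyr::case_when(
    .data$item %in% tb$top$item ~ "top",
    .data$item %in% tb$bottom$item ~ "bottom",
    TRUE ~ "mid"))
  ggplot2::ggplot(df,
                  ggplot2::aes(x = .data[[metric]],
                               y = stats::reorder(.data$item,
                                                  .data[[metric]]),
                               color = .data$group)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = stats::reorder(
      .data$item, .data[[metric]]))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_manual(values = c(top = "#2a9d36",
                                           bottom = "#d62828",
                                           mid = "grey50"), guide = "none") +
    ggplot2::labs(x = metric, y = NULL) +
    ggplot2::theme_minimal()
}
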