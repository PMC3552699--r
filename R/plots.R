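#' Heatmap of a subtype distance matrix
#'
#' @param object A `"subtype_dist"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot subtype_dist
#' @export
autoplot.subtype_dist <- function(object, ...) {
  df <- tidy(object)
  df2 <- tibble::tibble(label_a = df$label_b, label_b = df$label_a,
                        distance = df$distance, metric = df$metric)
  labs <- rownames(object)
  diag_df <- tibble::tibble(label_a = labs, label_b = labs, distance = 0,
                            metric = df$metric[1])
  full <- dplyr::bind_rows(df, df2, diag_df)
  full$label_a <- factor(full$label_a, levels = labs)
  full$label_b <- factor(full$label_b, levels = labs)
  ggplot2::ggplot(full, ggplot2::aes(x = .data$label_a, y = .data$label_b,
                                     fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "distance",
                  title = paste0("Subtype distances (",
                                 attr(object, "metric"), ")")) +
    ggplot2::theme_minimal()
}

#' Dendrogram-style segment plot of a merge tree
#'
#' @param object A `"merge_tree"`.
#' @param ... Unused.
#' @return A ggplot drawing the agglomeration as horizontal merge bars.
#' @method autoplot merge_tree
#' @export
autoplot.merge_tree <- function(object, ...) {
  hc <- object$hclust
  dend <- stats::as.dendrogram(hc)
  xy <- dendro_segments(dend)
  ggplot2::ggplot(xy) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_along(hc$labels[hc$order]),
                                labels = hc$labels[hc$order]) +
    ggplot2::labs(x = NULL, y = "merge height",
                  title = paste0("Hierarchical clustering (", object$linkage,
                                 " linkage)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

# flatten a dendrogram into plottable segments
dendro_segments <- function(d) {
  segs <- list()
  walk <- function(node) {
    if (stats::is.leaf(node)) {
      return(list(x = attr(node, "x_pos"), h = 0))
    }
    left <- walk(node[[1]]); right <- walk(node[[2]])
    h <- attr(node, "height")
    segs[[length(segs) + 1]] <<- data.frame(
      x = c(left$x, right$x, left$x),
      y = c(left$h, right$h, h),
      xend = c(left$x, right$x, right$x),
      yend = c(h, h, h))
    list(x = (left$x + right$x) / 2, h = h)
  }
  counter <- 0
  d <- stats::dendrapply(d, function(n) {
    if (stats::is.leaf(n)) {
      counter <<- counter + 1
      attr(n, "x_pos") <- counter
    }
    n
  })
  walk(d)
  do.call(rbind, segs)
}

#' Plot a pathway association network
#'
#' Fruchterman-Reingold layout; node size maps to pathway protein count,
#' node color to changed-protein count, edge width to Jaccard similarity.
#'
#' @param g An igraph pathway network from [build_pathway_network()].
#' @param seed Layout seed.
#' @return A ggplot.
#' @export
plot_pathway_network <- function(g, seed = 1L) {
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble::tibble(
    name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
    protein_count = igraph::V(g)$protein_count,
    changed_count = igraph::V(g)$changed_count
  )
  el <- igraph::as_edgelist(g)
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(el)) {
    edges <- tibble::tibble(
      x = nodes$x[match(el[, 1], nodes$name)],
      y = nodes$y[match(el[, 1], nodes$name)],
      xend = nodes$x[match(el[, 2], nodes$name)],
      yend = nodes$y[match(el[, 2], nodes$name)],
      jaccard = igraph::E(g)$jaccard
    )
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$jaccard),
      color = "grey60")
  }
  p +
    ggplot2::geom_point(ggplot2::aes(size = .data$protein_count,
                                     color = .data$changed_count)) +
    ggplot2::scale_color_viridis_c() +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::labs(title = paste("Pathway association network,",
                                igraph::graph_attr(g, "subtype")),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
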