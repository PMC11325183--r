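#' Plot a conformation tree
#'
#' Dendrogram-style rendering: the vertical axis is the DBSCAN radius
#' epsilon, each node is a vertical segment spanning the radii over which it
#' exists as a distinct cluster, and children attach to their parent at the
#' parent's birth radius. Dense clusters (deep wells) therefore hang lowest;
#' the root sits at the top. Node colours come from an optional annotation.
#'
#' @param object A `conf_tree`.
#' @param annotation Optional `node_annotation` tibble from
#'   [annotate_tree()]; rendered via [node_color_mix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.conf_tree <- function(object, annotation = NULL, ...) {
  nd <- object$nodes
  kids_of <- split(nd$node_id[!is.na(nd$parent_id)],
                   nd$parent_id[!is.na(nd$parent_id)])
  roots <- nd$node_id[is.na(nd$parent_id)]
  xpos <- stats::setNames(rep(NA_real_, nrow(nd)), nd$node_id)
  leaf_x <- 0
  assign_x <- function(id) {
    kids <- kids_of[[as.character(id)]]
    if (is.null(kids) || !length(kids)) {
      leaf_x <<- leaf_x + 1
      xpos[as.character(id)] <<- leaf_x
    } else {
      for (k in kids) assign_x(k)
      xpos[as.character(id)] <<- mean(xpos[as.character(kids)])
    }
  }
  for (r in roots) assign_x(r)

  i_par <- match(nd$parent_id, nd$node_id)
  seg <- tibble::tibble(
    node_id = nd$node_id,
    x = unname(xpos[as.character(nd$node_id)]),
    y0 = nd$eps_first,
    y1 = ifelse(is.na(i_par), nd$eps_last, nd$eps_first[i_par]),
    color = "#555555"
  )
  if (!is.null(annotation)) {
    mixed <- node_color_mix(annotation)
    j <- match(seg$node_id, mixed$node_id)
    seg$color[!is.na(j)] <- mixed$color[j[!is.na(j)]]
  }
  conn <- dplyr::filter(
    tibble::tibble(
      xp = unname(xpos[as.character(nd$parent_id)]),
      x = seg$x,
      y = seg$y1
    ),
    !is.na(.data$xp)
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = conn,
      ggplot2::aes(x = .data$x, xend = .data$xp, y = .data$y,
                   yend = .data$y),
      colour = "grey60") +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$x, y = .data$y0,
                   yend = .data$y1, colour = I(.data$color)),
      linewidth = 1.2) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = expression(epsilon ~ "(cluster radius)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Scatter plot of projected frames
#'
#' @param projected A `projected_ensemble` tibble.
#' @param x,y Component columns to show (defaults `pc1`, `pc2`).
#' @param color_by Optional column name used for point colour (e.g.
#'   `source_id` or a joined label).
#' @return A ggplot object.
#' @export
plot_projection <- function(projected, x = "pc1", y = "pc2",
                            color_by = NULL) {
  stopifnot(all(c(x, y) %in% names(projected)))
  p <- ggplot2::ggplot(projected,
                       ggplot2::aes(.data[[x]], .data[[y]])) +
    ggplot2::labs(x = x, y = y) +
    ggplot2::theme_minimal()
  if (is.null(color_by)) {
    p + ggplot2::geom_point(alpha = 0.6, size = 0.8)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[color_by]]),
                            alpha = 0.6, size = 0.8)
  }
}

#' Scree plot of a PCA model
#'
#' @param object A `conf_pca`.
#' @param ... Unused.
#' @return A ggplot object showing per-component explained variance ratio.
#' @exportS3Method ggplot2::autoplot
autoplot.conf_pca <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$component, .data$explained)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative), colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative), colour = "grey30") +
    ggplot2::labs(x = "principal component",
                  y = "explained variance ratio") +
    ggplot2::theme_minimal()
}
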