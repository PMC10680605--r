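# ggplot2 rendering of tissues, heat maps, growth axes and fitted objects.
# Values outside a heat map's render range are clipped at display time only.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @noRd
snapshot_polygons <- function(snapshot) {
  dplyr::bind_rows(lapply(snapshot$cells, function(c) {
    tibble::tibble(label = c$label, x = c$vertices[, 1], y = c$vertices[, 2])
  }))
}

#' Render a tissue snapshot, optionally painted with a heat map
#'
#' @param object A [tissue_snapshot()].
#' @param heat Optional [heatmap_tbl()]; its `render_range` sets the fill
#'   limits and out-of-range values are clipped to the range ends.
#' @param outline Optional integer labels to outline (e.g. division
#'   products from [division_outlines()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tissue_snapshot <- function(object, heat = NULL, outline = NULL,
                                     ...) {
  poly <- snapshot_polygons(object)
  p <- ggplot2::ggplot(poly, ggplot2::aes(.data$x, .data$y,
                                          group = .data$label))
  if (is.null(heat)) {
    p <- p + ggplot2::geom_polygon(fill = "grey85", colour = "grey30",
                                   linewidth = 0.2)
  } else {
    rng <- attr(heat, "render_range")
    poly2 <- dplyr::left_join(poly, heat, by = "label")
    poly2$value <- pmin(pmax(poly2$value, rng[1]), rng[2])
    p <- ggplot2::ggplot(poly2, ggplot2::aes(.data$x, .data$y,
                                             group = .data$label,
                                             fill = .data$value)) +
      ggplot2::geom_polygon(colour = "grey20", linewidth = 0.2) +
      ggplot2::scale_fill_viridis_c(limits = rng,
                                    name = attr(heat, "quantity"))
  }
  if (!is.null(outline)) {
    sel <- poly[poly$label %in% outline, ]
    p <- p + ggplot2::geom_polygon(data = sel, fill = NA, colour = "white",
                                   linewidth = 0.7)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = paste0("t = ", object$time_h, " h")) +
    ggplot2::theme_minimal()
}

#' Overlay principal growth directions on a snapshot plot
#'
#' Draws, for each fitted lineage, a black line through the cell centroid
#' oriented along the principal direction of growth with length
#' proportional to the anisotropy ratio s1/s2.
#'
#' @param snapshot The snapshot whose labels key the tensors (the earlier
#'   time point for cumulative spans).
#' @param tensors Tibble from [growth_tensors()].
#' @param heat Optional [heatmap_tbl()] to paint underneath.
#' @param scale Line length per unit anisotropy, in um (default 4).
#' @return A ggplot object.
#' @export
plot_growth_axes <- function(snapshot, tensors, heat = NULL, scale = 4) {
  p <- autoplot.tissue_snapshot(snapshot, heat = heat)
  cen <- cell_centroids(snapshot)
  tb <- dplyr::inner_join(tensors, cen, by = "label")
  tb$len <- scale * tb$anisotropy
  seg <- tibble::tibble(
    x = tb$x - cos(tb$theta_max) * tb$len / 2,
    xend = tb$x + cos(tb$theta_max) * tb$len / 2,
    y = tb$y - sin(tb$theta_max) * tb$len / 2,
    yend = tb$y + sin(tb$theta_max) * tb$len / 2
  )
  p + ggplot2::geom_segment(
    data = seg,
    ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                 yend = .data$yend),
    inherit.aes = FALSE, colour = "black", linewidth = 0.8)
}

#' @describeIn pcoa Scatter plot of the first two principal coordinates.
#' @param object A `pcoa_fit`.
#' @export
autoplot.pcoa_fit <- function(object, ...) {
  pts <- object$points
  ev <- object$eigenvalues
  rel <- 100 * ev[1:2] / sum(ev[ev > 0])
  ggplot2::ggplot(pts, ggplot2::aes(.data$axis1, .data$axis2)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", rel[1]),
                  y = sprintf("PCo2 (%.1f%%)", rel[2])) +
    ggplot2::theme_minimal()
}

#' @describeIn shape_variability Aligned contours with the mean shape.
#' @param object A `shape_variability` object.
#' @export
autoplot.shape_variability <- function(object, ...) {
  ms <- object$mean_shape
  tb <- dplyr::bind_rows(lapply(seq_along(ms$aligned), function(i) {
    v <- ms$aligned[[i]]
    tibble::tibble(contour = i, x = v[, 1], y = v[, 2])
  }))
  mn <- tibble::tibble(x = ms$mean[, 1], y = ms$mean[, 2])
  ggplot2::ggplot(tb, ggplot2::aes(.data$x, .data$y, group = .data$contour)) +
    ggplot2::geom_path(colour = "red", alpha = 0.4, linewidth = 0.3) +
    ggplot2::geom_path(data = rbind(mn, mn[1, ]),
                       ggplot2::aes(group = NULL), colour = "black",
                       linewidth = 0.8) +
    ggplot2::coord_equal() + ggplot2::theme_void()
}
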