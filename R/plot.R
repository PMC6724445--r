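#' Overlay plot of a registration result
#'
#' Plots the 2D centerline mask in grey with the registered, projected 3D
#' centerline on top, colored by depth along the viewing axis (blue =
#' shallow, toward the source; red = deep), the standard fusion display for
#' guidance.
#'
#' @param object a `registration_result`
#' @param point_size plotted point size
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.registration_result <- function(object, point_size = 0.4, ...) {
  px <- as.data.frame(mask_pixels(object$centerline$mask))
  proj <- object$projected
  ggplot2::ggplot() +
    ggplot2::geom_point(data = px, ggplot2::aes(x = .data$x, y = .data$y),
                        color = "grey70", size = point_size) +
    ggplot2::geom_point(data = proj,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$depth),
                        size = point_size) +
    ggplot2::scale_color_gradient(low = "blue", high = "red",
                                  name = "depth (mm)") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("registered overlay, AADD %.3g mm",
                                  object$final_aadd)) +
    ggplot2::theme_minimal()
}

#' Plot a local distance map
#'
#' @param object a `local_distance_map`
#' @param ... unused
#' @return a ggplot raster of the capped distance field with the source
#'   centerline visible as the zero set
#' @export
autoplot.local_distance_map <- function(object, ...) {
  d <- expand.grid(x = seq_len(ncol(object$grid)) - 1L,
                   y = seq_len(nrow(object$grid)) - 1L)
  d$dist <- as.vector(t(object$grid))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$dist)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = sprintf("distance (%s)", object$unit)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot the importance weighting of a vessel tree
#'
#' Projects the tree orthographically onto the first two patient axes and
#' colors points by their importance value, mirroring the anatomical
#' weighting display (proximal main branch bright, inactive sub-branches at
#' the floor value).
#'
#' @param object a `vessel_tree` with importance assigned
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.vessel_tree <- function(object, ...) {
  d <- object$points
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  color = .data$alpha)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::scale_color_viridis_c(name = "importance", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
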