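# ggplot2 display helpers for the package's image-like objects and
# fitted pipelines.

raster_df <- function(m) {
  tibble::tibble(
    y = rep(0:(nrow(m) - 1), times = ncol(m)),
    x = rep(0:(ncol(m) - 1), each = nrow(m)),
    value = as.vector(m))
}

img_theme <- function() {
  ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a phosphene frame, activation map, or coverage heatmap
#'
#' @param x The object to display.
#' @param ... Ignored.
#' @return A ggplot object (y axis pointing down, image convention).
#' @export
plot_frame <- function(x, ...) {
  m <- if (inherits(x, "spv_screen_frame")) x$pixels else unclass(x)
  ggplot2::ggplot(raster_df(m), ggplot2::aes(.data$x, .data$y,
                                             fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    img_theme()
}

#' @rdname plot_frame
#' @export
plot_activation_map <- function(x, ...) {
  m <- if (inherits(x, "spv_activation_map")) x$values else x
  plot_frame(m)
}

#' @rdname plot_frame
#' @export
plot_coverage_heatmap <- function(x, ...) {
  df <- raster_df(unclass(x))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "coverage") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot a synthetic scene and its mask outline
#'
#' @param scene An `spv_scene`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_scene <- function(scene, ...) {
  H <- nrow(scene$mask)
  W <- ncol(scene$mask)
  df <- raster_df(scene$mask)
  df$r <- as.vector(scene$image[, , 1])
  df$g <- as.vector(scene$image[, , 2])
  df$b <- as.vector(scene$image[, , 3])
  df$col <- grDevices::rgb(df$r, df$g, df$b)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$col)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::ggtitle(paste0(scene$scene_id, " (class ", scene$label, ")"))
}

#' Training curves of a fitted pipeline
#'
#' Loss components and validation accuracy per epoch.
#'
#' @param object A `pointspv_fit`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot pointspv_fit
#' @export
autoplot.pointspv_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$records,
                              c("L_P", "L_CE", "L", "val_accuracy"),
                              names_to = "series")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
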