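# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot enhancement curves
#'
#' Overlays voxel time courses from one or more reconstructions; feed it
#' the output of [extract_curves()] (optionally row-bound with a
#' `method` column).
#'
#' @param curves Tibble with `time`, `value` (or `pse`) and `voxel`
#'   columns; an optional `method` column maps to color.
#' @param y Column to plot: `"value"` or `"pse"`.
#' @return A ggplot object.
#' @export
plot_enhancement_curves <- function(curves, y = c("value", "pse")) {
  y <- match.arg(y)
  aes <- if ("method" %in% names(curves)) {
    ggplot2::aes(x = .data$time, y = .data[[y]],
                 group = interaction(.data$voxel, .data$method),
                 color = .data$method)
  } else {
    ggplot2::aes(x = .data$time, y = .data[[y]], group = .data$voxel)
  }
  ggplot2::ggplot(curves, aes) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "time (s)",
                  y = if (y == "pse") "percent signal enhancement (%)" else "signal (a.u.)")
}

#' @method autoplot image_series
#' @export
autoplot.image_series <- function(object, frame = 1, slice = NULL, ...) {
  gs <- object$grid_shape
  if (is.null(slice)) slice <- max(1L, gs[3] %/% 2L)
  m <- series_matrix(object)[, frame]
  vol <- array(m, gs)
  df <- expand.grid(x = seq_len(gs[1]), y = seq_len(gs[2]))
  df$value <- as.vector(vol[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = sprintf("frame %d (t = %.2f s), slice z = %d",
                                  frame, object$times[frame], slice))
}

#' @method autoplot error_ratio
#' @export
autoplot.error_ratio <- function(object, ...) {
  df <- tibble::tibble(ratio = object$ratios)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(bins = 50) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = object$median, color = "red") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "per-voxel error ratio (A / B)", y = "voxels")
}

#' @method autoplot emm_fit
#' @export
autoplot.emm_fit <- function(object, ...) {
  d <- object$data
  fmod <- emm_pse_model(object$model)
  grid <- tibble::tibble(time = seq(min(d$time), max(d$time), length.out = 400))
  grid$pse <- fmod(grid$time, object$A, object$alpha, object$t0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$pse)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, color = "red") +
    ggplot2::labs(x = "time (s)", y = "PSE (%)")
}
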