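# ggplot2 figures for angle samples and pipeline results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of dominant-orientation angles
#'
#' Frequency distribution over (-90, 90] with the circular mean marked,
#' one facet per group. This is the standard summary figure for a
#' chirality assay: a negative mean line indicates clockwise (CW)
#' alignment, positive counterclockwise (CCW).
#'
#' @param data A data frame with a `theta_deg` column and (optionally) a
#'   `group` column, e.g. the `angles` table of a [run_image_pipeline()]
#'   result.
#' @param bin_width Bin width in degrees (must divide 180), default 10.
#' @return A ggplot object.
#' @export
plot_angle_histogram <- function(data, bin_width = 10) {
  stopifnot("theta_deg" %in% names(data))
  freq <- angle_frequency(data, bin_width = bin_width)
  summ <- summarize_angles(data)
  has_groups <- "group" %in% names(freq)
  p <- ggplot2::ggplot(freq, ggplot2::aes(x = bin_mid, y = count)) +
    ggplot2::geom_col(width = bin_width, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(data = summ, ggplot2::aes(xintercept = mean_deg),
                        colour = "red", linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::scale_x_continuous(breaks = seq(-90, 90, 30)) +
    ggplot2::labs(x = "dominant orientation (degrees)", y = "rectangles",
                  title = "Dominant-orientation distribution",
                  subtitle = "red = circular mean; negative mean = CW chirality") +
    ggplot2::theme_minimal()
  if (has_groups) p <- p + ggplot2::facet_wrap(~group)
  p
}

#' @rdname plot_angle_histogram
#' @param object A `chirality_run` from [run_image_pipeline()].
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.chirality_run <- function(object, bin_width = 10, ...) {
  if (is.null(object$summary) || nrow(object$angles) == 0) {
    stop("no included rectangles: nothing to plot", call. = FALSE)
  }
  plot_angle_histogram(object$angles, bin_width = bin_width)
}

#' Render a per-pixel orientation map
#'
#' QC figure for [orientation_map()]: a raster coloured with a cyclic
#' (180-degree periodic) hue scale.
#'
#' @param theta_map Matrix of angles from [orientation_map()].
#' @return A ggplot object.
#' @export
plot_orientation_map <- function(theta_map) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(theta_map)), times = ncol(theta_map)),
    col = rep(seq_len(ncol(theta_map)), each = nrow(theta_map)),
    theta = as.vector(theta_map))
  cyc <- grDevices::hsv(h = seq(0, 1, length.out = 19))
  ggplot2::ggplot(df, ggplot2::aes(col, -row, fill = theta)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = cyc, limits = c(-90, 90),
                                  na.value = "black",
                                  name = "angle (deg)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, title = "Local orientation map") +
    ggplot2::theme_void()
}
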