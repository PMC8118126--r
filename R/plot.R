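# QC visualizations (ggplot2).

#' Overlay the estimated midline on a slice
#'
#' @param vol a [flair_volume()].
#' @param result a `midline_result`.
#' @param slice slice index (default: middle slice).
#' @return a ggplot object.
#' @export
plot_midline_overlay <- function(vol, result, slice = NULL) {
  d <- dim(vol$data)
  if (is.null(slice)) slice <- (d[1] + 1L) %/% 2L
  img <- vol$data[slice, , ]
  df <- data.frame(row = rep(seq_len(d[2]), d[3]),
                   col = rep(seq_len(d[3]), each = d[2]),
                   intensity = as.vector(img))
  pts <- result$native_points[[slice]]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("slice %d (theta = %.1f deg)", slice, result$theta_used),
                  x = "column", y = "row", fill = "I") +
    ggplot2::theme_minimal()
  if (!is.null(pts)) {
    p <- p + ggplot2::geom_path(data = data.frame(row = pts[, 1], col = pts[, 2]),
                                color = "red", linewidth = 0.6)
  }
  p
}

#' Score curve of a head-angle estimate
#'
#' @param object a `head_angle`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.head_angle <- function(object, ...) {
  df <- data.frame(theta = object$grid, score = object$score)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$theta_hat, color = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "candidate angle (deg)",
                  y = "normalized cross-correlation",
                  title = sprintf("head angle estimate: %.1f deg", object$theta_hat)) +
    ggplot2::theme_minimal()
}

#' Cohort asymmetry-index QC plot
#'
#' @param records QC tibble from [flag_outliers()] / [cohort_asymmetry()].
#' @param z_cut the flagging cut-off to draw.
#' @return a ggplot object.
#' @export
plot_cohort_qc <- function(records, z_cut = 3) {
  df <- as.data.frame(records)
  df$idx <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$z,
                                   color = .data$flagged)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = z_cut, linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    ggplot2::labs(x = "subject", y = "asymmetry-index z-score") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @keywords internal
NULL
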