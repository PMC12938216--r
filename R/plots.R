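#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a flow curve
#'
#' @param object A `flow_curve`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot flow_curve
#' @export
autoplot.flow_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_ms / 1000,
                                       y = .data$q_ml_s)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "flow (mL/s)",
                  title = sprintf("%s flow curve", object$vessel[1])) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' @param object A `bland_altman` result.
#' @param ... Ignored.
#' @return A ggplot with bias (solid) and limits of agreement (dotted).
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tibble::tibble(mean = object$means, diff = object$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dotted") +
    ggplot2::labs(x = "mean of methods", y = "difference",
                  title = sprintf("Bland-Altman (bias %.3g, LOA [%.3g, %.3g])",
                                  object$bias, object$loa_low,
                                  object$loa_high)) +
    ggplot2::theme_minimal()
}

#' Plot one frame of a velocity series
#'
#' @param vs A `velocity_series`.
#' @param frame Frame index.
#' @return A ggplot raster of the velocity map (cm/s).
#' @export
plot_velocity_frame <- function(vs, frame = 1) {
  stopifnot(inherits(vs, "velocity_series"))
  v <- vs$v[, , frame]
  df <- expand.grid(x = seq_len(nrow(v)), y = seq_len(ncol(v)))
  df$v <- as.vector(v)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "grey95",
                                  high = "#a50026", name = "cm/s") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("velocity, frame %d (t = %.0f ms)", frame,
                                  vs$frame_times_ms[frame])) +
    ggplot2::theme_void()
}
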