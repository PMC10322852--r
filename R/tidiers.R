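# broom-style tidiers and ggplot2 autoplot methods for the package's result
# objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a detection report
#'
#' @param x A `detection_report`.
#' @param ... Unused.
#' @return Per-cell tibble: `id`, `depth_um`, `detected`, `first_face`,
#'   `last_face`.
#' @export
tidy.detection_report <- function(x, ...) {
  x$cells
}

#' @rdname tidy.detection_report
#' @return `glance()`: one-row tibble with `n_true`, `n_detected`,
#'   `n_missed`, `sensitivity`, `slice_thickness_um`, `threshold`,
#'   `merge_rule`.
#' @export
glance.detection_report <- function(x, ...) {
  tibble::tibble(
    n_true = x$n_true,
    n_detected = x$n_detected,
    n_missed = x$n_missed,
    sensitivity = x$sensitivity,
    slice_thickness_um = x$slice_thickness_um,
    threshold = x$threshold,
    merge_rule = x$merge_rule
  )
}

#' Tidy a log-log slope fit
#'
#' @param x A `loglog_fit` from [fit_loglog_slope()].
#' @param ... Unused.
#' @return One-row tibble with `slope`, `intercept`, `r_squared`,
#'   `n_points`, `range_lo`, `range_hi`.
#' @export
tidy.loglog_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    intercept = x$intercept,
    r_squared = x$r_squared,
    n_points = x$n_points,
    range_lo = x$thickness_range[1],
    range_hi = x$thickness_range[2]
  )
}

#' Tidy an exponential decay fit
#'
#' @param x A `decay_fit` from [estimate_attenuation()].
#' @param ... Unused.
#' @return One-row tibble with `attenuation_cm1`, `intensity_gray`,
#'   `r_squared`, `n_points`.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    attenuation_cm1 = x$attenuation_cm1,
    intensity_gray = x$intensity_gray,
    r_squared = x$r_squared,
    n_points = x$n_points
  )
}

#' Plot a sensitivity curve
#'
#' Linear-scale sensitivity against the swept quantity, or the log-log view
#' in which the sub-optimal decline of a compliant volume is a -45 degree
#' line.
#'
#' @param object A `sensitivity_curve`.
#' @param scale `"linear"` or `"loglog"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sensitivity_curve <- function(object, scale = c("linear", "loglog"), ...) {
  scale <- match.arg(scale)
  kind <- attr(object, "sweep_kind") %||% "thickness"
  xlab <- if (kind == "thickness") {
    "Slice thickness (µm)"
  } else {
    "Cell intensity (gray level)"
  }
  df <- tibble::as_tibble(object)
  if ("replicate" %in% names(df)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$sweep_value, y = .data$sensitivity,
      group = .data$replicate
    )) +
      ggplot2::geom_line(alpha = 0.4)
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$sweep_value, y = .data$sensitivity
    )) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 0.8)
  }
  p <- p +
    ggplot2::labs(x = xlab, y = "Detection sensitivity") +
    ggplot2::theme_minimal()
  if (scale == "loglog") {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a subsurface decay profile with its exponential fit
#'
#' @param profile Tibble with `depth_um`, `intensity` (see
#'   [extract_decay_profile()]).
#' @param fit Optional `decay_fit` to overlay.
#' @return A ggplot object.
#' @export
plot_decay_profile <- function(profile, fit = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(
    x = .data$depth_um, y = .data$intensity
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Depth below block-face (µm)",
      y = "Intensity (gray level)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- tibble::tibble(depth_um = seq(0, max(profile$depth_um), length.out = 100))
    grid$intensity <- fit$intensity_gray *
      exp(-fit$attenuation_cm1 * grid$depth_um / .UM_PER_CM)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}
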