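# Closed-form detection model for block-face imaging of point fluorophores.
#
# Depths and thicknesses are micrometres throughout the package; effective
# attenuation coefficients are cm^-1 as conventionally printed for tissue.
# The conversion lives in the single constant below.

.UM_PER_CM <- 1e4

#' Optical parameter triple for a fluorescent cell population
#'
#' Bundles the three composite quantities that govern detectability under
#' block-face imaging: the unattenuated cell intensity `I_fluo` (gray level),
#' the effective tissue attenuation coefficient `mu_T` (cm^-1, combining
#' excitation- and emission-side absorption and scattering), and the detector
#' threshold `T` (gray level).
#'
#' @param cell_intensity Unattenuated cell intensity, gray level (> 0).
#' @param attenuation Effective attenuation coefficient, cm^-1 (> 0).
#' @param threshold Detection threshold, gray level (> 0).
#'
#' @return An object of class `optical_params`: a named list with elements
#'   `cell_intensity`, `attenuation`, `threshold`.
#' @examples
#' op <- optical_params(30, 314, 10)
#' optimal_thickness(op$cell_intensity, op$attenuation, op$threshold)
#' @export
optical_params <- function(cell_intensity, attenuation, threshold) {
  check_positive(cell_intensity, "cell_intensity")
  check_positive(attenuation, "attenuation")
  check_positive(threshold, "threshold")
  structure(
    list(
      cell_intensity = as.numeric(cell_intensity),
      attenuation = as.numeric(attenuation),
      threshold = as.numeric(threshold)
    ),
    class = "optical_params"
  )
}

#' @export
print.optical_params <- function(x, ...) {
  cat(sprintf(
    "<optical_params> I_fluo = %g gray, mu_T = %g cm^-1, T = %g gray\n",
    x$cell_intensity, x$attenuation, x$threshold
  ))
  if (x$cell_intensity >= x$threshold) {
    cat(sprintf(
      "  X_optimal = %.2f um\n",
      optimal_thickness(x$cell_intensity, x$attenuation, x$threshold)
    ))
  } else {
    cat("  cell intensity below threshold: never detectable\n")
  }
  invisible(x)
}

#' Block-face intensity of a fluorophore at depth
#'
#' Beer-Lambert single-exponential depth attenuation: a fluorophore of
#' unattenuated intensity `I_fluo` buried `x` micrometres below the exposed
#' block-face is imaged at `I(x) = I_fluo * exp(-mu_T * x)`.
#'
#' @param cell_intensity Unattenuated intensity, gray level (> 0). Recycled.
#' @param attenuation Effective attenuation coefficient, cm^-1 (> 0). Recycled.
#' @param depth Depth below the block-face, micrometres (>= 0). Recycled.
#'
#' @return Numeric vector of gray levels in `(0, cell_intensity]`.
#' @examples
#' surface_intensity(30, 314, 35) # ~ 10 gray: at the optimal depth for T = 10
#' @export
surface_intensity <- function(cell_intensity, attenuation, depth) {
  check_positive(cell_intensity, "cell_intensity")
  check_positive(attenuation, "attenuation")
  check_non_negative(depth, "depth")
  cell_intensity * exp(-attenuation * depth / .UM_PER_CM)
}

#' Threshold detection rule
#'
#' A signal is detected when its imaged intensity reaches the detector
#' threshold; the boundary is inclusive.
#'
#' @param intensity Imaged intensity, gray level (>= 0). Recycled.
#' @param threshold Detection threshold, gray level (>= 0). Recycled.
#' @return Logical vector, `TRUE` where `intensity >= threshold`.
#' @examples
#' is_detected(c(9.999, 10, 15), 10)
#' @export
is_detected <- function(intensity, threshold) {
  check_non_negative(intensity, "intensity")
  check_non_negative(threshold, "threshold")
  intensity >= threshold
}

#' Optimal slice thickness
#'
#' The largest section thickness at which the dimmest cell in a slice (the
#' one at the slice bottom, depth `x = X`) still reaches the detection
#' threshold: `X_optimal = -ln(T / I_fluo) / mu_T`. This equals the subsurface
#' fluorescence length `e` of a single cell.
#'
#' @inheritParams optical_params
#' @return Optimal thickness in micrometres (>= 0). Vectorised.
#' @examples
#' optimal_thickness(c(30, 50, 80), 314, 10) # ~ 35, 51, 66 um
#' optimal_thickness(300, 332, 10)           # ~ 102.45 um
#' @export
optimal_thickness <- function(cell_intensity, attenuation, threshold) {
  check_positive(cell_intensity, "cell_intensity")
  check_positive(attenuation, "attenuation")
  check_positive(threshold, "threshold")
  if (any(cell_intensity < threshold)) {
    rlang::abort(
      "`cell_intensity` below `threshold`: such cells are never detectable at any thickness.",
      class = "cryosect_undetectable"
    )
  }
  -log(threshold / cell_intensity) / attenuation * .UM_PER_CM
}

#' Discretized optimal slice thickness
#'
#' The sectioning simulators place one cell per 1-um depth bin at bin centres
#' (0.5, 1.5, ... um). The thickness breakpoint they recover is therefore the
#' number of bin centres within the continuous optimal depth: the count of
#' integers `i` with `i - bin_width/2 <= X_optimal`.
#'
#' @inheritParams optical_params
#' @param bin_width Depth bin width, micrometres (default 1).
#' @return Integer thickness in micrometres.
#' @examples
#' discrete_optimal_thickness(c(30, 50, 80), 314, 10) # 35, 51, 66
#' discrete_optimal_thickness(40, 314, 10)            # 44
#' @export
discrete_optimal_thickness <- function(cell_intensity, attenuation, threshold,
                                       bin_width = 1) {
  x_opt <- optimal_thickness(cell_intensity, attenuation, threshold)
  as.integer(floor(x_opt / bin_width + 0.5))
}

#' Optimal cell intensity at a fixed slice thickness
#'
#' The minimum unattenuated intensity such that a cell at the bottom of a
#' slice of thickness `X` is still detected: `I_optimal = T * exp(mu_T * X)`.
#' Inverse of [optimal_thickness()].
#'
#' @param threshold Detection threshold, gray level (> 0).
#' @param attenuation Effective attenuation coefficient, cm^-1 (> 0).
#' @param slice_thickness Fixed slice thickness, micrometres (>= 0).
#' @return Gray level (>= threshold). Vectorised.
#' @examples
#' optimal_intensity(10, c(214, 314, 414), 20) # ~ 15.34, 18.74, 22.89 gray
#' @export
optimal_intensity <- function(threshold, attenuation, slice_thickness) {
  check_positive(threshold, "threshold")
  check_positive(attenuation, "attenuation")
  check_non_negative(slice_thickness, "slice_thickness")
  threshold * exp(attenuation * slice_thickness / .UM_PER_CM)
}

#' Piecewise sensitivity-vs-thickness relationship
#'
#' Under the compliant assumptions (homogeneous tissue, equal intensities,
#' no signal overlap, uniform cell depths) the detection sensitivity is 100%
#' up to the optimal thickness and falls off as its reciprocal beyond it:
#' `Sens(X) = 1` for `X <= X_optimal`, `X_optimal / X` otherwise.
#'
#' @param slice_thickness Slice thickness, micrometres (> 0). Recycled.
#' @param x_optimal Optimal thickness, micrometres (> 0). Recycled.
#' @return Sensitivity as a fraction in `(0, 1]`.
#' @examples
#' sensitivity_piecewise(100, 58.15) # ~ 0.58: 42% of cells lost
#' @export
sensitivity_piecewise <- function(slice_thickness, x_optimal) {
  check_positive(slice_thickness, "slice_thickness")
  check_positive(x_optimal, "x_optimal")
  pmin(1, x_optimal / slice_thickness)
}

#' Expected number of detected cells under uniform depth placement
#'
#' For `N` cells uniformly spread in depth with subsurface fluorescence
#' length `e`, sectioning at thickness `X` detects `n = ceiling((e / X) * N)`
#' cells, capped at `N` (over-sampling resolves all cells via component
#' grouping).
#'
#' @param subsurface_length Subsurface fluorescence length `e`, micrometres (> 0).
#' @param slice_thickness Slice thickness `X`, micrometres (> 0).
#' @param n_cells True number of cells `N` (> 0).
#' @return Integer count in `[0, n_cells]`. Vectorised.
#' @examples
#' expected_count(20, c(20, 40, 70), 7) # 7, 4, 2
#' @export
expected_count <- function(subsurface_length, slice_thickness, n_cells) {
  check_positive(subsurface_length, "subsurface_length")
  check_positive(slice_thickness, "slice_thickness")
  check_positive(n_cells, "n_cells")
  as.integer(pmin(n_cells, ceiling(subsurface_length / slice_thickness * n_cells)))
}

#' Under-sampling correction of an observed count
#'
#' Inverts the sensitivity relationship to estimate the true cell count from
#' a count observed at a sub-optimal thickness:
#' `Count(X_optimal) = Count(X) / Sens(X)`.
#'
#' @param observed_count Observed (detected) count (>= 0).
#' @param sensitivity Sensitivity at the thickness used, fraction in `(0, 1]`.
#' @return Real-valued estimate (not rounded); `>= observed_count`.
#' @examples
#' corrected_count(58, 0.58) # 100
#' @export
corrected_count <- function(observed_count, sensitivity) {
  check_non_negative(observed_count, "observed_count")
  if (any(sensitivity <= 0)) {
    rlang::abort("`sensitivity` must be > 0: the correction is undefined at zero sensitivity.",
      class = "cryosect_zero_sensitivity"
    )
  }
  if (any(sensitivity > 1)) {
    rlang::abort("`sensitivity` must be <= 1.")
  }
  observed_count / sensitivity
}
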