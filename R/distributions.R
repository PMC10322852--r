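# Depth distributions and intensity mixtures: the generalisations of the
# uniform-placement sensitivity relationship to arbitrary cell-depth
# densities and heterogeneous cell brightness.

#' Cell depth distribution
#'
#' A probability density of cell depth over a regular or irregular depth grid,
#' used to generalise the sensitivity relationship beyond uniform placement.
#' The density must integrate (trapezoidal rule on the grid) to 1 within 1e-6.
#'
#' @param grid Ascending depth grid, micrometres (>= 0).
#' @param density Probability density per micrometre at each grid point (>= 0).
#' @return A tibble of class `depth_distribution` with columns `depth_um`,
#'   `density`.
#' @examples
#' depth_distribution(seq(0, 100, 0.5), rep(0.01, 201))
#' @export
depth_distribution <- function(grid, density) {
  if (length(grid) != length(density) || length(grid) < 2) {
    rlang::abort("`grid` and `density` must have equal length >= 2.",
      class = "cryosect_invalid_argument"
    )
  }
  check_non_negative(grid, "grid")
  check_non_negative(density, "density")
  if (is.unsorted(grid, strictly = TRUE)) {
    rlang::abort("`grid` must be strictly ascending.", class = "cryosect_invalid_argument")
  }
  total <- trapz(grid, density)
  if (abs(total - 1) > 1e-6) {
    rlang::abort(sprintf("`density` must integrate to 1 on `grid` (got %.8f).", total),
      class = "cryosect_invalid_argument"
    )
  }
  tibble::new_tibble(
    tibble::tibble(depth_um = as.numeric(grid), density = as.numeric(density)),
    class = "depth_distribution"
  )
}

#' Uniform depth distribution over `[0, max_depth]`
#'
#' @param max_depth Upper end of the depth range, micrometres (> 0).
#' @param step Grid spacing, micrometres (default 0.1).
#' @return A [depth_distribution()].
#' @export
uniform_depth_distribution <- function(max_depth, step = 0.1) {
  check_positive(max_depth, "max_depth")
  g <- seq(0, max_depth, by = step)
  if (g[length(g)] < max_depth) g <- c(g, max_depth)
  depth_distribution(g, rep(1 / max_depth, length(g)))
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Pool per-slice depth distributions into a whole-volume distribution
#'
#' Slices may hold different numbers of cells with different within-slice
#' depth densities; the pooled density is the count-weighted mixture
#' `p(x) = sum_i (N_i / N) p_i(x)`, with all components on a shared grid.
#'
#' @param components List of `list(count =, dist =)` pairs, where `count` is
#'   the number of cells in the slice and `dist` a [depth_distribution()];
#'   all distributions must share the same grid.
#' @return A [depth_distribution()] on the shared grid.
#' @export
pool_distributions <- function(components) {
  if (!is.list(components) || length(components) < 1) {
    rlang::abort("`components` must be a non-empty list of (count, dist) pairs.",
      class = "cryosect_invalid_argument"
    )
  }
  counts <- purrr::map_dbl(components, "count")
  dists <- purrr::map(components, "dist")
  check_positive(counts, "count")
  grid <- dists[[1]]$depth_um
  for (d in dists) {
    if (!inherits(d, "depth_distribution")) {
      rlang::abort("each `dist` must be a depth_distribution.",
        class = "cryosect_invalid_argument"
      )
    }
    if (length(d$depth_um) != length(grid) || any(d$depth_um != grid)) {
      rlang::abort("all component distributions must share the same depth grid.",
        class = "cryosect_invalid_argument"
      )
    }
  }
  w <- counts / sum(counts)
  pooled <- purrr::reduce(
    purrr::map2(w, dists, function(wi, di) wi * di$density),
    `+`
  )
  depth_distribution(grid, pooled)
}

#' Sensitivity under an arbitrary cell depth distribution
#'
#' The detected fraction is the ratio of the probability mass within the
#' detectable depth `[0, X_optimal]` to the mass within one slice `[0, X]`,
#' evaluated by trapezoidal quadrature on the stored grid. Reduces to the
#' piecewise relationship for a uniform density.
#'
#' @param dist A [depth_distribution()] whose grid covers `[0, slice_thickness]`.
#' @param slice_thickness Slice thickness, micrometres (> 0).
#' @param x_optimal Optimal thickness, micrometres (> 0).
#' @return Sensitivity fraction in `[0, 1]`.
#' @examples
#' d <- uniform_depth_distribution(100)
#' distribution_sensitivity(d, 100, 58.15) # ~ 0.5815
#' @export
distribution_sensitivity <- function(dist, slice_thickness, x_optimal) {
  if (!inherits(dist, "depth_distribution")) {
    rlang::abort("`dist` must be a depth_distribution.", class = "cryosect_invalid_argument")
  }
  check_positive(slice_thickness, "slice_thickness")
  check_positive(x_optimal, "x_optimal")
  if (x_optimal >= slice_thickness) {
    return(1)
  }
  if (max(dist$depth_um) < slice_thickness) {
    rlang::abort("distribution grid does not cover [0, slice_thickness].",
      class = "cryosect_invalid_argument"
    )
  }
  num <- partial_integral(dist, x_optimal)
  den <- partial_integral(dist, slice_thickness)
  if (den <= 0) {
    rlang::abort("no probability mass within the slice: sensitivity undefined.",
      class = "cryosect_empty_slice"
    )
  }
  min(1, num / den)
}

# Trapezoidal integral of the density over [0, upper], splitting the grid
# cell that straddles `upper` by linear interpolation.
partial_integral <- function(dist, upper) {
  x <- dist$depth_um
  y <- dist$density
  inside <- x <= upper
  if (!any(inside)) {
    return(0)
  }
  xi <- x[inside]
  yi <- y[inside]
  total <- if (length(xi) >= 2) trapz(xi, yi) else 0
  k <- sum(inside)
  if (k < length(x) && x[k] < upper) {
    y_up <- y[k] + (y[k + 1] - y[k]) * (upper - x[k]) / (x[k + 1] - x[k])
    total <- total + (y[k] + y_up) * (upper - x[k]) / 2
  }
  total
}

#' Intensity mixture of cell sub-populations
#'
#' Groups of cells sharing a common unattenuated intensity, with counts; used
#' to evaluate the population sensitivity when brightness is heterogeneous.
#'
#' @param group_intensity Gray level per group (> 0).
#' @param group_count Positive integer count per group.
#' @return A tibble of class `intensity_mixture` with columns `intensity`,
#'   `count`.
#' @export
intensity_mixture <- function(group_intensity, group_count) {
  check_positive(group_intensity, "group_intensity")
  if (length(group_intensity) != length(group_count) || length(group_count) < 1) {
    rlang::abort("`group_intensity` and `group_count` must be equal-length, non-empty.",
      class = "cryosect_invalid_argument"
    )
  }
  if (any(group_count <= 0) || any(group_count != floor(group_count))) {
    rlang::abort("`group_count` must be positive integers.",
      class = "cryosect_invalid_argument"
    )
  }
  tibble::new_tibble(
    tibble::tibble(
      intensity = as.numeric(group_intensity),
      count = as.integer(group_count)
    ),
    class = "intensity_mixture"
  )
}

#' Population sensitivity for a mixture of cell intensities
#'
#' Count-weighted average of the per-group piecewise sensitivity,
#' `Sens = sum_j (N_j / N) Sens(I_j)`; groups dimmer than the threshold are
#' never detected and contribute zero at any thickness.
#'
#' @param mixture An [intensity_mixture()].
#' @param slice_thickness Slice thickness, micrometres (> 0).
#' @param attenuation Effective attenuation coefficient, cm^-1 (> 0).
#' @param threshold Detection threshold, gray level (> 0).
#' @return Sensitivity fraction in `[0, 1]`.
#' @examples
#' m <- intensity_mixture(c(30, 80), c(50, 50))
#' mixture_sensitivity(m, 66, 314, 10)
#' @export
mixture_sensitivity <- function(mixture, slice_thickness, attenuation, threshold) {
  if (!inherits(mixture, "intensity_mixture") || nrow(mixture) < 1) {
    rlang::abort("`mixture` must be a non-empty intensity_mixture.",
      class = "cryosect_invalid_argument"
    )
  }
  check_positive(slice_thickness, "slice_thickness")
  sens <- purrr::map_dbl(mixture$intensity, function(int) {
    if (int < threshold) {
      return(0)
    }
    sensitivity_piecewise(
      slice_thickness,
      # intensity == threshold gives X_optimal 0: detectable only exactly at
      # the block-face, a zero-measure event under continuous placement
      max(optimal_thickness(int, attenuation, threshold), .Machine$double.xmin)
    )
  })
  sum(mixture$count * sens) / sum(mixture$count)
}
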