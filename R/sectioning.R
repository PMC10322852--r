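# Digital sectioning: slice a virtual volume at a fixed thickness, image the
# exposed block-face before every cut, and mark each cell detected when its
# attenuated intensity at some block-face reaches the threshold.
#
# Block-face phase: the first image is taken at depth 0 (before the first
# cut); subsequent faces sit at X, 2X, ... A cell at depth d is present at
# face z iff d >= z (a cell exactly at the cut plane is just exposed, x = 0),
# so its closest look is the face at floor(d / X) * X. The whole sweep is
# therefore vectorised over cells without looping over faces.

# Depth range over which a cell remains above threshold; -Inf marks cells
# dimmer than the threshold, which no block-face can see.
subsurface_length_cells <- function(intensity, attenuation, threshold) {
  ifelse(
    intensity < threshold,
    -Inf,
    -log(threshold / pmax(intensity, threshold)) / attenuation * .UM_PER_CM
  )
}

section_cells <- function(volume, slice_thickness, threshold) {
  e <- subsurface_length_cells(volume$intensity, volume$attenuation_cm1, threshold)
  k_last <- floor(volume$depth_um / slice_thickness)
  k_first <- pmax(0, ceiling((volume$depth_um - e) / slice_thickness))
  detected <- is.finite(e) & k_first <= k_last
  first_face <- last_face <- rep(NA_integer_, nrow(volume))
  first_face[detected] <- as.integer(k_first[detected])
  last_face[detected] <- as.integer(k_last[detected])
  tibble::tibble(
    id = volume$id,
    depth_um = volume$depth_um,
    u_um = volume$u_um,
    v_um = volume$v_um,
    detected = detected,
    first_face = first_face,
    last_face = last_face
  )
}

new_detection_report <- function(cells, slice_thickness, threshold, merge_rule,
                                 n_detected) {
  n_true <- nrow(cells)
  structure(
    list(
      cells = cells,
      n_true = n_true,
      n_detected = as.integer(n_detected),
      n_missed = as.integer(n_true - n_detected),
      sensitivity = n_detected / n_true,
      slice_thickness_um = slice_thickness,
      threshold = threshold,
      merge_rule = merge_rule
    ),
    class = "detection_report"
  )
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf(
    "<detection_report> X = %g um, T = %g gray (%s de-duplication)\n  detected %d / %d cells  (sensitivity %.1f%%)\n",
    x$slice_thickness_um, x$threshold, x$merge_rule,
    x$n_detected, x$n_true, 100 * x$sensitivity
  ))
  invisible(x)
}

#' Digital sectioning of a virtual volume
#'
#' Sections the volume at a fixed thickness, imaging each block-face before
#' the cut; a cell is detected when its Beer-Lambert surface intensity at any
#' block-face reaches the threshold. Cells are de-duplicated by identity
#' (each counts once however many faces see it), which is exact under the
#' non-overlap assumption of unique lateral positions.
#'
#' @param volume A `virtual_volume` (non-empty).
#' @param slice_thickness Section thickness `X`, micrometres (> 0).
#' @param threshold Detection threshold `T`, gray level (> 0).
#' @return A `detection_report`: counts, sensitivity `n/N`, and a per-cell
#'   tibble with the first/last block-face index at which each cell was seen
#'   (see [tidy.detection_report()]).
#' @examples
#' vol <- build_compliant_volume(150, 30, 314)
#' run_digital_sectioning(vol, 20, 10)$sensitivity # 1
#' run_digital_sectioning(vol, 70, 10)$sensitivity # 0.5
#' @export
run_digital_sectioning <- function(volume, slice_thickness, threshold) {
  check_volume(volume)
  check_positive(slice_thickness, "slice_thickness")
  check_positive(threshold, "threshold")
  cells <- section_cells(volume, slice_thickness, threshold)
  new_detection_report(cells, slice_thickness, threshold, "identity",
    sum(cells$detected)
  )
}

#' Digital sectioning with overlap-aware counting
#'
#' For volumes where distinct cells can share a lateral column, signals that
#' abut along depth merge and are seen as one object. Counting uses the
#' disappearance-event rule: within each lateral column, detectable cells are
#' counted once per distinct last-visible block-face index (two cells cut
#' away in the same slab while both visible merge into one count). At
#' `X = 1` um any placement with >= 1 um depth separation is fully resolved.
#'
#' @inheritParams run_digital_sectioning
#' @return A `detection_report` (merge rule `"disappearance"`).
#' @export
run_overlap_sectioning <- function(volume, slice_thickness, threshold) {
  check_volume(volume)
  check_positive(slice_thickness, "slice_thickness")
  check_positive(threshold, "threshold")
  if (anyNA(volume$u_um) || anyNA(volume$v_um)) {
    rlang::abort("overlap counting needs lateral positions for every cell.",
      class = "cryosect_invalid_argument"
    )
  }
  cells <- section_cells(volume, slice_thickness, threshold)
  n_detected <- cells |>
    dplyr::filter(.data$detected) |>
    dplyr::distinct(.data$u_um, .data$v_um, .data$last_face) |>
    nrow()
  new_detection_report(cells, slice_thickness, threshold, "disappearance",
    n_detected
  )
}

check_volume <- function(volume) {
  if (!inherits(volume, "virtual_volume") || nrow(volume) < 1) {
    rlang::abort("`volume` must be a non-empty virtual_volume.",
      class = "cryosect_empty_volume"
    )
  }
  invisible(volume)
}

new_sensitivity_curve <- function(df, sweep_kind, provenance = list()) {
  tibble::new_tibble(df,
    sweep_kind = sweep_kind,
    provenance = provenance,
    class = "sensitivity_curve"
  )
}

#' Sensitivity-vs-thickness sweep
#'
#' Runs the digital sectioning over a list of section thicknesses on the same
#' frozen volume and collects the sensitivity curve (the central calibration
#' output of the model).
#'
#' @param volume A `virtual_volume`.
#' @param thickness_list Thicknesses to test, micrometres (> 0).
#' @param threshold Detection threshold, gray level (> 0).
#' @param method `"identity"` (non-overlapping de-duplication) or
#'   `"overlap"` (disappearance-event counting, see
#'   [run_overlap_sectioning()]).
#' @return A `sensitivity_curve` tibble with columns `sweep_value`
#'   (thickness, um), `count`, `n_true`, `sensitivity`, sorted by thickness.
#' @examples
#' vol <- build_compliant_volume(150, 30, 314)
#' curve <- sweep_thickness(vol, seq(5, 150, 5), 10)
#' find_optimal_thickness(curve)
#' @export
sweep_thickness <- function(volume, thickness_list, threshold,
                            method = c("identity", "overlap")) {
  method <- match.arg(method)
  check_positive(thickness_list, "thickness_list")
  runner <- if (method == "identity") run_digital_sectioning else run_overlap_sectioning
  rows <- purrr::map(sort(thickness_list), function(x) {
    rep <- runner(volume, x, threshold)
    tibble::tibble(
      sweep_value = x,
      count = rep$n_detected,
      n_true = rep$n_true,
      sensitivity = rep$sensitivity
    )
  })
  new_sensitivity_curve(
    purrr::list_rbind(rows),
    "thickness",
    list(
      method = method, threshold = threshold,
      volume_kind = attr(volume, "kind"),
      volume_thickness_um = volume_thickness(volume),
      n_cells = nrow(volume),
      seed = attr(volume, "seed")
    )
  )
}

#' Sensitivity-vs-intensity sweep at fixed thickness
#'
#' Builds one compliant volume per candidate cell intensity and sections each
#' at a fixed thickness, mapping out the minimum brightness needed to hold
#' 100% sensitivity (the optimal intensity).
#'
#' @param thickness Fixed section thickness, micrometres (> 0).
#' @param intensity_list Cell intensities to test, gray level (> 0).
#' @param attenuation Effective attenuation coefficient, cm^-1 (> 0).
#' @param threshold Detection threshold, gray level (> 0).
#' @param volume_thickness Slab thickness of the test volumes, micrometres
#'   (default 150).
#' @return A `sensitivity_curve` tibble with `sweep_value` = intensity;
#'   sensitivity is 0 for intensities below the threshold and non-decreasing
#'   in intensity.
#' @examples
#' curve <- sweep_intensity(20, 1:30, 314, 10)
#' @export
sweep_intensity <- function(thickness, intensity_list, attenuation, threshold,
                            volume_thickness = 150) {
  check_positive(thickness, "thickness")
  check_positive(intensity_list, "intensity_list")
  rows <- purrr::map(sort(intensity_list), function(int) {
    vol <- build_compliant_volume(volume_thickness, int, attenuation)
    rep <- run_digital_sectioning(vol, thickness, threshold)
    tibble::tibble(
      sweep_value = int,
      count = rep$n_detected,
      n_true = rep$n_true,
      sensitivity = rep$sensitivity
    )
  })
  new_sensitivity_curve(
    purrr::list_rbind(rows),
    "intensity",
    list(
      thickness_um = thickness, attenuation_cm1 = attenuation,
      threshold = threshold, volume_thickness_um = volume_thickness
    )
  )
}

#' Replicated thickness sweeps over stochastic volumes
#'
#' Rebuilds the volume for each seed (e.g. a perturbed or overlapping
#' placement), sweeps thickness, and stacks the curves with a `replicate`
#' column; [summarise_sweep()] reduces them to mean and sd per thickness.
#'
#' @param volume_fn Function of one argument (`seed`) returning a
#'   `virtual_volume`.
#' @param thickness_list Thicknesses to test, micrometres.
#' @param threshold Detection threshold, gray level.
#' @param seeds Integer vector of seeds, one replicate per seed (default
#'   `1:10`).
#' @param method Counting rule, as in [sweep_thickness()].
#' @return A `sensitivity_curve` tibble with an extra `replicate` column.
#' @export
sweep_replicates <- function(volume_fn, thickness_list, threshold,
                             seeds = 1:10, method = c("identity", "overlap")) {
  method <- match.arg(method)
  curves <- purrr::map2(seeds, seq_along(seeds), function(seed, i) {
    cv <- sweep_thickness(volume_fn(seed), thickness_list, threshold, method)
    cv$replicate <- i
    cv$seed <- seed
    cv
  })
  prov <- attr(curves[[1]], "provenance")
  prov$seeds <- seeds
  new_sensitivity_curve(purrr::list_rbind(curves), "thickness", prov)
}

#' @rdname sweep_replicates
#' @param curve A replicated `sensitivity_curve`.
#' @return `summarise_sweep()`: a tibble with `sweep_value`,
#'   `sensitivity_mean`, `sensitivity_sd`, `count_mean`, `n_replicates`.
#' @export
summarise_sweep <- function(curve) {
  curve |>
    dplyr::group_by(.data$sweep_value) |>
    dplyr::summarise(
      sensitivity_mean = mean(.data$sensitivity),
      sensitivity_sd = stats::sd(.data$sensitivity),
      count_mean = mean(.data$count),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}

#' Breakpoint of a sensitivity curve
#'
#' The optimal thickness as measured from a sweep: the largest tested
#' thickness whose sensitivity is still at least `1 - tolerance`.
#'
#' @param curve A thickness-sweep `sensitivity_curve`.
#' @param tolerance Allowed shortfall from full sensitivity (default 0:
#'   strictly 100%).
#' @return Thickness in micrometres.
#' @examples
#' vol <- build_compliant_volume(150, 50, 314)
#' find_optimal_thickness(sweep_thickness(vol, 1:150, 10)) # 51
#' @export
find_optimal_thickness <- function(curve, tolerance = 0) {
  if (!identical(attr(curve, "sweep_kind"), "thickness")) {
    rlang::abort("`curve` must be a thickness sweep.", class = "cryosect_invalid_argument")
  }
  ok <- curve$sweep_value[curve$sensitivity >= 1 - tolerance]
  if (length(ok) == 0) {
    rlang::abort("no tested thickness reaches the sensitivity criterion.",
      class = "cryosect_not_found"
    )
  }
  max(ok)
}

#' Log-log slope of the sub-optimal sensitivity decline
#'
#' Ordinary least-squares slope of `log(sensitivity)` against
#' `log(thickness)` over a thickness window. For compliant volumes the
#' sub-optimal decline is reciprocal, so the slope is -1 (a -45 degree line);
#' tissue inhomogeneity flattens it towards 0 while brightness variation
#' preserves it.
#'
#' @param curve A thickness-sweep `sensitivity_curve`.
#' @param thickness_range Length-2 numeric `(lo, hi]` window in micrometres;
#'   points with zero sensitivity are dropped.
#' @return A `loglog_fit` object with elements `slope`, `intercept`,
#'   `r_squared`, `n_points`, `thickness_range`; see [tidy.loglog_fit()].
#' @examples
#' vol <- build_compliant_volume(1000, 30, 314)
#' fit <- fit_loglog_slope(sweep_thickness(vol, seq(5, 150, 5), 10), c(35, 150))
#' fit$slope # ~ -1
#' @export
fit_loglog_slope <- function(curve, thickness_range) {
  if (!identical(attr(curve, "sweep_kind"), "thickness")) {
    rlang::abort("`curve` must be a thickness sweep.", class = "cryosect_invalid_argument")
  }
  if (length(thickness_range) != 2 || thickness_range[1] >= thickness_range[2]) {
    rlang::abort("`thickness_range` must be an increasing (lo, hi] pair.",
      class = "cryosect_invalid_argument"
    )
  }
  pts <- curve |>
    dplyr::filter(
      .data$sweep_value > thickness_range[1],
      .data$sweep_value <= thickness_range[2],
      .data$sensitivity > 0
    )
  if (nrow(pts) < 3) {
    rlang::abort("need >= 3 positive-sensitivity points in the range.",
      class = "cryosect_invalid_argument"
    )
  }
  fit <- stats::lm(log(sensitivity) ~ log(sweep_value), data = pts)
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = stats::cor(log(pts$sensitivity), log(pts$sweep_value))^2,
      n_points = nrow(pts),
      thickness_range = thickness_range
    ),
    class = "loglog_fit"
  )
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf(
    "<loglog_fit> slope %.3f (R^2 %.4f, %d points in (%g, %g] um)\n",
    x$slope, x$r_squared, x$n_points,
    x$thickness_range[1], x$thickness_range[2]
  ))
  invisible(x)
}
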