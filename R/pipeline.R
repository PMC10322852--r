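# Section-and-image resampling pipeline: simulate thicker sections from a
# thinly sliced stack by slice skipping, count cells by thresholding plus 3-D
# connected-component analysis, and calibrate the sensitivity-vs-thickness
# relationship and the optical parameters from the data themselves.

#' Resample a stack by slice skipping
#'
#' Keeps every `skip`-th slice (anchored at the first by default), emulating
#' acquisition at `skip` times the native section thickness.
#'
#' @param stack An `image_stack`.
#' @param skip Positive integer skip factor; 1 is the identity.
#' @param offset Index of the first kept slice minus one (default 0; the
#'   counting can shift by a few cells with phase, so the anchor is explicit).
#' @return An `image_stack` with updated slice thickness and provenance.
#' @examples
#' vol <- build_compliant_volume(100, 30, 314)
#' stk <- render_image_stack(vol, 10)
#' n_slices(resample_stack(stk, 2)) # 5
#' @export
resample_stack <- function(stack, skip, offset = 0) {
  skip <- check_scalar_count(skip, "skip")
  n <- n_slices(stack)
  keep <- seq(1 + offset, n, by = skip)
  if (length(keep) <= 1) {
    rlang::warn(sprintf(
      "skip %d leaves a single slice of a %d-slice stack.", skip, n
    ))
    keep <- keep[1]
  }
  prov <- stack$provenance
  prov$resampled_skip <- skip
  prov$resampled_offset <- offset
  image_stack(
    stack$voxels[keep, , , drop = FALSE],
    stack$slice_thickness_um * skip,
    stack$pixel_size_um,
    provenance = prov
  )
}

#' Threshold + 3-D connected-component cell detection
#'
#' Labels voxels at or above the threshold by 3-D connectivity (26-connected
#' by default) so that the subsurface "comet tail" of one cell, which appears
#' in several consecutive slices, is grouped into a single component instead
#' of being counted once per slice.
#'
#' @param stack An `image_stack`.
#' @param threshold Detection threshold, gray level (> 0).
#' @param connectivity 26 (faces, edges and corners) or 6 (faces only).
#' @return A tibble of class `cell_components`, one row per component:
#'   `component`, `n_voxels`, `peak_intensity`, peak position
#'   (`peak_slice`, `peak_row`, `peak_col`), centroid columns, and
#'   `first_slice` / `last_slice` span. Zero rows when nothing is above
#'   threshold.
#' @examples
#' vol <- build_compliant_volume(60, 30, 314)
#' comps <- detect_components(render_image_stack(vol, 10), 10)
#' nrow(comps) # 60
#' @export
detect_components <- function(stack, threshold, connectivity = 26) {
  check_positive(threshold, "threshold")
  if (!connectivity %in% c(6, 26)) {
    rlang::abort("`connectivity` must be 6 or 26.", class = "cryosect_invalid_argument")
  }
  d <- dim(stack$voxels)
  on_idx <- which(stack$voxels >= threshold)
  empty <- tibble::new_tibble(
    tibble::tibble(
      component = integer(), n_voxels = integer(),
      peak_intensity = numeric(),
      peak_slice = integer(), peak_row = integer(), peak_col = integer(),
      centroid_slice = numeric(), centroid_row = numeric(),
      centroid_col = numeric(),
      first_slice = integer(), last_slice = integer()
    ),
    class = "cell_components"
  )
  if (length(on_idx) == 0) {
    return(empty)
  }
  coords <- arrayInd(on_idx, d) # columns: slice, row, col
  labels <- label_components_3d(coords, d, connectivity)
  values <- stack$voxels[on_idx]
  df <- tibble::tibble(
    component = labels,
    slice = coords[, 1], row = coords[, 2], col = coords[, 3],
    value = values
  )
  out <- df |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(
      n_voxels = dplyr::n(),
      peak_intensity = max(.data$value),
      peak_slice = .data$slice[which.max(.data$value)],
      peak_row = .data$row[which.max(.data$value)],
      peak_col = .data$col[which.max(.data$value)],
      centroid_slice = mean(.data$slice),
      centroid_row = mean(.data$row),
      centroid_col = mean(.data$col),
      first_slice = min(.data$slice),
      last_slice = max(.data$slice),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$component)
  tibble::new_tibble(out, class = "cell_components")
}

# Connected components of above-threshold voxels via the adjacency graph:
# voxels are vertices, an edge joins neighbours under the chosen
# connectivity, and components come from igraph. Only half the neighbour
# offsets are needed since edges are undirected.
label_components_3d <- function(coords, dims, connectivity) {
  key <- function(s, r, c) (s - 1) * dims[2] * dims[3] + (r - 1) * dims[3] + c
  keys <- key(coords[, 1], coords[, 2], coords[, 3])
  pos <- seq_along(keys)
  if (connectivity == 6) {
    offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    offs <- as.matrix(expand.grid(ds = -1:1, dr = -1:1, dc = -1:1))
    offs <- offs[offs[, 1] != 0 | offs[, 2] != 0 | offs[, 3] != 0, ]
    # keep one of each +/- pair
    offs <- offs[offs[, 1] > 0 |
      (offs[, 1] == 0 & offs[, 2] > 0) |
      (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  }
  edges <- integer(0)
  for (o in seq_len(nrow(offs))) {
    s2 <- coords[, 1] + offs[o, 1]
    r2 <- coords[, 2] + offs[o, 2]
    c2 <- coords[, 3] + offs[o, 3]
    inb <- s2 >= 1 & s2 <= dims[1] & r2 >= 1 & r2 <= dims[2] &
      c2 >= 1 & c2 <= dims[3]
    if (!any(inb)) next
    m <- match(key(s2[inb], r2[inb], c2[inb]), keys)
    hit <- !is.na(m)
    if (any(hit)) {
      edges <- c(edges, rbind(pos[inb][hit], m[hit]))
    }
  }
  g <- igraph::make_empty_graph(n = length(keys), directed = FALSE)
  if (length(edges) > 0) {
    g <- igraph::add_edges(g, edges)
  }
  igraph::components(g)$membership
}

#' Sensitivity-vs-thickness calibration by slice skipping
#'
#' The calibration recipe for choosing a section thickness from thin-slice
#' data: resample the stack at each skip factor, count cells by threshold +
#' 3-D CCA, and normalise counts by the skip-1 reference. The result doubles
#' as a `sensitivity_curve` over effective thickness, so
#' [find_optimal_thickness()] and [fit_loglog_slope()] apply directly.
#'
#' @param stack An `image_stack` (native, thinly sliced).
#' @param skip_list Integer skip factors; must contain 1 unless
#'   `reference_count` is supplied.
#' @param threshold Detection threshold, gray level (> 0).
#' @param connectivity Passed to [detect_components()].
#' @param reference_count Optional known full-sampling count.
#' @return A `sensitivity_curve` tibble (class also `stack_report`) with
#'   columns `skip`, `sweep_value` (effective thickness, um), `count`,
#'   `n_true` (the reference count), `sensitivity`.
#' @examples
#' vol <- build_compliant_volume(200, 38, 314)
#' stk <- render_image_stack(vol, 10)
#' rep <- sensitivity_vs_skip(stk, 1:8, 10)
#' find_optimal_thickness(rep) # 40: largest multiple of 10 under 42.52
#' @export
sensitivity_vs_skip <- function(stack, skip_list, threshold,
                                connectivity = 26, reference_count = NULL) {
  skip_list <- sort(unique(as.integer(skip_list)))
  if (any(skip_list < 1)) {
    rlang::abort("skip factors must be >= 1.", class = "cryosect_invalid_argument")
  }
  if (is.null(reference_count) && !1L %in% skip_list) {
    rlang::abort("`skip_list` must contain 1, or supply `reference_count`.",
      class = "cryosect_invalid_argument"
    )
  }
  counts <- purrr::map_int(skip_list, function(k) {
    nrow(detect_components(resample_stack(stack, k), threshold, connectivity))
  })
  ref <- reference_count %||% counts[skip_list == 1L]
  if (any(counts > ref)) {
    rlang::warn("a subsampled count exceeds the reference count; sensitivities are clipped at 1.")
  }
  df <- tibble::tibble(
    skip = skip_list,
    sweep_value = skip_list * stack$slice_thickness_um,
    count = counts,
    n_true = as.integer(ref),
    sensitivity = pmin(1, counts / ref)
  )
  tibble::new_tibble(df,
    sweep_kind = "thickness",
    provenance = list(
      method = "section_and_image", threshold = threshold,
      native_thickness_um = stack$slice_thickness_um,
      connectivity = connectivity
    ),
    class = c("stack_report", "sensitivity_curve")
  )
}

#' Subsurface decay profile of one detected component
#'
#' Per-slice intensity at the component's lateral peak position, indexed by
#' distance above the brightest (deepest-seen) slice: the raw material for
#' exponential attenuation fitting. The cell's own slice is the zero-distance
#' point; below it the signal has been cut away.
#'
#' @param stack An `image_stack`.
#' @param component One row of a `cell_components` tibble (spanning >= 3
#'   slices).
#' @return A tibble with columns `depth_um` (distance above the brightest
#'   slice) and `intensity`, ascending in depth.
#' @export
extract_decay_profile <- function(stack, component) {
  if (nrow(component) != 1) {
    rlang::abort("`component` must be a single component row.",
      class = "cryosect_invalid_argument"
    )
  }
  span <- component$last_slice - component$first_slice + 1
  if (span < 3) {
    rlang::abort("component spans fewer than 3 slices: not enough points to fit.",
      class = "cryosect_insufficient_data"
    )
  }
  slices <- component$first_slice:component$last_slice
  inten <- stack$voxels[cbind(slices, component$peak_row, component$peak_col)]
  tibble::tibble(
    depth_um = (component$last_slice - slices) * stack$slice_thickness_um,
    intensity = inten
  ) |>
    dplyr::arrange(.data$depth_um)
}

#' Estimate the effective attenuation coefficient from a decay profile
#'
#' Log-linear (exponential regression) fit of intensity against depth: the
#' slope gives the effective attenuation coefficient in cm^-1 and the
#' exponentiated intercept estimates the unattenuated intensity.
#'
#' @param profile Tibble with columns `depth_um`, `intensity` (>= 3 points,
#'   all intensities > 0).
#' @return A `decay_fit` list: `attenuation_cm1`, `intensity_gray`,
#'   `r_squared`, `n_points`; see [tidy.decay_fit()].
#' @examples
#' prof <- tibble::tibble(
#'   depth_um = seq(0, 50, 10),
#'   intensity = surface_intensity(300, 332, seq(0, 50, 10))
#' )
#' estimate_attenuation(prof)$attenuation_cm1 # 332
#' @export
estimate_attenuation <- function(profile) {
  if (nrow(profile) < 3) {
    rlang::abort("need >= 3 profile points.", class = "cryosect_insufficient_data")
  }
  if (any(profile$intensity <= 0)) {
    rlang::abort("all profile intensities must be > 0 for the log fit.",
      class = "cryosect_invalid_argument"
    )
  }
  fit <- stats::lm(log(intensity) ~ depth_um, data = profile)
  slope <- unname(stats::coef(fit)[2]) # per um
  if (slope >= 0) {
    rlang::warn("decay profile is non-decreasing with depth: fitted attenuation is non-positive.")
  }
  structure(
    list(
      attenuation_cm1 = -slope * .UM_PER_CM,
      intensity_gray = exp(unname(stats::coef(fit)[1])),
      r_squared = stats::cor(log(profile$intensity), profile$depth_um)^2,
      n_points = nrow(profile)
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> mu_T = %.1f cm^-1, I_fluo = %.1f gray (R^2 %.4f, %d points)\n",
    x$attenuation_cm1, x$intensity_gray, x$r_squared, x$n_points
  ))
  invisible(x)
}

#' Estimate the population cell intensity from detected components
#'
#' Mean of the per-component peak intensities. The brightest voxel of a
#' component is its look closest to the block-face (depth near 0), so the
#' mean peak approximates the unattenuated cell intensity, with a residual
#' attenuation bias bounded by the within-slab depth.
#'
#' @param components A `cell_components` tibble (>= 1 row).
#' @return Mean peak intensity, gray level.
#' @export
estimate_cell_intensity <- function(components) {
  if (nrow(components) < 1) {
    rlang::abort("no components to summarise.", class = "cryosect_insufficient_data")
  }
  mean(components$peak_intensity)
}
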