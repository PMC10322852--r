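# Virtual tissue volumes: programmatic stand-ins for a slab of tissue holding
# point-like fluorescent cells. A volume is a tibble with one row per cell
# (id, depth, lateral position, per-cell intensity and attenuation) plus
# slab-level attributes. All depths are measured from the original top
# surface; the depth relative to a block-face is depth minus removed material.

new_virtual_volume <- function(cells, thickness_um, kind,
                               cell_spacing_um = NA_real_,
                               density_cells_cm2 = NA_real_,
                               area_cm2 = NA_real_,
                               lateral_pitch_um = NA_real_,
                               seed = NA_integer_) {
  tibble::new_tibble(
    cells,
    thickness_um = as.numeric(thickness_um),
    kind = kind,
    cell_spacing_um = cell_spacing_um,
    density_cells_cm2 = density_cells_cm2,
    area_cm2 = area_cm2,
    lateral_pitch_um = lateral_pitch_um,
    seed = seed,
    class = "virtual_volume"
  )
}

#' Slab thickness of a virtual volume
#'
#' @param volume A virtual volume tibble.
#' @return Thickness in micrometres (falls back to the deepest cell rounded up
#'   when the attribute has been stripped by data manipulation).
#' @export
volume_thickness <- function(volume) {
  attr(volume, "thickness_um") %||% ceiling(max(volume$depth_um))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Unique lateral grid positions: row-major square grid, one cell per site.
lateral_grid <- function(n, pitch) {
  ncol <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  list(u = (idx %% ncol) * pitch, v = (idx %/% ncol) * pitch)
}

#' Build a compliant virtual volume
#'
#' The reference simulation substrate: one model cell per 1-um depth bin at
#' bin centres (0.5, 1.5, ..., S - 0.5 um), so a slab of thickness `S` holds
#' exactly `N = S` cells, all with identical intensity and attenuation and
#' each at a distinct lateral grid position (no signal overlap). This
#' satisfies all three model assumptions: homogeneous tissue, equal cell
#' brightness, no overlap.
#'
#' @param thickness Slab thickness `S`, a positive integer number of
#'   micrometres.
#' @param intensity Unattenuated cell intensity, gray level (> 0).
#' @param attenuation Effective attenuation coefficient, cm^-1 (> 0).
#' @param lateral_pitch Spacing of the unique lateral grid, micrometres
#'   (default 20).
#' @return A `virtual_volume` tibble with columns `id`, `depth_um`, `u_um`,
#'   `v_um`, `intensity`, `attenuation_cm1`.
#' @examples
#' vol <- build_compliant_volume(150, 30, 314)
#' nrow(vol) # 150 cells
#' @export
build_compliant_volume <- function(thickness, intensity, attenuation,
                                   lateral_pitch = 20) {
  thickness <- check_scalar_count(thickness, "thickness")
  check_positive(intensity, "intensity")
  check_positive(attenuation, "attenuation")
  n <- thickness
  lat <- lateral_grid(n, lateral_pitch)
  cells <- tibble::tibble(
    id = seq_len(n),
    depth_um = seq_len(n) - 0.5,
    u_um = lat$u,
    v_um = lat$v,
    intensity = rep(as.numeric(intensity), n),
    attenuation_cm1 = rep(as.numeric(attenuation), n)
  )
  new_virtual_volume(cells, thickness, "compliant",
    cell_spacing_um = 1, lateral_pitch_um = lateral_pitch
  )
}

#' Build a regularly spaced virtual volume
#'
#' Cells at a fixed depth interval `t = S / N`, one per interval at its
#' centre, at unique lateral positions. This is the textbook worked
#' configuration for reasoning about section thickness versus counting (e.g.
#' 7 cells spaced 10 um in a 70-um slab whose subsurface fluorescence extends
#' 20 um).
#'
#' @param thickness Slab thickness `S`, micrometres (> 0).
#' @param n_cells Number of cells `N`; `thickness / n_cells` is the spacing.
#' @param intensity Unattenuated cell intensity, gray level. To express the
#'   configuration in terms of a subsurface length `e` instead, pass
#'   `intensity = optimal_intensity(threshold, attenuation, e)`.
#' @param attenuation Effective attenuation coefficient, cm^-1 (> 0).
#' @param lateral_pitch Spacing of the unique lateral grid, micrometres.
#' @return A `virtual_volume` tibble.
#' @examples
#' # 7 cells, 10-um spacing, subsurface length exactly 20 um for T = 10:
#' vol <- build_spaced_volume(70, 7, optimal_intensity(10, 314, 20), 314)
#' @export
build_spaced_volume <- function(thickness, n_cells, intensity, attenuation,
                                lateral_pitch = 20) {
  check_positive(thickness, "thickness")
  n_cells <- check_scalar_count(n_cells, "n_cells")
  check_positive(intensity, "intensity")
  check_positive(attenuation, "attenuation")
  spacing <- thickness / n_cells
  lat <- lateral_grid(n_cells, lateral_pitch)
  cells <- tibble::tibble(
    id = seq_len(n_cells),
    depth_um = (seq_len(n_cells) - 0.5) * spacing,
    u_um = lat$u,
    v_um = lat$v,
    intensity = rep(as.numeric(intensity), n_cells),
    attenuation_cm1 = rep(as.numeric(attenuation), n_cells)
  )
  new_virtual_volume(cells, thickness, "spaced", cell_spacing_um = spacing,
    lateral_pitch_um = lateral_pitch
  )
}

#' Perturb per-cell attenuation (tissue inhomogeneity)
#'
#' Adds zero-mean Gaussian deviates (sd `sigma`) to every cell's attenuation
#' coefficient, emulating a mix of tissue types; values are clipped below at
#' 1 cm^-1 since a non-positive attenuation is unphysical.
#'
#' @param volume A `virtual_volume`.
#' @param sigma Standard deviation of the perturbation, cm^-1 (>= 0).
#' @param seed Integer seed for reproducibility (optional).
#' @return The perturbed `virtual_volume` (kind `"perturbed"` unless
#'   `sigma = 0`, which returns the input unchanged).
#' @export
perturb_attenuation <- function(volume, sigma, seed = NULL) {
  check_non_negative(sigma, "sigma")
  if (sigma == 0) {
    return(volume)
  }
  dev <- with_seed(seed, stats::rnorm(nrow(volume), 0, sigma))
  out <- volume
  out$attenuation_cm1 <- pmax(1, volume$attenuation_cm1 + dev)
  attr(out, "kind") <- "perturbed"
  attr(out, "seed") <- seed %||% NA_integer_
  out
}

#' Perturb per-cell intensity (cell brightness variation)
#'
#' Adds zero-mean Gaussian deviates (sd `sigma`) to every cell's unattenuated
#' intensity, emulating dye loss, photobleaching or uneven labelling; values
#' are clipped below at 0. Cells that fall below the detection threshold are
#' permanently undetectable at any slice thickness.
#'
#' @inheritParams perturb_attenuation
#' @param sigma Standard deviation of the perturbation, gray level (>= 0).
#' @return The perturbed `virtual_volume`.
#' @export
perturb_intensity <- function(volume, sigma, seed = NULL) {
  check_non_negative(sigma, "sigma")
  if (sigma == 0) {
    return(volume)
  }
  dev <- with_seed(seed, stats::rnorm(nrow(volume), 0, sigma))
  out <- volume
  out$intensity <- pmax(0, volume$intensity + dev)
  attr(out, "kind") <- "perturbed"
  attr(out, "seed") <- seed %||% NA_integer_
  out
}

#' Build an overlapping virtual volume
#'
#' Random cell placement on a fixed tissue area so that subsurface signals of
#' different cells can merge along depth: `N = round(density * area)` cells
#' with depths uniform on `[0, thickness)` and lateral positions drawn with
#' replacement from a discrete pixel grid over the area, so distinct cells
#' can share a lateral column. The degree of overlap is governed by the cell
#' density (cells/cm^2).
#'
#' @param thickness Slab thickness, micrometres (> 0).
#' @param density Cell density, cells/cm^2 (> 0).
#' @param area Tissue area, cm^2 (> 0).
#' @param intensity Unattenuated cell intensity, gray level (> 0).
#' @param attenuation Effective attenuation coefficient, cm^-1 (> 0).
#' @param lateral_pitch Pitch of the discrete lateral grid, micrometres
#'   (default 100); the grid has `floor(sqrt(area) / pitch)` columns per side.
#' @param seed Integer seed (optional).
#' @return A `virtual_volume` tibble (kind `"overlap"`).
#' @examples
#' vol <- build_overlap_volume(1000, 400, 1, 40, 314, seed = 1)
#' nrow(vol) # 400 cells
#' @export
build_overlap_volume <- function(thickness, density, area, intensity,
                                 attenuation, lateral_pitch = 100,
                                 seed = NULL) {
  check_positive(thickness, "thickness")
  check_positive(density, "density")
  check_positive(area, "area")
  check_positive(intensity, "intensity")
  check_positive(attenuation, "attenuation")
  n <- round(density * area)
  if (n < 1) {
    rlang::abort("density * area rounds to zero cells.", class = "cryosect_empty_volume")
  }
  side_um <- sqrt(area) * 1e4
  n_sites <- max(1L, floor(side_um / lateral_pitch))
  cells <- with_seed(seed, tibble::tibble(
    id = seq_len(n),
    depth_um = stats::runif(n, 0, thickness),
    u_um = (sample.int(n_sites, n, replace = TRUE) - 1L) * lateral_pitch,
    v_um = (sample.int(n_sites, n, replace = TRUE) - 1L) * lateral_pitch,
    intensity = rep(as.numeric(intensity), n),
    attenuation_cm1 = rep(as.numeric(attenuation), n)
  ))
  new_virtual_volume(cells, thickness, "overlap",
    density_cells_cm2 = density, area_cm2 = area,
    lateral_pitch_um = lateral_pitch, seed = seed %||% NA_integer_
  )
}

#' Write / read a virtual volume as CSV
#'
#' One row per cell: `id, depth_um, u_um, v_um, intensity, attenuation_cm1`.
#'
#' @param volume A `virtual_volume`.
#' @param path Output CSV path.
#' @return `write_volume_csv()` returns `path` invisibly; `read_volume_csv()`
#'   returns a `virtual_volume` (thickness taken from `thickness` or inferred
#'   from the deepest cell).
#' @export
write_volume_csv <- function(volume, path) {
  utils::write.csv(
    as.data.frame(volume[c("id", "depth_um", "u_um", "v_um", "intensity", "attenuation_cm1")]),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_volume_csv
#' @param thickness Slab thickness in micrometres; inferred when `NULL`.
#' @export
read_volume_csv <- function(path, thickness = NULL) {
  cells <- tibble::as_tibble(utils::read.csv(path))
  need <- c("id", "depth_um", "u_um", "v_um", "intensity", "attenuation_cm1")
  if (!all(need %in% names(cells))) {
    rlang::abort(
      paste0("volume CSV must have columns: ", paste(need, collapse = ", ")),
      class = "cryosect_invalid_argument"
    )
  }
  new_virtual_volume(
    cells[need],
    thickness %||% ceiling(max(cells$depth_um)),
    "imported"
  )
}
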