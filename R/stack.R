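# Block-face image stacks: a grayscale volume (slices x rows x cols) with
# slice-thickness and pixel-size metadata, either rendered synthetically from
# a virtual volume or read from disk (multi-page TIFF + plain-text sidecar).

#' Construct an image stack
#'
#' @param voxels Numeric array `slices x rows x cols` of gray levels (>= 0).
#' @param slice_thickness Section thickness between consecutive block-faces,
#'   micrometres (> 0).
#' @param pixel_size Lateral pixel size, micrometres (> 0).
#' @param provenance Named list of generation parameters (seed, volume
#'   parameters, noise level, ...).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, slice_thickness, pixel_size,
                        provenance = list()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3) {
    rlang::abort("`voxels` must be a 3-D array (slices x rows x cols).",
      class = "cryosect_invalid_argument"
    )
  }
  if (any(voxels < 0)) {
    rlang::abort("`voxels` must be non-negative gray levels.",
      class = "cryosect_invalid_argument"
    )
  }
  check_positive(slice_thickness, "slice_thickness")
  check_positive(pixel_size, "pixel_size")
  structure(
    list(
      voxels = voxels,
      slice_thickness_um = as.numeric(slice_thickness),
      pixel_size_um = as.numeric(pixel_size),
      provenance = provenance
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %d slices x %d x %d px, X = %g um, pixel %g um\n",
    d[1], d[2], d[3], x$slice_thickness_um, x$pixel_size_um
  ))
  invisible(x)
}

#' Number of slices in a stack
#' @param stack An `image_stack`.
#' @return Integer slice count.
#' @export
n_slices <- function(stack) dim(stack$voxels)[1]

#' Render a synthetic block-face image stack from a virtual volume
#'
#' Emulates the slice-and-image acquisition: one image per block-face at
#' depths `0, X, 2X, ...` (`ceiling(S / X)` slices). Every cell not yet cut
#' away (block-face depth <= cell depth) contributes its Beer-Lambert surface
#' intensity at its lateral pixel; contributions at a shared pixel add. Once
#' the slab containing a cell is sectioned its signal disappears. A disc
#' footprint and additive Gaussian noise (clipped at 0) are optional.
#'
#' @param volume A `virtual_volume` with lateral positions.
#' @param slice_thickness Section thickness, micrometres (> 0).
#' @param pixel_size Lateral pixel size, micrometres (default 10).
#' @param background Constant background gray level (default 0).
#' @param noise_sd Additive Gaussian noise sd, gray level (default 0).
#' @param footprint_radius Cell footprint radius in pixels (default 0: a
#'   single pixel, matching the point-cell model).
#' @param seed Integer seed for the noise (optional).
#' @return An `image_stack` whose provenance records all parameters.
#' @examples
#' vol <- build_compliant_volume(100, 30, 314)
#' stk <- render_image_stack(vol, 20)
#' n_slices(stk) # 5
#' @export
render_image_stack <- function(volume, slice_thickness, pixel_size = 10,
                               background = 0, noise_sd = 0,
                               footprint_radius = 0, seed = NULL) {
  check_volume(volume)
  check_positive(slice_thickness, "slice_thickness")
  check_positive(pixel_size, "pixel_size")
  check_non_negative(background, "background")
  check_non_negative(noise_sd, "noise_sd")
  s_um <- volume_thickness(volume)
  n_sl <- ceiling(s_um / slice_thickness)
  ncol_px <- floor(max(volume$u_um) / pixel_size) + 1 + footprint_radius
  nrow_px <- floor(max(volume$v_um) / pixel_size) + 1 + footprint_radius
  vox <- array(background, dim = c(n_sl, nrow_px, ncol_px))
  col_px <- floor(volume$u_um / pixel_size) + 1L
  row_px <- floor(volume$v_um / pixel_size) + 1L
  offs <- footprint_offsets(footprint_radius)
  for (k in seq_len(n_sl)) {
    z <- (k - 1) * slice_thickness
    present <- volume$depth_um >= z
    if (!any(present)) next
    inten <- surface_intensity(
      volume$intensity[present],
      volume$attenuation_cm1[present],
      volume$depth_um[present] - z
    )
    rr <- row_px[present]
    cc <- col_px[present]
    for (o in seq_len(nrow(offs))) {
      r2 <- rr + offs$dr[o]
      c2 <- cc + offs$dc[o]
      ok <- r2 >= 1 & r2 <= nrow_px & c2 >= 1 & c2 <= ncol_px
      if (!any(ok)) next
      idx <- cbind(rep(k, sum(ok)), r2[ok], c2[ok])
      # accumulate: overlapping contributions at a shared pixel are summed
      for (j in seq_len(nrow(idx))) {
        vox[idx[j, 1], idx[j, 2], idx[j, 3]] <-
          vox[idx[j, 1], idx[j, 2], idx[j, 3]] + inten[ok][j]
      }
    }
  }
  if (noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(length(vox), 0, noise_sd))
    vox <- pmax(0, vox + noise)
    dim(vox) <- c(n_sl, nrow_px, ncol_px)
  }
  image_stack(
    vox, slice_thickness, pixel_size,
    provenance = list(
      generator = "render_image_stack",
      volume_kind = attr(volume, "kind"),
      n_cells = nrow(volume),
      volume_thickness_um = s_um,
      background = background,
      noise_sd = noise_sd,
      footprint_radius = footprint_radius,
      seed = seed %||% NA_integer_
    )
  )
}

footprint_offsets <- function(radius) {
  if (radius <= 0) {
    return(data.frame(dr = 0L, dc = 0L))
  }
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

#' Write / read an image stack as multi-page TIFF with a sidecar
#'
#' Voxels are written as 16-bit unsigned grayscale (values scaled by
#' `max_gray`, default 65535) with a YAML sidecar (`<path>.yml`) carrying
#' `slice_thickness_um`, `pixel_size_um`, `max_gray`, and the provenance.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @param max_gray Full-scale gray level used for 16-bit scaling.
#' @return `write_image_stack()` returns `path` invisibly;
#'   `read_image_stack()` returns an `image_stack`.
#' @export
write_image_stack <- function(stack, path, max_gray = 65535) {
  d <- dim(stack$voxels)
  pages <- purrr::map(seq_len(d[1]), function(k) {
    pmin(1, stack$voxels[k, , , drop = TRUE] / max_gray)
  })
  pages <- purrr::map(pages, function(m) {
    if (is.null(dim(m))) dim(m) <- d[2:3]
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    slice_thickness_um = stack$slice_thickness_um,
    pixel_size_um = stack$pixel_size_um,
    max_gray = max_gray,
    provenance = stack$provenance
  )
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_image_stack
#' @param meta_path Sidecar metadata path; defaults to `<path>.yml`.
#' @export
read_image_stack <- function(path, meta_path = paste0(path, ".yml")) {
  if (!file.exists(meta_path)) {
    rlang::abort(sprintf("missing stack metadata sidecar: %s", meta_path),
      class = "cryosect_missing_metadata"
    )
  }
  meta <- yaml::read_yaml(meta_path)
  for (field in c("slice_thickness_um", "pixel_size_um")) {
    if (is.null(meta[[field]])) {
      rlang::abort(sprintf("stack metadata is missing field `%s`.", field),
        class = "cryosect_missing_metadata"
      )
    }
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  max_gray <- meta$max_gray %||% 65535
  d2 <- dim(pages[[1]])
  vox <- array(0, dim = c(length(pages), d2[1], d2[2]))
  for (k in seq_along(pages)) vox[k, , ] <- pages[[k]] * max_gray
  image_stack(
    vox, meta$slice_thickness_um, meta$pixel_size_um,
    provenance = meta$provenance %||% list()
  )
}
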