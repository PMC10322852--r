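# Stack rendering, TIFF round trip, slice skipping, 3-D CCA counting, decay
# profiles and optical parameter estimation.

test_that("a rendered single cell decays per the attenuation law and then vanishes", {
  vol <- build_spaced_volume(100, 1, 200, 332) # one cell at depth 50
  stk <- render_image_stack(vol, 10)
  expect_equal(n_slices(stk), 10)
  px <- stk$voxels[, 1, 1]
  # slices 1..6 image block-faces 0..50: exponential decay in distance
  expect_equal(px[1:6], surface_intensity(200, 332, 50 - (0:5) * 10))
  # sectioned away after the slab containing the cell
  expect_equal(px[7:10], rep(0, 4))
  expect_true(all(diff(px[1:6]) > 0)) # brighter as the block-face approaches
})

test_that("rendered stacks have ceiling(S/X) slices and sum shared-pixel contributions", {
  vol <- build_compliant_volume(100, 30, 314)
  expect_equal(n_slices(render_image_stack(vol, 20)), 5)
  expect_equal(n_slices(render_image_stack(vol, 30)), 4)
  # two cells forced onto one pixel add their intensities
  v2 <- build_spaced_volume(40, 2, 100, 314, lateral_pitch = 0.001)
  stk <- render_image_stack(v2, 40, pixel_size = 10)
  expect_equal(
    stk$voxels[1, 1, 1],
    sum(surface_intensity(100, 314, c(10, 30)))
  )
})

test_that("image stacks round-trip through 16-bit TIFF with sidecar metadata", {
  vol <- build_compliant_volume(60, 300, 314)
  stk <- render_image_stack(vol, 10, noise_sd = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(stk, path)
  back <- read_image_stack(path)
  expect_equal(back$slice_thickness_um, 10)
  expect_equal(back$pixel_size_um, 10)
  expect_equal(back$voxels, stk$voxels, tolerance = 1) # 16-bit quantisation
  # missing sidecar is a hard error naming the file
  file.remove(paste0(path, ".yml"))
  expect_error(read_image_stack(path), class = "cryosect_missing_metadata")
})

test_that("slice skipping keeps every k-th slice and scales the thickness", {
  vol <- build_compliant_volume(100, 30, 314)
  stk <- render_image_stack(vol, 10)
  expect_identical(resample_stack(stk, 1)$voxels, stk$voxels)
  r2 <- resample_stack(stk, 2)
  expect_equal(n_slices(r2), 5)
  expect_equal(r2$slice_thickness_um, 20)
  expect_equal(r2$voxels[2, , ], stk$voxels[3, , ])
  r3 <- resample_stack(stk, 3)
  expect_equal(r3$slice_thickness_um, 30)
  expect_warning(resample_stack(stk, 50), "single slice")
})

test_that("threshold + 3-D CCA counts one component per cell", {
  vol <- build_compliant_volume(60, 30, 314)
  stk <- render_image_stack(vol, 10)
  comps <- detect_components(stk, 10)
  expect_equal(nrow(comps), 60) # subsurface tails merge per cell
  expect_true(all(comps$peak_intensity >= 10))
  # laterally distant cells stay separate; an empty stack yields none
  v2 <- build_spaced_volume(40, 2, 100, 314, lateral_pitch = 80)
  expect_equal(nrow(detect_components(render_image_stack(v2, 10), 10)), 2)
  empty <- image_stack(array(0, c(3, 4, 4)), 10, 10)
  expect_equal(nrow(detect_components(empty, 10)), 0)
  # 6-connectivity never merges more than 26-connectivity
  expect_gte(
    nrow(detect_components(stk, 10, connectivity = 6)),
    nrow(detect_components(stk, 10, connectivity = 26))
  )
})

test_that("render -> detect round trip recovers N below the optimal thickness", {
  vol <- build_compliant_volume(100, 30, 314)
  for (x in c(10, 20, 35)) {
    comps <- detect_components(render_image_stack(vol, x), 10)
    expect_equal(nrow(comps), 100)
  }
  expect_lt(nrow(detect_components(render_image_stack(vol, 50), 10)), 100)
})

test_that("skip-based sensitivity curve has nested counts and the analytic breakpoint", {
  vol <- build_compliant_volume(1000, 38, 314)
  stk <- render_image_stack(vol, 10)
  rep <- sensitivity_vs_skip(stk, 1:15, 10)
  expect_equal(rep$sensitivity[rep$skip == 1], 1)
  expect_true(all(diff(rep$count) <= 0)) # nesting for noiseless stacks
  # analytic optimum 42.52 um: full sensitivity holds through 40 um
  expect_equal(find_optimal_thickness(rep), 40)
  # sub-optimal tail tracks the piecewise prediction within 3%
  xo <- optimal_thickness(38, 314, 10)
  tail_pts <- rep[rep$sweep_value > 50, ]
  expect_true(all(abs(
    tail_pts$sensitivity - sensitivity_piecewise(tail_pts$sweep_value, xo)
  ) < 0.03))
  expect_error(sensitivity_vs_skip(stk, 2:5, 10), class = "cryosect_invalid_argument")
})

test_that("decay profiles follow the attenuation law and fit back exactly", {
  vol <- build_spaced_volume(200, 1, 300, 332) # one deep bright cell
  stk <- render_image_stack(vol, 10)
  comps <- detect_components(stk, 10)
  prof <- extract_decay_profile(stk, comps[1, ])
  expect_equal(diff(prof$depth_um), rep(10, nrow(prof) - 1))
  expect_true(all(diff(prof$intensity) < 0))
  expect_equal(
    prof$intensity,
    surface_intensity(max(prof$intensity), 332, prof$depth_um)
  )
  fit <- estimate_attenuation(prof)
  expect_equal(fit$attenuation_cm1, 332, tolerance = 1e-6)
  # a 372 profile built directly
  prof2 <- tibble::tibble(
    depth_um = seq(0, 60, 10),
    intensity = surface_intensity(87, 372, seq(0, 60, 10))
  )
  fit2 <- estimate_attenuation(prof2)
  expect_equal(fit2$attenuation_cm1, 372, tolerance = 1e-6)
  expect_equal(fit2$intensity_gray, 87, tolerance = 1e-6)
  expect_error(estimate_attenuation(prof2[1:2, ]), class = "cryosect_insufficient_data")
  short <- comps[1, ]
  short$first_slice <- short$last_slice - 1
  expect_error(extract_decay_profile(stk, short), class = "cryosect_insufficient_data")
})

test_that("attenuation estimates stay within 5% under multiplicative noise", {
  depths <- seq(0, 50, 10)
  clean <- surface_intensity(87, 372, depths)
  ests <- vapply(1:100, function(seed) {
    set.seed(seed)
    noisy <- clean * (1 + stats::rnorm(length(clean), 0, 0.05))
    estimate_attenuation(tibble::tibble(depth_um = depths, intensity = noisy))$attenuation_cm1
  }, numeric(1))
  expect_lt(abs(mean(ests) / 372 - 1), 0.05)
})

test_that("cell intensity estimate is the mean peak with bounded attenuation bias", {
  comps <- tibble::tibble(peak_intensity = c(30, 50))
  expect_equal(estimate_cell_intensity(comps), 40)
  expect_equal(estimate_cell_intensity(comps[2, ]), 50)
  # bin-centre cells: the brightest look sits at x = depth mod X, so the
  # estimate is biased low by at most the one-slab attenuation factor
  vol <- build_compliant_volume(200, 87, 372)
  est <- estimate_cell_intensity(detect_components(render_image_stack(vol, 20), 10))
  expect_lte(est, 87)
  expect_gte(est, 87 * exp(-372 * 20 * 1e-4))
  # cells exposed exactly at a block-face are recovered without bias
  one <- build_spaced_volume(40, 2, 87, 372)
  stk1 <- render_image_stack(one, 5) # faces at 0,5,...: depth 10 and 30 exposed
  expect_equal(
    estimate_cell_intensity(detect_components(stk1, 10)), 87,
    tolerance = 1e-9
  )
  expect_error(estimate_cell_intensity(comps[0, ]), class = "cryosect_insufficient_data")
})
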