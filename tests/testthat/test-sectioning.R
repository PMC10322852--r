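# Digital sectioning engine: agreement with the brute-force block-face
# oracle, sweep behaviour, breakpoints, overlap counting and slope fits.

test_that("digital sectioning agrees with the brute-force block-face oracle", {
  set.seed(21)
  for (i in 1:15) {
    s <- sample(80:300, 1)
    I <- runif(1, 12, 120)
    mu <- runif(1, 150, 500)
    x <- sample(5:120, 1)
    vol <- build_compliant_volume(s, I, mu)
    rep <- run_digital_sectioning(vol, x, 10)
    expect_equal(rep$n_detected, oracle_count(vol$depth_um, I, mu, x, 10))
    expect_equal(rep$n_detected + rep$n_missed, rep$n_true)
    expect_equal(rep$sensitivity, rep$n_detected / rep$n_true)
  }
})

test_that("ceiling identity holds when the slab is a multiple of the thickness", {
  # S = 140, X = 70: two full slabs of floor(34.99 + 0.5) = 35 detectable bins
  vol <- build_compliant_volume(140, 30, 314)
  rep <- run_digital_sectioning(vol, 70, 10)
  expect_equal(rep$sensitivity, 0.5)
  expect_equal(rep$n_detected, expected_count(35, 70, 140))
  # S = 150, X = 70: the 10-um remainder slab is fully detectable, so the
  # count exceeds the ceiling formula by the edge effect
  rep2 <- run_digital_sectioning(build_compliant_volume(150, 30, 314), 70, 10)
  expect_equal(rep2$n_detected, 80L)
})

test_that("compliant sensitivity is perfect up to the optimal thickness", {
  vol <- build_compliant_volume(150, 30, 314)
  expect_equal(run_digital_sectioning(vol, 20, 10)$sensitivity, 1)
  for (x in c(5, 10, 35)) {
    expect_equal(run_digital_sectioning(vol, x, 10)$sensitivity, 1)
  }
  expect_lt(run_digital_sectioning(vol, 36, 10)$sensitivity, 1)
  # all cells dimmer than the threshold: nothing detected
  dim_vol <- build_compliant_volume(50, 30, 314)
  expect_equal(run_digital_sectioning(dim_vol, 20, 40)$sensitivity, 0)
})

test_that("thickness sweeps are non-increasing with breakpoint at the discrete optimum", {
  for (I in c(30, 50, 80)) {
    vol <- build_compliant_volume(150, I, 314)
    curve <- sweep_thickness(vol, 5:150, 10)
    expect_true(all(diff(curve$sensitivity) <= 0))
    expect_equal(
      find_optimal_thickness(curve),
      discrete_optimal_thickness(I, 314, 10)
    )
  }
  # sub-optimal tail tracks the piecewise relationship within discretisation
  vol <- build_compliant_volume(1000, 30, 314)
  curve <- sweep_thickness(vol, seq(40, 150, 10), 10)
  xo <- optimal_thickness(30, 314, 10)
  pred <- sensitivity_piecewise(curve$sweep_value, xo)
  # 1/N per point plus the remainder-slab edge effect (< one extra bin set)
  expect_true(all(abs(curve$sensitivity - pred) <= 35 / 1000 + 1 / 1000))
})

test_that("find_optimal_thickness errors when nothing reaches the criterion", {
  vol <- build_compliant_volume(150, 30, 314)
  curve <- sweep_thickness(vol, seq(50, 150, 10), 10)
  expect_error(find_optimal_thickness(curve), class = "cryosect_not_found")
  expect_error(find_optimal_thickness(sweep_intensity(20, 1:5, 314, 10, 50)),
    class = "cryosect_invalid_argument"
  )
})

test_that("intensity sweeps rise from zero below threshold to one at the optimum", {
  curve <- sweep_intensity(20, 1:30, 314, 10, 150)
  expect_true(all(curve$sensitivity[curve$sweep_value < 10] == 0))
  expect_true(all(diff(curve$sensitivity) >= 0))
  i_opt <- optimal_intensity(10, 314, 20) # 18.74
  reached <- curve$sweep_value[curve$sensitivity == 1]
  expect_equal(min(reached), ceiling(i_opt))
})

test_that("overlap counting resolves everything at 1 um and reduces to identity when sparse", {
  ov <- build_overlap_volume(1000, 400, 1, 40, 314, seed = 7)
  expect_equal(run_overlap_sectioning(ov, 1, 10)$sensitivity, 1)
  # compliant volumes have unique lateral columns: both rules agree exactly
  vol <- build_compliant_volume(150, 30, 314)
  for (x in c(10, 40, 70)) {
    expect_equal(
      run_overlap_sectioning(vol, x, 10)$n_detected,
      run_digital_sectioning(vol, x, 10)$n_detected
    )
  }
})

test_that("higher density lowers overlap sensitivity at fixed thickness", {
  mean_sens <- function(density, x) {
    mean(vapply(1:10, function(sd) {
      run_overlap_sectioning(
        build_overlap_volume(1000, density, 1, 40, 314, seed = sd), x, 10
      )$sensitivity
    }, numeric(1)))
  }
  s400 <- mean_sens(400, 30)
  s800 <- mean_sens(800, 30)
  s1600 <- mean_sens(1600, 30)
  expect_gt(s400, s800)
  expect_gt(s800, s1600)
})

test_that("perturbation never raises mean sensitivity at fixed thickness", {
  mean_sens <- function(sigma_i, sigma_mu, x) {
    mean(vapply(1:10, function(sd) {
      vol <- build_compliant_volume(500, 40, 314)
      if (sigma_i > 0) vol <- perturb_intensity(vol, sigma_i, seed = sd)
      if (sigma_mu > 0) vol <- perturb_attenuation(vol, sigma_mu, seed = sd + 100)
      run_digital_sectioning(vol, x, 10)$sensitivity
    }, numeric(1)))
  }
  base <- mean_sens(0, 0, 40)
  for (sg in c(5, 10, 15)) expect_lte(mean_sens(sg, 0, 40), base + 0.01)
  for (sg in c(50, 100)) expect_lte(mean_sens(0, sg, 40), base + 0.01)
})

test_that("log-log slope fit recovers -1 on an exact reciprocal curve", {
  xo <- 42.5
  xs <- seq(50, 150, 10)
  curve <- cryosect:::new_sensitivity_curve(
    tibble::tibble(
      sweep_value = xs, count = NA_integer_, n_true = NA_integer_,
      sensitivity = sensitivity_piecewise(xs, xo)
    ),
    "thickness"
  )
  fit <- fit_loglog_slope(curve, c(45, 150))
  expect_equal(fit$slope, -1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_loglog_slope(curve, c(140, 150)),
    class = "cryosect_invalid_argument"
  ) # too few points
})

test_that("replicated sweeps stack and summarise per thickness", {
  curve <- sweep_replicates(
    function(sd) perturb_intensity(build_compliant_volume(200, 40, 314), 10, seed = sd),
    c(20, 60, 100), 10,
    seeds = 1:4
  )
  expect_equal(nrow(curve), 12)
  sm <- summarise_sweep(curve)
  expect_equal(sm$n_replicates, rep(4L, 3))
  expect_true(all(sm$sensitivity_sd >= 0, na.rm = TRUE))
})

test_that("detection reports tidy and glance cleanly", {
  rep <- run_digital_sectioning(build_compliant_volume(50, 30, 314), 20, 10)
  td <- tidy(rep)
  expect_equal(nrow(td), 50)
  expect_true(all(c("id", "depth_um", "detected", "first_face", "last_face") %in% names(td)))
  gl <- glance(rep)
  expect_equal(gl$n_true, 50)
  expect_equal(gl$sensitivity, 1)
})
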