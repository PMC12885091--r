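test_that("noise-free MESI fits recover the generating parameters", {
  grid <- make_exposure_grid(100)
  vc <- visibility_curve(grid, flow_state(1.5e-8, 0.35))
  fit <- fit_mesi(vc)
  expect_true(fit$converged)
  expect_equal(fit$bfi_hat, 1.5e-8, tolerance = 1e-6)
  expect_equal(fit$beta_hat, 0.35, tolerance = 1e-6)
  # random truths across the parameter box
  set.seed(21)
  for (i in 1:6) {
    f <- runif(1, 0.5e-8, 2e-8); be <- runif(1, 0.1, 0.5)
    fit <- fit_mesi(visibility_curve(grid, flow_state(f, be)))
    expect_equal(fit$bfi_hat, f, tolerance = 1e-5)
    expect_equal(fit$beta_hat, be, tolerance = 1e-5)
  }
})

test_that("MESI estimates beta freely, so mismatch cannot bias it", {
  grid <- make_exposure_grid(100)
  for (be in seq(0.1, 0.5, by = 0.1)) {
    fit <- fit_mesi(visibility_curve(grid, flow_state(1e-8, be)))
    expect_equal(fit$beta_hat, be, tolerance = 1e-5)
    expect_equal(fit$bfi_hat, 1e-8, tolerance = 1e-5)
  }
})

test_that("MESI flags degenerate and invalid inputs", {
  flat <- structure(list(exposures = make_exposure_grid(50),
                         k2 = rep(0.5, 50)), class = "visibility_curve")
  fit <- fit_mesi(flat)
  expect_true(fit$degenerate || !fit$converged)
  bad <- structure(list(exposures = c(1e-4, 1e-3, 5e-3),
                        k2 = c(0.3, NA, 0.1)), class = "visibility_curve")
  expect_error(fit_mesi(bad), "non-finite")
  two <- structure(list(exposures = c(1e-4, 1e-3), k2 = c(0.4, 0.2)),
                   class = "visibility_curve")
  expect_error(fit_mesi(two), "at least 3")
})

test_that("look-up table has the documented shape and structure", {
  lut <- build_lut(default_optics)
  expect_equal(dim(lut$k2), c(3, 51, 790))
  expect_equal(length(lut$bfi_grid), 790)
  expect_equal(mean(diff(lut$bfi_grid)), 1.0013e-10, tolerance = 1e-4)
  expect_equal(lut$beta_grid, seq(0, 0.5, by = 0.01))
  expect_true(all(lut$k2[, 1, ] == 0))          # beta = 0 slice
  # monotone decreasing in BFI for every (exposure, beta > 0) slice
  for (e in 1:3)
    expect_true(all(apply(lut$k2[e, -1, ], 1, diff) < 0))
})

test_that("LUT inversion round-trips and matches a bisection root solve", {
  lut <- build_lut(default_optics)
  spacing <- diff(lut$bfi_grid[1:2])
  k2 <- k2_model(1e-3, 1.5e-8, 0.5, default_optics)
  est <- invert_lut(lut, data.frame(exposure = 1e-3, k2 = k2), 0.5)
  expect_equal(as.numeric(est), 1.5e-8, tolerance = spacing / 1.5e-8)
  expect_false(attr(est, "extrapolated"))
  set.seed(31)
  for (i in 1:10) {
    Te <- sample(c(1e-4, 1e-3, 5e-3), 1)
    f_true <- runif(1, 0.2e-8, 7.5e-8)
    k2 <- k2_model(Te, f_true, 0.5, default_optics)
    est <- invert_lut(lut, data.frame(exposure = Te, k2 = k2), 0.5)
    expect_equal(as.numeric(est),
                 oracle_invert_bisect(Te, k2, 0.5),
                 tolerance = 2 * spacing / f_true)
  }
})

test_that("LUT inversion extrapolates (flagged) outside the calibrated range", {
  lut <- build_lut(default_optics)
  hi <- max(lut$k2[2, 51, ])   # K^2 of slowest tabulated flow at 1 ms
  est <- invert_lut(lut, data.frame(exposure = 1e-3, k2 = hi * 1.5), 0.5)
  expect_true(attr(est, "extrapolated"))
  lo <- min(lut$k2[2, 51, ])
  est2 <- invert_lut(lut, data.frame(exposure = 1e-3, k2 = lo / 2), 0.5)
  expect_true(attr(est2, "extrapolated"))
  expect_true(est2 > max(lut$bfi_grid))
  # non-positive measurements still invert (wildly), flagged, never an error
  est3 <- invert_lut(lut, data.frame(exposure = 1e-3, k2 = -0.01), 0.5)
  expect_true(attr(est3, "extrapolated"))
  expect_error(invert_lut(lut, data.frame(exposure = 2e-3, k2 = 0.1), 0.5),
               "not tabulated")
  expect_warning(invert_lut(lut, data.frame(exposure = 1e-3, k2 = 0.1),
                            0.503), "snapping")
  expect_error(invert_lut(lut, data.frame(exposure = 1e-3, k2 = 0.1), 0),
               "beta = 0")
})

test_that("SCOS and SPG follow their reciprocal-contrast formulas", {
  expect_equal(estimate_scos(c(0.25, 0.5)), c(4, 2))
  sm <- data.frame(exposure = c(1e-3, 1e-3), k2 = c(0.25, 0.5))
  expect_equal(estimate_spg(sm), c(2000, 1000))
  expect_true(is.na(estimate_scos(-0.1)))
  expect_true(is.na(estimate_spg(data.frame(exposure = 1e-3, k2 = 0))))
  expect_error(estimate_spg(data.frame(exposure = 0, k2 = 0.5)), "positive")
})

test_that("SPG and SCOS report exactly the same relative changes", {
  sm_base <- data.frame(exposure = c(1e-4, 1e-3, 5e-3),
                        k2 = c(0.31, 0.12, 0.04))
  sm_new <- data.frame(exposure = c(1e-4, 1e-3, 5e-3),
                       k2 = c(0.26, 0.08, 0.022))
  # the 1/(2T) prefactor cancels per exposure
  expect_equal(estimate_spg(sm_new) / estimate_spg(sm_base),
               estimate_scos(sm_new) / estimate_scos(sm_base),
               tolerance = 1e-14)
})

test_that("relative change is a plain percent difference", {
  expect_equal(relative_change(0.5e-8, 1e-8), -50)
  expect_equal(relative_change(1e-8, 1e-8), 0)
  expect_equal(relative_change(2e-8, 1e-8), 100)
  expect_equal(relative_change(c(1, 3), 2), c(-50, 50))
  expect_error(relative_change(1, 0), "non-zero")
  expect_error(relative_change(1, NaN), "non-zero")
})

test_that("the LUT survives a text round trip", {
  lut <- build_lut(default_optics, n_bfi = 25L, beta_step = 0.1)
  path <- tempfile(fileext = ".tsv")
  write_lut(lut, path)
  back <- read_lut(path)
  expect_equal(back$k2, lut$k2)
  expect_equal(back$bfi_grid, lut$bfi_grid)
  expect_equal(back$optics$mu_a, lut$optics$mu_a)
})
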