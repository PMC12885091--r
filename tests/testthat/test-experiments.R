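# Experiment drivers exercised at small Monte-Carlo sizes; the quantitative
# behaviour at the study's full conditions is covered by test-acceptance.R.

small_lut <- build_lut(optical_properties())

test_that("experiments are exactly reproducible from (config, seed)", {
  a <- run_noise_comparison(n_trials = 3L, n_exposures = 60L,
                            alphas = c(0, 0.1), seed = 5L, lut = small_lut)
  b <- run_noise_comparison(n_trials = 3L, n_exposures = 60L,
                            alphas = c(0, 0.1), seed = 5L, lut = small_lut)
  expect_identical(a, b)
  c2 <- run_noise_comparison(n_trials = 3L, n_exposures = 60L,
                             alphas = c(0, 0.1), seed = 6L, lut = small_lut)
  expect_false(identical(a, c2))
})

test_that("noise-comparison output is balanced and SCOS equals SPG exactly", {
  out <- run_noise_comparison(n_trials = 4L, n_exposures = 60L,
                              alphas = c(0, 0.1), seed = 2L, lut = small_lut)
  # 4 methods x 2 alphas x (3 scenarios + average)
  expect_equal(nrow(out), 4 * 2 * 4)
  scos <- subset(out, method == "SCOS")
  spg <- subset(out, method == "SPG")
  expect_equal(scos$mean, spg$mean, tolerance = 1e-12)
  expect_equal(scos$max, spg$max, tolerance = 1e-12)
  # noise-free MESI and LUT recover changes with near-zero bias
  nf <- subset(out, alpha == 0 & scenario == "average")
  expect_lt(nf$mean[nf$method == "MESI"], 0.01)
  expect_lt(nf$mean[nf$method == "LUT"], 0.01)
})

test_that("beta-mismatch driver isolates the matched, noise-free identity", {
  out <- run_beta_mismatch(beta_true = 0.5, alphas = 0, n_trials = 1L,
                           n_exposures = 60L, seed = 3L, lut = small_lut)
  lut_rows <- subset(out$bfi_error, method == "LUT")
  # matched beta, no noise: error below the one-grid-spacing equivalent
  expect_true(all(lut_rows$mean < 100 * 1.1e-10 / 0.5e-8))
  mesi_rows <- subset(out$bfi_error, method == "MESI")
  expect_true(all(mesi_rows$mean < 1e-3))
  ce <- subset(out$change_error, beta_true == 0.5)
  expect_true(all(ce$error < 0.01))
})

test_that("beta mismatch biases the LUT but not MESI, even without noise", {
  out <- run_beta_mismatch(beta_true = c(0.3, 0.5), alphas = 0,
                           n_trials = 1L, n_exposures = 60L, seed = 3L,
                           lut = small_lut)
  mism <- subset(out$bfi_error, beta_true == 0.3)
  expect_true(all(mism$mean[mism$method == "LUT"] > 5))
  expect_true(all(mism$mean[mism$method == "MESI"] < 1e-3))
  ce <- subset(out$change_error, scenario == "average" & is.na(exposure))
  expect_gt(ce$error[ce$beta_true == 0.3], ce$error[ce$beta_true == 0.5])
})

test_that("exposure-reduction driver reports balanced summaries", {
  out <- run_exposure_reduction(counts = c(60L, 15L), alphas = 0.01,
                                n_realizations = 5L, seed = 9L)
  expect_equal(nrow(out), 2 * 4 * 1)
  expect_true(all(out$n == 5))
  expect_true(all(out$mean >= out$min & out$mean <= out$max))
})

test_that("noise-free pulsatile recovery separates exact from proxy methods", {
  ps <- pulsatile_waveform(duration = 2, rate = 10, seed = 8)
  out <- run_pulsatile(ps, alpha = 0, n_trials = 1L, n_exposures = 100L,
                       seed = 1L, lut = small_lut)
  # model-based inversions reproduce the waveform
  for (m in c("MESI", "LUT0.5", "LUT0.45")) {
    dev <- max_tracking_error(out$recovered[[m]], out$truth)$average_max
    expect_lt(dev, 0.5)
  }
  # reciprocal-contrast proxies carry a deterministic dynamic-range
  # compression: systolic peaks are underestimated even without noise
  i_peak <- which.max(out$truth)
  expect_lt(out$recovered$SCOS[1, i_peak], out$truth[i_peak])
  expect_equal(out$recovered$SCOS, out$recovered$SPG, tolerance = 1e-12)
  # and the compression is bounded for the 2x peak waveform
  expect_lt(max_tracking_error(out$recovered$SCOS, out$truth)$average_max, 10)
})
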