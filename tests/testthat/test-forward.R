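test_that("effective reflection coefficient matches the boundary polynomial", {
  # hand evaluation: -1.440 + 0.710 + 0.668 + 0.0636 at n_rel = 1
  expect_equal(effective_reflection(1), 0.0016, tolerance = 1e-12)
  # hand evaluation at the tissue/air default ratio 1.4
  expect_equal(effective_reflection(1.4), 0.52948898, tolerance = 1e-7)
  expect_error(effective_reflection(0.9), "n_rel")
})

test_that("optical properties validate inputs and derive boundary geometry", {
  op <- default_optics
  expect_equal(op$z0, 0.1)
  expect_equal(op$k0, 2 * pi * 1.4 / 785e-7)
  expect_true(op$R_eff >= 0 && op$R_eff < 1)
  expect_equal(op$zb, 2 * (1 + op$R_eff) / (3 * 10 * (1 - op$R_eff)))
  expect_equal(op$r1, sqrt(9 + 0.01))
  expect_equal(op$rb, sqrt(9 + (0.1 + 2 * op$zb)^2))
  expect_error(optical_properties(mu_a = -1), "positive")
  expect_error(optical_properties(n_tissue = 1.0, n_medium = 1.4),
               "n_tissue >= n_medium")
})

test_that("g1 is normalized, monotone, and matches its closed form", {
  fs <- flow_state(1e-8, 0.5)
  expect_identical(g1(0, fs), 1)
  # independent closed-form evaluation frozen as the oracle
  expect_equal(g1(1e-4, fs), oracle_g1(1e-4, 1e-8), tolerance = 1e-12)
  expect_equal(oracle_g1(1e-4, 1e-8), 0.01783597, tolerance = 1e-6)
  taus <- 10^seq(-6, -3, length.out = 20)
  expect_true(all(diff(g1(taus, fs)) < 0))
  # faster flow decorrelates faster at any fixed positive lag
  expect_true(all(g1(taus, flow_state(2e-8, 0.5)) < g1(taus, fs)))
  expect_error(g1(-1e-5, fs), "non-negative")
})

test_that("speckle variance obeys its structural limits", {
  fs <- flow_state(1e-8, 0.5)
  # short-exposure limit K^2 -> beta
  expect_equal(speckle_variance(1e-9, fs), 0.5, tolerance = 1e-4)
  # beta is an exact multiplicative prefactor
  Ts <- c(1e-4, 1e-3, 5e-3)
  k2_b1 <- speckle_variance(Ts, flow_state(1e-8, 1))
  for (be in c(0.1, 0.3, 0.5))
    expect_equal(speckle_variance(Ts, flow_state(1e-8, be)) / be, k2_b1,
                 tolerance = 1e-12)
  # monotone non-increasing in T and in F across the parameter box
  grid <- 10^seq(-5, -2, length.out = 30)
  for (f in c(0.5, 2) * 1e-8) {
    k2 <- speckle_variance(grid, flow_state(f, 0.5))
    expect_true(all(diff(k2) < 0))
    expect_true(all(k2 > 0 & k2 <= 0.5))
  }
  flows <- c(0.5, 1, 1.5, 2) * 1e-8
  k2f <- sapply(flows, function(f) speckle_variance(Ts, flow_state(f, 0.5)))
  expect_true(all(apply(k2f, 1, diff) < 0))
  expect_error(speckle_variance(-1e-3, fs), "positive")
})

test_that("fast vectorized model agrees with adaptive quadrature", {
  Ts <- 10^seq(-5, -2, length.out = 15)
  set.seed(11)
  for (i in 1:10) {
    f <- runif(1, 0.1e-8, 8e-8)
    be <- runif(1, 0.05, 1)
    expect_equal(k2_model(Ts, f, be, default_optics),
                 speckle_variance(Ts, flow_state(f, be), default_optics),
                 tolerance = 1e-10)
  }
})

test_that("exposure grids are log-spaced with exact endpoints", {
  expect_equal(as.numeric(make_exposure_grid(3, 1e-5, 1e-3)),
               c(1e-5, 1e-4, 1e-3))
  g <- make_exposure_grid(10000, 1e-5, 1e-2)
  expect_identical(g[1], 1e-5)
  expect_identical(g[10000], 1e-2)
  expect_true(!is.unsorted(g, strictly = TRUE))
  expect_error(make_exposure_grid(1, 1e-5, 1e-2), ">= 2")
  expect_error(make_exposure_grid(10, 1e-2, 1e-5), "t_min < t_max")
})

test_that("visibility curves start near beta and never cross in flow", {
  grid <- make_exposure_grid(60)
  curves <- lapply(c(0.5, 1, 1.5, 2) * 1e-8, function(f)
    visibility_curve(grid, flow_state(f, 0.5)))
  k2 <- sapply(curves, `[[`, "k2")
  # the first (shortest-exposure) value is the largest and bounded by beta
  expect_true(all(k2[1, ] == apply(k2, 2, max)))
  expect_true(all(k2[1, ] < 0.5))
  # and approaches beta as the grid start moves toward zero exposure
  tiny <- visibility_curve(make_exposure_grid(5, 1e-9, 1e-8),
                           flow_state(1e-8, 0.5))
  expect_equal(tiny$k2[1], 0.5, tolerance = 2e-4)
  expect_true(all(apply(k2, 2, diff) < 0))     # non-increasing in T
  expect_true(all(apply(k2, 1, diff) < 0))     # ordered in F at every T
  expect_identical(curves[[1]]$noise_level, 0)
  expect_equal(curves[[1]]$truth$bfi, 0.5e-8)
})

test_that("visibility curves survive a text round trip", {
  vc <- visibility_curve(make_exposure_grid(20), flow_state(1.5e-8, 0.35))
  path <- tempfile(fileext = ".tsv")
  write_visibility_curve(vc, path)
  back <- read_visibility_curve(path)
  expect_equal(back$exposures, vc$exposures)
  expect_equal(back$k2, vc$k2)
  expect_equal(back$truth$bfi, 1.5e-8)
  expect_equal(back$truth$beta, 0.35)
  expect_equal(back$optics$rho, 3)
})

test_that("optics configs load from YAML and JSON", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("mu_a: 0.2", "rho: 2.5"), yml)
  op <- read_optics_config(yml)
  expect_equal(op$mu_a, 0.2)
  expect_equal(op$rho, 2.5)
  expect_equal(op$mu_s_prime, 10)  # default retained
  jsn <- tempfile(fileext = ".json")
  writeLines('{"n_tissue": 1.33, "n_medium": 1.0}', jsn)
  expect_equal(read_optics_config(jsn)$n_tissue, 1.33)
  expect_warning(read_optics_config({
    f <- tempfile(fileext = ".yaml"); writeLines("bogus: 1", f); f
  }), "unknown")
})
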