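#' Multi-exposure speckle imaging fit (MESI)
#'
#' Jointly estimates the blood flow index and the speckle averaging factor
#' by unconstrained Nelder-Mead minimization of the plain sum of squared
#' residuals between a measured visibility curve and the semi-infinite
#' speckle-variance model,
#' \deqn{\mathrm{SSE}(F, \beta) = \sum_T \left[K^2_{model}(T; F, \beta)
#'       - K^2_{meas}(T)\right]^2.}
#'
#' The simplex works on `(F / 1e-8, beta)` so both coordinates are O(1); the
#' model is evaluated with `|F|` and `beta` clipped to `(1e-6, 1]` so the
#' objective stays defined everywhere. After the first minimization the
#' simplex is restarted once from the solution (configurable), which removes
#' the occasional premature termination on the shallow `(F, beta)` valley.
#'
#' @param curve a `visibility_curve`, or anything with `$exposures` and
#'   `$k2` (at least 3 points).
#' @param optics an [optical_properties()] object.
#' @param init_bfi,init_beta initial guesses (defaults: mid-range flow
#'   1e-8 cm^2/s, beta 0.5).
#' @param restarts number of simplex restarts from the incumbent solution.
#' @param max_iter Nelder-Mead iteration cap per (re)start.
#' @param rel_tol relative convergence tolerance of the simplex.
#' @return An object of class `mesi_fit`: list with `bfi_hat`, `beta_hat`,
#'   `sse`, `converged`, `n_iter`, and `degenerate` (`TRUE` when the
#'   solution ran into the clipping bounds or a vanishing flow, as happens
#'   for structurally uninformative input such as a constant curve).
#' @examples
#' vc <- visibility_curve(make_exposure_grid(100), flow_state(1.5e-8, 0.35))
#' fit <- fit_mesi(vc)
#' c(fit$bfi_hat, fit$beta_hat)
#' @export
fit_mesi <- function(curve, optics = optical_properties(),
                     init_bfi = 1e-8, init_beta = 0.5,
                     restarts = 1L, max_iter = 2000L, rel_tol = 1e-9) {
  Ts <- curve$exposures
  k2 <- curve$k2
  if (length(Ts) < 3L)
    stop("MESI needs at least 3 exposures (2 free parameters)")
  if (any(!is.finite(Ts)) || any(!is.finite(k2)))
    stop("curve contains non-finite values")
  obj <- function(p) {
    f <- abs(p[1]) * 1e-8
    be <- min(max(p[2], 1e-6), 1)
    k2_sse_cpp(Ts, k2, f, be, optics$mu_a, optics$mu_s_prime, optics$k0,
               optics$r1, optics$rb, gl_nodes$x, gl_nodes$w)
  }
  p <- c(init_bfi / 1e-8, init_beta)
  n_iter <- 0L
  conv <- 1L
  for (k in 0:max(0L, restarts)) {
    o <- stats::optim(p, obj, method = "Nelder-Mead",
                      control = list(reltol = rel_tol, maxit = max_iter))
    p <- o$par
    n_iter <- n_iter + o$counts[["function"]]
    conv <- o$convergence
  }
  bfi_hat <- abs(p[1]) * 1e-8
  beta_raw <- p[2]
  beta_hat <- min(max(beta_raw, 1e-6), 1)
  degenerate <- beta_raw <= 1e-6 || beta_raw > 1 || bfi_hat < 1e-12
  structure(list(bfi_hat = bfi_hat, beta_hat = beta_hat,
                 sse = o$value, converged = conv == 0L && !degenerate,
                 n_iter = as.integer(n_iter), degenerate = degenerate),
            class = "mesi_fit")
}

#' @export
print.mesi_fit <- function(x, ...) {
  cat(sprintf("MESI fit: BFI = %.6g cm^2/s, beta = %.4f (SSE %.3g, %s, %d evals)\n",
              x$bfi_hat, x$beta_hat, x$sse,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Build a single-exposure look-up table K^2(exposure, beta, BFI)
#'
#' Tabulates the forward model on a dense `(BFI, beta)` grid at a few fixed
#' exposures, for direct inversion of single-exposure speckle contrast.
#' Because the model is exactly proportional to `beta`, the table is filled
#' from the unit-beta profile; each `(exposure, beta > 0)` slice is verified
#' to be strictly decreasing in BFI so the inversion is unique.
#'
#' @param optics an [optical_properties()] object.
#' @param exposures the single-exposure durations, seconds.
#' @param bfi_range range of tabulated flows, cm^2/s.
#' @param n_bfi number of (uniform) flow grid points.
#' @param beta_max,beta_step the beta grid runs from 0 to `beta_max` in
#'   steps of `beta_step`.
#' @return An object of class `speckle_lut` with fields `exposures`,
#'   `bfi_grid`, `beta_grid`, `k2` (array exposure x beta x BFI) and
#'   `optics`.
#' @export
build_lut <- function(optics = optical_properties(),
                      exposures = c(1e-4, 1e-3, 5e-3),
                      bfi_range = c(0.1e-8, 8e-8), n_bfi = 790L,
                      beta_max = 0.5, beta_step = 0.01) {
  stopifnot(is_optics(optics), length(exposures) >= 1L,
            all(exposures > 0), n_bfi >= 2L)
  bfi_grid <- seq(bfi_range[1], bfi_range[2], length.out = n_bfi)
  beta_grid <- seq(0, beta_max, by = beta_step)
  # unit-beta profile h(T, F); K^2 = beta * h
  h <- vapply(bfi_grid,
              function(f) k2_model(exposures, f, 1, optics),
              numeric(length(exposures)))
  h <- matrix(h, nrow = length(exposures))  # exposures x bfi
  for (i in seq_along(exposures)) {
    if (any(diff(h[i, ]) >= 0))
      stop("LUT build: K^2 not strictly decreasing in BFI at exposure ",
           exposures[i], " s")
  }
  k2 <- outer(h, beta_grid)              # exposures x bfi x beta
  k2 <- aperm(k2, c(1, 3, 2))            # exposures x beta x bfi
  structure(list(exposures = exposures, bfi_grid = bfi_grid,
                 beta_grid = beta_grid, k2 = k2, optics = optics),
            class = "speckle_lut")
}

#' @export
print.speckle_lut <- function(x, ...) {
  cat(sprintf("Speckle LUT: %d exposures x %d beta x %d BFI values\n",
              length(x$exposures), length(x$beta_grid), length(x$bfi_grid)))
  cat(sprintf("  exposures: %s s\n", paste(x$exposures, collapse = ", ")))
  cat(sprintf("  BFI %g..%g cm^2/s, beta 0..%g step %g\n",
              min(x$bfi_grid), max(x$bfi_grid), max(x$beta_grid),
              x$beta_grid[2] - x$beta_grid[1]))
  invisible(x)
}

#' Invert single-exposure speckle contrast through the look-up table
#'
#' Maps measured `K^2` values to BFI by piecewise-linear interpolation of
#' the monotone `K^2 -> BFI` relation at the requested exposure and assumed
#' beta. Measurements outside the tabulated `K^2` range are linearly
#' extrapolated from the nearest two grid nodes; this can produce wildly
#' wrong flows (including negative ones) under strong noise, which is the
#' documented failure mode of single-exposure inversion, so extrapolated
#' results are flagged rather than clamped.
#'
#' @param lut a [build_lut()] result.
#' @param samples a `single_exposure_samples` data frame (or any data frame
#'   with `exposure` and `k2` columns).
#' @param beta_assumed the beta assumed for inversion; snapped to the
#'   nearest beta grid node (with a warning if not already on the grid).
#' @return Numeric vector of BFI estimates with attribute `extrapolated`
#'   (logical vector marking out-of-range inversions).
#' @export
invert_lut <- function(lut, samples, beta_assumed = 0.5) {
  stopifnot(inherits(lut, "speckle_lut"))
  ib <- which.min(abs(lut$beta_grid - beta_assumed))
  if (abs(lut$beta_grid[ib] - beta_assumed) > 1e-9) {
    warning("beta_assumed = ", beta_assumed,
            " is not on the beta grid; snapping to ", lut$beta_grid[ib])
  }
  if (lut$beta_grid[ib] == 0)
    stop("cannot invert at beta = 0 (K^2 identically zero)")
  n <- nrow(samples)
  out <- numeric(n)
  extrap <- logical(n)
  for (s in seq_len(n)) {
    ie <- which(abs(lut$exposures - samples$exposure[s]) <=
                  1e-9 * samples$exposure[s])
    if (length(ie) != 1L)
      stop("exposure ", samples$exposure[s], " s is not tabulated in the LUT")
    kk <- lut$k2[ie, ib, ]               # decreasing in BFI
    x <- samples$k2[s]
    m <- length(kk)
    if (x > kk[1]) {                     # slower than slowest tabulated flow
      out[s] <- lut$bfi_grid[1] +
        (x - kk[1]) * (lut$bfi_grid[2] - lut$bfi_grid[1]) / (kk[2] - kk[1])
      extrap[s] <- TRUE
    } else if (x < kk[m]) {              # faster than fastest tabulated flow
      out[s] <- lut$bfi_grid[m] +
        (x - kk[m]) * (lut$bfi_grid[m] - lut$bfi_grid[m - 1]) /
          (kk[m] - kk[m - 1])
      extrap[s] <- TRUE
    } else {
      out[s] <- stats::approx(rev(kk), rev(lut$bfi_grid), xout = x)$y
    }
  }
  attr(out, "extrapolated") <- extrap
  out
}

#' Single-exposure flow estimators: SCOS and SPG
#'
#' SCOS proxies the blood flow index by the reciprocal speckle variance,
#' `BFI = 1 / K^2` (arbitrary units). SPG uses `BFI = 1 / (2 T K^2)`
#' (arbitrary units); the `1/(2T)` prefactor cancels in any relative-change
#' calculation at a fixed exposure, so SCOS and SPG report identical
#' relative flow changes. Non-positive `K^2` values (possible under strong
#' multiplicative noise) yield `NA`, to be excluded and counted downstream.
#'
#' @param samples a `single_exposure_samples` data frame (or any data frame
#'   with `exposure` and `k2` columns; `estimate_scos` also accepts a bare
#'   numeric vector of `K^2` values).
#' @return Numeric vector of flow estimates in arbitrary units.
#' @examples
#' estimate_scos(c(0.25, 0.5))  # 4, 2
#' @export
estimate_scos <- function(samples) {
  k2 <- if (is.numeric(samples)) samples else samples$k2
  out <- ifelse(is.finite(k2) & k2 > 0, 1 / k2, NA_real_)
  as.numeric(out)
}

#' @rdname estimate_scos
#' @export
estimate_spg <- function(samples) {
  if (is.numeric(samples))
    stop("estimate_spg needs exposures; pass a data frame with ",
         "'exposure' and 'k2' columns")
  if (any(samples$exposure <= 0)) stop("exposures must be positive")
  k2 <- samples$k2
  out <- ifelse(is.finite(k2) & k2 > 0,
                1 / (2 * samples$exposure * k2), NA_real_)
  as.numeric(out)
}

#' Relative flow change versus a baseline estimate
#'
#' `rBFI = (est - baseline) / baseline * 100` (percent). Works identically
#' for physical-unit (MESI, LUT) and arbitrary-unit (SCOS, SPG) estimates,
#' since any fixed scale cancels.
#'
#' @param estimate flow estimate(s).
#' @param baseline_estimate the baseline flow estimate (single finite,
#'   non-zero value).
#' @return Percent change(s).
#' @examples
#' relative_change(0.5e-8, 1e-8)  # -50
#' @export
relative_change <- function(estimate, baseline_estimate) {
  if (length(baseline_estimate) != 1L || !is.finite(baseline_estimate) ||
      baseline_estimate == 0)
    stop("'baseline_estimate' must be a single finite non-zero value")
  (estimate - baseline_estimate) / baseline_estimate * 100
}

#' Write / read a look-up table as a delimited file with a JSON header
#'
#' The `K^2` values are stored long-form (`exposure_s`, `beta`, `bfi`, `k2`)
#' in a tab-separated table; grids and optics go to `<path>.json`.
#'
#' @param lut a `speckle_lut`.
#' @param path output file path.
#' @return `write_lut` returns `path` invisibly; `read_lut` a `speckle_lut`.
#' @export
write_lut <- function(lut, path) {
  stopifnot(inherits(lut, "speckle_lut"))
  long <- expand.grid(exposure_s = lut$exposures, beta = lut$beta_grid,
                      bfi = lut$bfi_grid, KEEP.OUT.ATTRS = FALSE)
  long$k2 <- as.vector(lut$k2)
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(exposures = lut$exposures, bfi_grid = lut$bfi_grid,
               beta_grid = lut$beta_grid,
               optics = unclass(lut$optics)[c("mu_a", "mu_s_prime",
                                              "wavelength", "n_tissue",
                                              "n_medium", "rho")])
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  long <- utils::read.table(path, header = TRUE, sep = "\t")
  k2 <- array(long$k2, dim = c(length(meta$exposures),
                               length(meta$beta_grid),
                               length(meta$bfi_grid)))
  structure(list(exposures = meta$exposures, bfi_grid = meta$bfi_grid,
                 beta_grid = meta$beta_grid, k2 = k2,
                 optics = do.call(optical_properties, as.list(meta$optics))),
            class = "speckle_lut")
}
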