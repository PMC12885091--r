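#' Multiplicative measurement-noise specification
#'
#' Describes the zero-mean multiplicative Gaussian noise applied to speckle
#' variance data, `K2_noisy = K2_true * (1 + alpha * z)`, `z ~ N(0, 1)`,
#' together with the master seed and number of Monte-Carlo repetitions.
#'
#' @param alpha noise fraction (e.g. 0.05, 0.10, 0.15); >= 0.
#' @param seed master RNG seed (integer).
#' @param n_trials number of Monte-Carlo repetitions; >= 1.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(alpha, seed = 1L, n_trials = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0)
    stop("'alpha' must be a single non-negative number")
  if (n_trials < 1) stop("'n_trials' must be >= 1")
  structure(list(alpha = alpha, seed = as.integer(seed),
                 n_trials = as.integer(n_trials)),
            class = "noise_spec")
}

# Counter-based stream seed: a trial's random draws depend only on
# (master seed, experiment id, trial index), so any single trial can be
# regenerated in isolation. Kept below 2^31 in double arithmetic.
derive_seed <- function(seed, trial_index, stream_id = 0L) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m)
  s <- (s + (as.numeric(trial_index) %% m) * 1000003) %% m
  s <- (s + (as.numeric(stream_id) %% m) * 7919) %% m
  as.integer(s)
}

# Evaluate `expr` under a deterministic, isolated RNG stream; the caller's
# global RNG state is untouched.
with_stream <- function(seed, trial_index, stream_id, expr) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(derive_seed(seed, trial_index, stream_id))
  expr
}

#' Apply multiplicative Gaussian noise to a visibility curve
#'
#' Each speckle-variance value is multiplied by an independent
#' `1 + alpha * z`, `z ~ N(0, 1)`. Draws are a deterministic function of the
#' spec's seed, the trial index and the exposure index, so individual trials
#' are reproducible in isolation. Noisy values are recorded as-is: they may
#' exceed `beta` or, rarely, fall at or below zero; downstream estimators
#' decide how to handle such values.
#'
#' @param curve a noise-free `visibility_curve`.
#' @param spec a [noise_spec()].
#' @param trial_index Monte-Carlo trial counter (integer, >= 0).
#' @param stream_id optional experiment identifier entering the seed
#'   derivation, so different experiments draw independent streams.
#' @return A `visibility_curve` with `noise_level = alpha`.
#' @export
apply_noise <- function(curve, spec, trial_index = 0L, stream_id = 0L) {
  stopifnot(inherits(curve, "visibility_curve"), inherits(spec, "noise_spec"))
  if (curve$noise_level != 0)
    stop("'curve' already carries noise (noise_level = ", curve$noise_level,
         "); noise can only be applied to a noise-free curve")
  if (spec$alpha == 0) return(curve)
  z <- with_stream(spec$seed, trial_index, stream_id,
                   stats::rnorm(length(curve$k2)))
  curve$k2 <- curve$k2 * (1 + spec$alpha * z)
  curve$noise_level <- spec$alpha
  curve
}

#' Extract single-exposure samples from a visibility curve
#'
#' Picks the curve's values at the requested exposures (nearest grid point,
#' required to lie within 0.1 percent of the request).
#'
#' @param curve a `visibility_curve`.
#' @param exposures requested exposure durations, seconds.
#' @return A data frame of class `single_exposure_samples` with columns
#'   `exposure` (the grid value used) and `k2`, in request order.
#' @export
sample_exposures <- function(curve, exposures) {
  stopifnot(inherits(curve, "visibility_curve"))
  if (any(exposures < min(curve$exposures) - 1e-12) ||
      any(exposures > max(curve$exposures) + 1e-12))
    stop("requested exposure outside the span of the curve's grid")
  idx <- vapply(exposures, function(e) {
    i <- which.min(abs(curve$exposures - e))
    if (abs(curve$exposures[i] - e) > 1e-3 * e)
      stop("no grid point within 0.1% of requested exposure ", e, " s")
    i
  }, integer(1))
  structure(data.frame(exposure = curve$exposures[idx], k2 = curve$k2[idx]),
            class = c("single_exposure_samples", "data.frame"))
}
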