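#' Monte-Carlo study: sensitivity to speckle-averaging mismatch
#'
#' Simulates visibility curves at several true beta values, adds
#' multiplicative noise, and recovers the flow with MESI (beta free) and
#' with single-exposure LUT inversion at a fixed assumed beta. Returns mean
#' absolute percent BFI errors (over trials and the flow levels) per method,
#' exposure, true beta and noise level, and for the noise-free condition
#' the LUT errors in recovered percent flow change per scenario.
#'
#' @param optics an [optical_properties()] object.
#' @param beta_true true beta values used in the forward simulation.
#' @param beta_assumed beta assumed in the LUT inversion.
#' @param alphas noise fractions (0 entries give a single noise-free trial).
#' @param n_trials Monte-Carlo trials per (beta_true, alpha) condition.
#' @param n_exposures exposures in the MESI curve grid (log-spaced
#'   0.01-10 ms).
#' @param exposures_single single-exposure durations, seconds.
#' @param flows the true flows; default the four steady-state scenarios.
#' @param seed master seed.
#' @param lut optional prebuilt [build_lut()] (built on the fly otherwise).
#' @return List of two data frames: `bfi_error` (columns `method`,
#'   `exposure`, `beta_true`, `alpha`, then the [aggregate_errors()]
#'   summary) and `change_error` (noise-free LUT flow-change errors per
#'   scenario and exposure, plus scenario/exposure averages as rows with
#'   `exposure = NA` / `scenario = "average"`).
#' @export
run_beta_mismatch <- function(optics = optical_properties(),
                              beta_true = seq(0.1, 0.5, by = 0.1),
                              beta_assumed = 0.5,
                              alphas = c(0, 0.05, 0.10, 0.15),
                              n_trials = 10000L,
                              n_exposures = 10000L,
                              exposures_single = c(1e-4, 1e-3, 5e-3),
                              flows = c(0.5, 1, 1.5, 2) * 1e-8,
                              seed = 1L,
                              lut = NULL) {
  grid <- make_exposure_grid(n_exposures)
  if (is.null(lut)) lut <- build_lut(optics, exposures_single)
  bfi_rows <- list()
  exp_sorted <- sort(exposures_single)
  for (bt in beta_true) {
    base_curves <- lapply(flows, function(f)
      visibility_curve(grid, flow_state(f, bt), optics))
    # exact-exposure curves for the single-exposure methods
    single_curves <- lapply(flows, function(f)
      visibility_curve(exp_sorted, flow_state(f, bt), optics))
    for (al in alphas) {
      nt <- if (al == 0) 1L else n_trials
      spec <- noise_spec(al, seed = seed, n_trials = nt)
      err_mesi <- c()
      err_lut <- matrix(NA_real_, 0, length(exposures_single))
      for (tr in seq_len(nt)) {
        for (j in seq_along(flows)) {
          stream <- 1000L * j + round(bt * 100)
          noisy <- apply_noise(base_curves[[j]], spec, trial_index = tr,
                               stream_id = stream)
          fit <- fit_mesi(noisy, optics)
          err_mesi <- c(err_mesi, bfi_percent_error(fit$bfi_hat, flows[j]))
          sm <- sample_exposures(
            apply_noise(single_curves[[j]], spec, trial_index = tr,
                        stream_id = stream + 500L),
            exposures_single)
          bhat <- invert_lut(lut, sm, beta_assumed)
          err_lut <- rbind(err_lut, bfi_percent_error(bhat, flows[j]))
        }
      }
      bfi_rows[[length(bfi_rows) + 1L]] <- cbind(
        data.frame(method = "MESI", exposure = NA_real_,
                   beta_true = bt, alpha = al),
        aggregate_errors(err_mesi))
      for (e in seq_along(exposures_single)) {
        bfi_rows[[length(bfi_rows) + 1L]] <- cbind(
          data.frame(method = "LUT", exposure = exposures_single[e],
                     beta_true = bt, alpha = al),
          aggregate_errors(err_lut[, e]))
      }
    }
  }
  list(bfi_error = do.call(rbind, bfi_rows),
       change_error = lut_change_error_table(optics, beta_true, beta_assumed,
                                             exposures_single, flows, lut))
}

# Noise-free LUT flow-change errors per scenario/exposure/beta_true
# (the beta-mismatch bias isolated from noise).
lut_change_error_table <- function(optics, beta_true, beta_assumed,
                                   exposures_single, flows, lut) {
  baseline <- 1e-8
  scen <- setdiff(flows, baseline)
  true_change <- relative_change(scen, baseline)
  rows <- list()
  for (bt in beta_true) {
    errs <- matrix(NA_real_, length(scen), length(exposures_single))
    for (e in seq_along(exposures_single)) {
      k2b <- k2_model(exposures_single[e], baseline, bt, optics)
      f_base <- invert_lut(lut, data.frame(exposure = exposures_single[e],
                                           k2 = k2b), beta_assumed)
      for (s in seq_along(scen)) {
        k2s <- k2_model(exposures_single[e], scen[s], bt, optics)
        f_hat <- invert_lut(lut, data.frame(exposure = exposures_single[e],
                                            k2 = k2s), beta_assumed)
        errs[s, e] <- change_error(relative_change(f_hat, f_base),
                                   true_change[s])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        beta_true = bt, exposure = exposures_single[e],
        scenario = sprintf("%+g%%", true_change),
        error = errs[, e])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      beta_true = bt, exposure = NA_real_,
      scenario = sprintf("%+g%%", true_change),
      error = rowMeans(errs))
    rows[[length(rows) + 1L]] <- data.frame(
      beta_true = bt, exposure = NA_real_,
      scenario = "average", error = mean(errs))
  }
  do.call(rbind, rows)
}

#' Monte-Carlo study: noise response of all four estimators at matched beta
#'
#' With no speckle-averaging mismatch (`beta_true = beta_assumed`), measures
#' how the error in recovered percent flow change grows with multiplicative
#' noise for MESI, LUT, SCOS and SPG. Single-exposure methods are evaluated
#' at each of the three exposures and averaged; SCOS and SPG are identical
#' by construction and serve as a cross-check of the pipeline.
#'
#' @inheritParams run_beta_mismatch
#' @param beta the (matched) speckle averaging factor.
#' @return Data frame with columns `method`, `alpha`, `scenario` (the true
#'   percent change, or `"average"` across the non-baseline scenarios) and
#'   the error summary over trials.
#' @export
run_noise_comparison <- function(optics = optical_properties(),
                                 beta = 0.5,
                                 alphas = c(0, 0.05, 0.10, 0.15),
                                 n_trials = 10000L,
                                 n_exposures = 10000L,
                                 exposures_single = c(1e-4, 1e-3, 5e-3),
                                 flows = c(0.5, 1, 1.5, 2) * 1e-8,
                                 seed = 1L,
                                 lut = NULL) {
  grid <- make_exposure_grid(n_exposures)
  if (is.null(lut)) lut <- build_lut(optics, exposures_single)
  baseline <- 1e-8
  i_base <- which(flows == baseline)
  scen_idx <- setdiff(seq_along(flows), i_base)
  true_change <- relative_change(flows[scen_idx], baseline)
  exp_sorted <- sort(exposures_single)
  base_curves <- lapply(flows, function(f)
    visibility_curve(grid, flow_state(f, beta), optics))
  single_curves <- lapply(flows, function(f)
    visibility_curve(exp_sorted, flow_state(f, beta), optics))
  methods <- c("MESI", "LUT", "SCOS", "SPG")
  rows <- list()
  for (al in alphas) {
    nt <- if (al == 0) 1L else n_trials
    spec <- noise_spec(al, seed = seed, n_trials = nt)
    errs <- array(NA_real_, c(nt, length(scen_idx), length(methods)),
                  dimnames = list(NULL, NULL, methods))
    n_e <- length(exposures_single)
    for (tr in seq_len(nt)) {
      mesi <- numeric(length(flows))
      lutm <- scosm <- spgm <- matrix(NA_real_, length(flows), n_e)
      for (j in seq_along(flows)) {
        noisy <- apply_noise(base_curves[[j]], spec, trial_index = tr,
                             stream_id = 2000L + j)
        sm <- sample_exposures(
          apply_noise(single_curves[[j]], spec, trial_index = tr,
                      stream_id = 2500L + j),
          exposures_single)
        mesi[j] <- fit_mesi(noisy, optics)$bfi_hat
        lutm[j, ] <- invert_lut(lut, sm, beta)
        scosm[j, ] <- estimate_scos(sm)
        spgm[j, ] <- estimate_spg(sm)
      }
      for (s in seq_along(scen_idx)) {
        j <- scen_idx[s]
        errs[tr, s, "MESI"] <- change_error(
          relative_change(mesi[j], mesi[i_base]), true_change[s])
        # single-exposure methods: per-exposure change, averaged over exposures
        errs[tr, s, "LUT"] <- mean(change_error(
          (lutm[j, ] / lutm[i_base, ] - 1) * 100, true_change[s]))
        errs[tr, s, "SCOS"] <- mean(change_error(
          (scosm[j, ] / scosm[i_base, ] - 1) * 100, true_change[s]))
        errs[tr, s, "SPG"] <- mean(change_error(
          (spgm[j, ] / spgm[i_base, ] - 1) * 100, true_change[s]))
      }
    }
    for (m in methods) {
      for (s in seq_along(scen_idx)) {
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(method = m, alpha = al,
                     scenario = sprintf("%+g%%", true_change[s])),
          aggregate_errors(errs[, s, m]))
      }
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(method = m, alpha = al, scenario = "average"),
        aggregate_errors(rowMeans(matrix(errs[, , m], nrow = nt))))
    }
  }
  do.call(rbind, rows)
}

#' Monte-Carlo study: pulsatile flow tracking
#'
#' Frame-by-frame recovery of a pulsatile relative-flow waveform by all
#' methods: MESI refits (F, beta) on every frame (warm-started from the
#' previous frame), the LUT inverts each single exposure at one or more
#' assumed betas, and SCOS/SPG invert each single exposure directly.
#' Every recovered time course is normalized by its own time mean (the
#' baseline convention), and single-exposure methods are averaged across
#' the three exposures.
#'
#' @param series a [pulsatile_waveform()] (or imported) `pulsatile_series`.
#' @param optics an [optical_properties()] object.
#' @param alpha multiplicative noise fraction.
#' @param n_trials Monte-Carlo trials.
#' @param beta_true beta used in the forward simulation.
#' @param beta_assumed betas assumed for LUT inversion (each becomes a
#'   method `"LUT0.5"`, `"LUT0.45"`, ...).
#' @param n_exposures exposures per frame in the MESI curve grid.
#' @param exposures_single single-exposure durations, seconds.
#' @param seed master seed.
#' @param lut optional prebuilt LUT.
#' @return List with `truth` (true relative waveform, percent of baseline),
#'   `times`, and `recovered`: a named list of trials x time matrices
#'   (percent of baseline) per method.
#' @export
run_pulsatile <- function(series, optics = optical_properties(),
                          alpha = 0.05, n_trials = 5000L,
                          beta_true = 0.5, beta_assumed = c(0.5, 0.45),
                          n_exposures = 10000L,
                          exposures_single = c(1e-4, 1e-3, 5e-3),
                          seed = 1L, lut = NULL) {
  stopifnot(inherits(series, "pulsatile_series"))
  grid <- make_exposure_grid(n_exposures)
  if (is.null(lut)) lut <- build_lut(optics, exposures_single)
  n_t <- length(series$times)
  truth_rel <- series$bfi / mean(series$bfi) * 100
  exp_sorted <- sort(exposures_single)
  curves <- lapply(series$bfi, function(f)
    visibility_curve(grid, flow_state(f, beta_true), optics))
  single_curves <- lapply(series$bfi, function(f)
    visibility_curve(exp_sorted, flow_state(f, beta_true), optics))
  spec <- noise_spec(alpha, seed = seed, n_trials = n_trials)
  methods <- c("MESI", paste0("LUT", beta_assumed), "SCOS", "SPG")
  rec <- lapply(methods, function(m) matrix(NA_real_, n_trials, n_t))
  names(rec) <- methods
  n_e <- length(exposures_single)
  for (tr in seq_len(n_trials)) {
    mesi <- numeric(n_t)
    lutm <- array(NA_real_, c(n_t, n_e, length(beta_assumed)))
    scos <- matrix(NA_real_, n_t, n_e)
    spg <- matrix(NA_real_, n_t, n_e)
    prev_bfi <- 1e-8; prev_beta <- 0.5
    for (fr in seq_len(n_t)) {
      noisy <- apply_noise(curves[[fr]], spec, trial_index = tr,
                           stream_id = 3000L + fr)
      # restart only the cold first frame; warm starts converge directly
      fit <- fit_mesi(noisy, optics, init_bfi = prev_bfi,
                      init_beta = prev_beta,
                      restarts = if (fr == 1L) 1L else 0L)
      mesi[fr] <- fit$bfi_hat
      if (fit$converged) { prev_bfi <- fit$bfi_hat; prev_beta <- fit$beta_hat }
      sm <- sample_exposures(
        apply_noise(single_curves[[fr]], spec, trial_index = tr,
                    stream_id = 3500L + fr),
        exposures_single)
      for (bi in seq_along(beta_assumed))
        lutm[fr, , bi] <- invert_lut(lut, sm, beta_assumed[bi])
      scos[fr, ] <- estimate_scos(sm)
      spg[fr, ] <- estimate_spg(sm)
    }
    rec[["MESI"]][tr, ] <- mesi / mean(mesi) * 100
    for (bi in seq_along(beta_assumed)) {
      per_exp <- sapply(seq_len(n_e), function(e)
        lutm[, e, bi] / mean(lutm[, e, bi]) * 100)
      rec[[paste0("LUT", beta_assumed[bi])]][tr, ] <- rowMeans(per_exp)
    }
    rec[["SCOS"]][tr, ] <- rowMeans(sapply(seq_len(n_e), function(e)
      scos[, e] / mean(scos[, e]) * 100))
    rec[["SPG"]][tr, ] <- rowMeans(sapply(seq_len(n_e), function(e)
      spg[, e] / mean(spg[, e]) * 100))
  }
  list(truth = truth_rel, times = series$times, recovered = rec)
}

#' Monte-Carlo study: reducing the number of exposures in the MESI fit
#'
#' Measures the absolute percent BFI error of the MESI fit as the exposure
#' grid is thinned from densely sampled curves to experimentally feasible
#' counts, at each flow level and noise fraction. All grids are log-spaced
#' over the same 0.01-10 ms span.
#'
#' @inheritParams run_beta_mismatch
#' @param counts exposure counts to test.
#' @param beta the (matched) speckle averaging factor.
#' @param n_realizations noise realizations per condition.
#' @return Data frame with columns `n_exposures`, `flow`, `alpha` and the
#'   error summary across realizations.
#' @export
run_exposure_reduction <- function(optics = optical_properties(),
                                   counts = c(10000L, 1000L, 500L, 100L,
                                              25L, 15L),
                                   flows = c(0.5, 1, 1.5, 2) * 1e-8,
                                   alphas = c(0.01, 0.05),
                                   beta = 0.5,
                                   n_realizations = 100L,
                                   seed = 1L) {
  rows <- list()
  for (nc in counts) {
    grid <- make_exposure_grid(nc)
    for (j in seq_along(flows)) {
      curve <- visibility_curve(grid, flow_state(flows[j], beta), optics)
      for (al in alphas) {
        spec <- noise_spec(al, seed = seed, n_trials = n_realizations)
        errs <- vapply(seq_len(n_realizations), function(tr) {
          noisy <- apply_noise(curve, spec, trial_index = tr,
                               stream_id = 4000L + 10L * j + nc %% 7L)
          bfi_percent_error(fit_mesi(noisy, optics)$bfi_hat, flows[j])
        }, numeric(1))
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(n_exposures = nc, flow = flows[j], alpha = al),
          aggregate_errors(errs))
      }
    }
  }
  do.call(rbind, rows)
}
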