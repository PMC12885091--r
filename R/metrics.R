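#' Absolute percent error of a flow estimate
#'
#' `|est - truth| / truth * 100`. Non-finite estimates propagate as `NA`
#' (flagged, never an error), to be excluded and counted by
#' [aggregate_errors()].
#'
#' @param est estimated BFI (cm^2/s); vectorized.
#' @param truth true BFI (cm^2/s), > 0.
#' @return Non-negative percent error(s).
#' @examples
#' bfi_percent_error(0.6e-8, 0.5e-8)  # 20
#' @export
bfi_percent_error <- function(est, truth) {
  if (any(!is.finite(truth)) || any(truth <= 0))
    stop("'truth' must be positive and finite")
  out <- abs(est - truth) / truth * 100
  out[!is.finite(est)] <- NA_real_
  out
}

#' Error of a recovered percent flow change, in percentage points
#'
#' `|rbfi_est - rbfi_true|`: the absolute deviation of a recovered percent
#' change from the true percent change.
#'
#' @param rbfi_est recovered percent change(s).
#' @param rbfi_true true percent change(s).
#' @return Absolute deviation(s), percentage points.
#' @export
change_error <- function(rbfi_est, rbfi_true) {
  out <- abs(rbfi_est - rbfi_true)
  out[!is.finite(rbfi_est) | !is.finite(rbfi_true)] <- NA_real_
  out
}

#' Summarize a collection of errors
#'
#' Mean, standard deviation and full range (min-max, the error-bar
#' convention used throughout the experiment drivers) over a vector of
#' per-trial errors. Non-finite values are excluded and counted, never
#' imputed.
#'
#' @param errors numeric vector of errors (percent or percentage points).
#' @return An object of class `error_summary`: one-row data frame with
#'   `mean`, `sd`, `min`, `max`, `n` (values summarized) and `excluded`.
#' @examples
#' aggregate_errors(c(10, 20, 30))
#' @export
aggregate_errors <- function(errors) {
  bad <- !is.finite(errors)
  x <- errors[!bad]
  if (length(x) == 0L)
    stop("no finite errors left to summarize (", sum(bad), " excluded)")
  structure(data.frame(mean = mean(x),
                       sd = if (length(x) > 1L) stats::sd(x) else 0,
                       min = min(x), max = max(x),
                       n = length(x), excluded = sum(bad)),
            class = c("error_summary", "data.frame"))
}

#' Worst-case tracking error of a recovered waveform ensemble
#'
#' For an ensemble of recovered relative-flow time courses (trials in rows,
#' time points in columns), computes at each time point the maximum over
#' trials of the absolute deviation from the true waveform, plus the time
#' average of that worst-case curve.
#'
#' @param ensemble trials x time matrix of recovered relative flow, percent
#'   of baseline.
#' @param truth true relative flow time series, percent of baseline; length
#'   must match `ncol(ensemble)`.
#' @return List with `per_time` (max error at each time point) and
#'   `average_max` (its time mean).
#' @export
max_tracking_error <- function(ensemble, truth) {
  ensemble <- as.matrix(ensemble)
  if (ncol(ensemble) != length(truth))
    stop("ensemble has ", ncol(ensemble), " time points but truth has ",
         length(truth))
  dev <- abs(sweep(ensemble, 2, truth))
  per_time <- apply(dev, 2, max)
  list(per_time = per_time, average_max = mean(per_time))
}

#' Pointwise percentile envelope of a waveform ensemble
#'
#' Empirical lower/upper percentile curves across trials at each time point
#' (the band plotted around recovered pulsatile waveforms).
#'
#' @param ensemble trials x points matrix.
#' @param lo,hi percentiles in `[0, 100]`, `lo < hi`.
#' @return List with vectors `lo` and `hi`. With too few trials to resolve
#'   the requested tail a warning is given and the nearest-rank estimate is
#'   used.
#' @export
percentile_envelope <- function(ensemble, lo = 5, hi = 95) {
  if (!(lo < hi) || lo < 0 || hi > 100)
    stop("percentiles must satisfy 0 <= lo < hi <= 100")
  ensemble <- as.matrix(ensemble)
  n <- nrow(ensemble)
  tail_frac <- min(lo, 100 - hi) / 100
  type <- 7
  if (tail_frac > 0 && n * tail_frac < 1) {
    warning("only ", n, " trials: nearest-rank fallback for the ",
            lo, "th/", hi, "th percentiles")
    type <- 1
  }
  list(lo = apply(ensemble, 2, stats::quantile, probs = lo / 100,
                  type = type, names = FALSE),
       hi = apply(ensemble, 2, stats::quantile, probs = hi / 100,
                  type = type, names = FALSE))
}
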