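#' The four steady-state flow scenarios
#'
#' Baseline flow 1e-8 cm^2/s plus a halved, a 1.5x and a doubled flow:
#' relative changes of 0, -50, +50 and +100 percent. These are the
#' physiologically representative adult flow levels used by all
#' steady-state experiments.
#'
#' @param beta speckle averaging factor attached to every scenario.
#' @return List of [flow_state()] objects, ordered by flow
#'   (0.5, 1.0, 1.5, 2.0 x 1e-8 cm^2/s).
#' @export
steady_state_scenarios <- function(beta = 0.5) {
  lapply(c(0.5, 1, 1.5, 2) * 1e-8, flow_state, beta = beta)
}

#' Synthetic cardiac-like pulsatile blood-flow waveform
#'
#' Generates a periodic arterial-flow-like BFI time series standing in for
#' an in-vivo pulsatile recording: each beat has a fast raised-cosine
#' systolic upstroke (15 percent of the beat), an exponential diastolic
#' decay, and a small dicrotic bump 40 percent into the beat with amplitude
#' 20 percent of the pulse height. Beat-to-beat period jitter (uniform,
#' +/- `jitter`) is drawn from a seeded stream. The series is affinely
#' rescaled so its time mean equals `baseline` exactly and its maximum
#' equals `peak_ratio * baseline` exactly.
#'
#' The continuous beat template is evaluated directly at the sample instants
#' (a ~1 Hz pulse sampled at 10 Hz is deliberately under-sampled, as
#' camera-rate flow monitoring is in practice); no band-limiting is applied.
#'
#' @param duration total duration, s. `duration * rate` must be an integer
#'   number of samples >= 2.
#' @param rate sampling rate, Hz.
#' @param heart_rate cardiac frequency, Hz; must be below `rate / 2`.
#' @param peak_ratio systolic peak over baseline (time-mean); > 1.
#' @param baseline mean BFI, cm^2/s.
#' @param seed integer seed for the beat-period jitter.
#' @param jitter fractional beat-period jitter (0 disables it).
#' @return An object of class `pulsatile_series`: list with `times` (s),
#'   `bfi` (cm^2/s) and `baseline`.
#' @examples
#' ps <- pulsatile_waveform(seed = 1)
#' c(mean(ps$bfi), max(ps$bfi))  # 1e-8, 2e-8 by construction
#' @export
pulsatile_waveform <- function(duration = 10, rate = 10, heart_rate = 1.1,
                               peak_ratio = 2, baseline = 1e-8,
                               seed = 1L, jitter = 0.03) {
  n <- duration * rate
  if (abs(n - round(n)) > 1e-9 || round(n) < 2)
    stop("'duration * rate' must be an integer number of samples >= 2")
  n <- as.integer(round(n))
  if (heart_rate >= rate / 2)
    stop("'heart_rate' must be below the Nyquist frequency rate/2")
  if (peak_ratio <= 1) stop("'peak_ratio' must be > 1")
  if (baseline <= 0) stop("'baseline' must be positive")

  period <- 1 / heart_rate
  n_beats <- ceiling(duration / (period * (1 - abs(jitter)))) + 2L
  jit <- if (jitter > 0) {
    with_stream(seed, 0L, 777L, stats::runif(n_beats, -jitter, jitter))
  } else rep(0, n_beats)
  onsets <- cumsum(c(0, period * (1 + jit)))

  # beat template on local phase [0, 1): upstroke, decay, dicrotic bump
  template <- function(phase) {
    up <- 0.15
    s <- ifelse(phase < up,
                0.5 * (1 - cos(pi * phase / up)),
                exp(-(phase - up) / 0.20))
    s + 0.2 * exp(-0.5 * ((phase - 0.40) / 0.06)^2)
  }
  times <- seq(0, by = 1 / rate, length.out = n)
  beat <- findInterval(times, onsets)
  phase <- (times - onsets[beat]) / (onsets[beat + 1L] - onsets[beat])
  s <- template(phase)

  m <- mean(s); M <- max(s)
  if (M <= m) stop("degenerate waveform template")
  b <- (peak_ratio - 1) * baseline / (M - m)
  a <- baseline - b * m
  bfi <- a + b * s
  if (any(bfi <= 0))
    stop("waveform not positive; reduce 'peak_ratio' or the jitter")
  structure(list(times = times, bfi = bfi, baseline = baseline),
            class = "pulsatile_series")
}

#' @export
print.pulsatile_series <- function(x, ...) {
  cat(sprintf("Pulsatile series: %d samples over %.3g s, baseline %g cm^2/s, peak ratio %.3g\n",
              length(x$times), max(x$times) - min(x$times) + diff(x$times[1:2]),
              x$baseline, max(x$bfi) / x$baseline))
  invisible(x)
}

#' Write / read a pulsatile series as two-column CSV
#'
#' Columns `time_s`, `bfi`. Reading recomputes the baseline as the time
#' mean, so a user-supplied real waveform can replace the synthetic one.
#'
#' @param series a `pulsatile_series`.
#' @param path CSV file path.
#' @return `write_pulsatile_series` returns `path` invisibly;
#'   `read_pulsatile_series` returns a `pulsatile_series`.
#' @export
write_pulsatile_series <- function(series, path) {
  stopifnot(inherits(series, "pulsatile_series"))
  utils::write.csv(data.frame(time_s = series$times, bfi = series$bfi),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pulsatile_series
#' @export
read_pulsatile_series <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("time_s", "bfi") %in% names(tab)))
    stop("expected columns 'time_s' and 'bfi'")
  if (any(tab$bfi <= 0)) stop("BFI values must be positive")
  structure(list(times = tab$time_s, bfi = tab$bfi,
                 baseline = mean(tab$bfi)),
            class = "pulsatile_series")
}
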