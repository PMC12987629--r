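#' Processed photometry trace
#'
#' A motion-corrected / normalized signal together with its baseline
#' statistics and a provenance record of the applied steps. For unit `"z"`,
#' the mean over the baseline window is ~0 and its SD ~1 by construction.
#'
#' @param ts a [time_series()] with unit `"dff"` or `"z"`.
#' @param baseline_mean,baseline_sd baseline statistics in source units.
#' @param provenance character vector of applied steps and parameters.
#' @return Object of class `processed_trace`.
#' @export
processed_trace <- function(ts, baseline_mean = NA_real_,
                            baseline_sd = NA_real_, provenance = character()) {
  validate_time_series(ts)
  check_unit(ts, c("dff", "z"))
  structure(list(ts = ts, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, provenance = provenance),
            class = "processed_trace")
}

#' @export
print.processed_trace <- function(x, ...) {
  cat(sprintf("<processed_trace unit=%s n=%d fs=%g Hz>\n  steps: %s\n",
              x$ts$unit, length(x$ts$x), x$ts$fs,
              paste(x$provenance, collapse = " -> ")))
  invisible(x)
}

#' Isosbestic motion correction
#'
#' Fits the 415 nm isosbestic channel to the 470 nm signal channel by affine
#' least squares, `f(x415) = a * x415 + b` minimizing
#' `sum((x470 - f(x415))^2)`, and returns
#' `dF/F = (x470 - f(x415)) / f(x415)`. Because the fit is affine, the result
#' is invariant to affine transforms of the isosbestic channel. A constant
#' 415 channel (zero variance) cannot identify a slope; the fit falls back to
#' intercept-only with a warning.
#'
#' @param raw470,raw415 `time_series` of equal length and sampling rate.
#' @return A [processed_trace()] with unit `"dff"`; the fitted coefficients
#'   are recorded in `provenance`.
#' @export
isosbestic_correct <- function(raw470, raw415) {
  validate_time_series(raw470); validate_time_series(raw415)
  if (length(raw470$x) != length(raw415$x) || raw470$fs != raw415$fs)
    stop("channels must share length and fs")
  x <- raw415$x; y <- raw470$x
  vx <- stats::var(x)
  if (vx < .Machine$double.eps * max(1, mean(x)^2)) {
    if (stats::var(y) > 0)
      warning("constant 415 channel: falling back to intercept-only fit")
    a <- 0; b <- mean(y)
  } else {
    a <- stats::cov(x, y) / vx
    b <- mean(y) - a * mean(x)
  }
  f <- a * x + b
  if (any(f <= 0))
    stop("degenerate isosbestic fit: fitted control non-positive")
  dff <- (y - f) / f
  processed_trace(
    time_series(dff, fs = raw470$fs, t0 = raw470$t[1], unit = "dff"),
    provenance = sprintf("isosbestic_correct(a=%.6g, b=%.6g)", a, b))
}

#' z-score a trace to a baseline window
#'
#' `z(t) = (x(t) - mean_baseline) / sd_baseline`, with the baseline mean and
#' SD computed over `baseline_window` and stored for later conversion of
#' drug responses into baseline-SD units.
#'
#' @param trace a [processed_trace()] (or bare `time_series` with unit
#'   `"dff"`).
#' @param baseline_window numeric `(t0, t1)` in seconds, within the record.
#' @return A [processed_trace()] with unit `"z"`.
#' @export
zscore_to_baseline <- function(trace, baseline_window) {
  ts <- if (inherits(trace, "processed_trace")) trace$ts else trace
  validate_time_series(ts)
  stopifnot(length(baseline_window) == 2, baseline_window[1] < baseline_window[2])
  if (baseline_window[1] < ts$t[1] - 1e-9 ||
      baseline_window[2] > ts$t[length(ts$t)] + 1e-9)
    stop("baseline window outside record")
  sel <- ts$t >= baseline_window[1] & ts$t <= baseline_window[2]
  m <- mean(ts$x[sel]); s <- stats::sd(ts$x[sel])
  if (!is.finite(s) || s == 0) stop("zero baseline SD")
  z <- (ts$x - m) / s
  prov <- c(if (inherits(trace, "processed_trace")) trace$provenance,
            sprintf("zscore_to_baseline([%g, %g])",
                    baseline_window[1], baseline_window[2]))
  processed_trace(time_series(z, fs = ts$fs, t0 = ts$t[1], unit = "z"),
                  baseline_mean = m, baseline_sd = s, provenance = prov)
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain filter with raised-cosine band edges: exactly zero phase
#' (no lag bias in time-to-peak or cross-correlation estimates), unity
#' passband gain, DC completely removed. The signal is reflect-padded before
#' transforming to suppress wrap-around edge artifacts. Transition bands are
#' half a decade below the low edge and a quarter octave above the high
#' edge.
#'
#' @param ts a `time_series` (any unit).
#' @param lo,hi band edges, Hz, `0 < lo < hi < fs/2`.
#' @return A filtered `time_series` with the same unit.
#' @export
bandpass <- function(ts, lo, hi) {
  validate_time_series(ts)
  fs <- ts$fs
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi")
  if (hi >= fs / 2) stop("hi must be below the Nyquist frequency fs/2")
  x <- ts$x
  n <- length(x)
  npad <- min(n, max(16L, ceiling(3 / lo * fs)))
  xp <- c(rev(x[seq_len(npad)]), x, rev(x[(n - npad + 1):n]))
  m <- length(xp)
  f <- abs(seq(0, m - 1) / m * fs)
  f <- pmin(f, fs - f)                 # two-sided frequency axis
  gain <- edge_gain(f, lo, lo / 2, rising = TRUE) *
    edge_gain(f, hi, hi / 4, rising = FALSE)
  gain[f == 0] <- 0
  y <- Re(stats::fft(stats::fft(xp) * gain, inverse = TRUE)) / m
  time_series(y[(npad + 1):(npad + n)], fs = fs, t0 = ts$t[1],
              unit = ts$unit)
}

# Raised-cosine transition centred below (rising) or above (falling) the
# edge so that the gain is exactly 1 at the edge frequency itself.
edge_gain <- function(f, edge, width, rising) {
  g <- numeric(length(f))
  if (rising) {
    lo0 <- edge - width
    g[f >= edge] <- 1
    idx <- f > lo0 & f < edge
    g[idx] <- 0.5 * (1 - cos(pi * (f[idx] - lo0) / width))
  } else {
    hi1 <- edge + width
    g[f <= edge] <- 1
    idx <- f > edge & f < hi1
    g[idx] <- 0.5 * (1 + cos(pi * (f[idx] - edge) / width))
  }
  g
}

#' Anti-aliased resampling to a lower rate
#'
#' Low-pass filters at 90% of the output Nyquist frequency (zero-phase,
#' raised-cosine edge) and linearly interpolates onto the uniform output
#' grid. Upsampling is refused.
#'
#' @param ts a `time_series`.
#' @param fs_out output rate, Hz, `<= fs`.
#' @return A `time_series` at `fs_out`.
#' @export
resample <- function(ts, fs_out) {
  validate_time_series(ts)
  if (fs_out > ts$fs) stop("no upsampling: fs_out must be <= fs")
  if (fs_out == ts$fs) return(ts)
  x <- ts$x
  n <- length(x)
  cut <- 0.9 * fs_out / 2
  m <- 2L * n
  xp <- c(x, rev(x))
  f <- seq(0, m - 1) / m * ts$fs
  f <- pmin(f, ts$fs - f)
  gain <- edge_gain(f, cut, cut / 4, rising = FALSE)
  y <- Re(stats::fft(stats::fft(xp) * gain, inverse = TRUE)) / m
  y <- y[seq_len(n)]
  tout <- seq(ts$t[1], ts$t[n], by = 1 / fs_out)
  time_series(stats::approx(ts$t, y, xout = tout)$y, fs = fs_out,
              t0 = ts$t[1], unit = ts$unit)
}
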