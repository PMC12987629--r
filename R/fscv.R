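#' Evoked FSCV concentration trace
#'
#' A fast-scan cyclic voltammetry dopamine concentration trace (pre-calibrated
#' to uM) with its stimulus metadata. Electrode calibration chemistry and
#' voltammogram processing are upstream of this container.
#'
#' @param ts a [time_series()] with unit `"uM"`.
#' @param t_stim stimulus onset, s, within the record.
#' @param stim_kind `"single"` (single pulse) or `"train"`.
#' @param region,genotype,site,slice,condition metadata labels.
#' @param truth optional generator ground truth.
#' @return Object of class `fscv_trace`.
#' @export
fscv_trace <- function(ts, t_stim, stim_kind = c("single", "train"),
                       region = "DS", genotype = "WT", site = 1L,
                       slice = 1L, condition = "baseline", truth = NULL) {
  validate_time_series(ts)
  check_unit(ts, "uM")
  stim_kind <- match.arg(stim_kind)
  if (!all(is.finite(ts$x))) stop("fscv_trace: non-finite concentrations")
  if (t_stim < ts$t[1] || t_stim > ts$t[length(ts$t)])
    stop("fscv_trace: t_stim outside record")
  structure(list(ts = ts, t_stim = t_stim, stim_kind = stim_kind,
                 region = region, genotype = genotype, site = site,
                 slice = slice, condition = condition, truth = truth),
            class = "fscv_trace")
}

#' @export
print.fscv_trace <- function(x, ...) {
  cat(sprintf("<fscv_trace %s %s %s slice %s site %s: stim at %g s>\n",
              x$genotype, x$region, x$stim_kind, x$slice, x$site, x$t_stim))
  invisible(x)
}

#' Extract release/uptake kinetics from an evoked trace
#'
#' Measures the three kinetic readouts of an evoked dopamine transient:
#' peak concentration above baseline, time to peak (TTP), and clearance
#' half-time (first time after the peak at which the signal falls to
#' baseline plus half the peak, by linear interpolation between samples —
#' an offset-invariant definition).
#'
#' On a noiseless trace the readouts are taken directly from the samples and
#' are exact up to interpolation. On a noisy trace the direct maximum is
#' upward-biased by noise selection, so the readouts are refined by
#' least-squares fitting of the canonical rise--decay transient template
#' (linear rise, exponential fall, free baseline offset), initialized from a
#' lightly smoothed trace; the fitted parameters are reported. Sites where
#' the post-stimulus signal never exceeds baseline mean plus 4 baseline SD
#' are below detection and raise an error (callers exclude and log them).
#'
#' If the observed trace has not decayed to half peak by the record end, the
#' half-time is censored (`thalf_s = NA`, `censored = TRUE`).
#'
#' @param trace an [fscv_trace()].
#' @param baseline_window `(t0, t1)` s; default the whole pre-stimulus
#'   period.
#' @param search_window_s peak search window after the stimulus, s.
#' @param smooth_s Gaussian pre-smoothing SD for initialization, s.
#' @return Object of class `fscv_kinetics` with `peak_uM`, `ttp_s`,
#'   `thalf_s`, `censored`, `baseline_mean`, `method`.
#' @export
extract_kinetics <- function(trace, baseline_window = NULL,
                             search_window_s = 5, smooth_s = 0.05) {
  stopifnot(inherits(trace, "fscv_trace"))
  ts <- trace$ts
  t <- ts$t; x <- ts$x; fs <- ts$fs
  if (is.null(baseline_window)) baseline_window <- c(t[1], trace$t_stim)
  bsel <- t >= baseline_window[1] & t < baseline_window[2]
  if (sum(bsel) < 2) stop("baseline window too short")
  m0 <- mean(x[bsel]); s0 <- stats::sd(x[bsel])
  wsel <- t > trace$t_stim & t <= trace$t_stim + search_window_s
  if (!any(wsel)) stop("empty search window")
  noiseless <- s0 < 1e-9 * max(abs(x - m0), 1e-12)

  # peak measurement and detection both on the (smoothed) working signal,
  # with the baseline SD of that same signal
  sig <- if (noiseless) x else gaussian_smooth(x, fs, smooth_s)
  m0 <- mean(sig[bsel]); s0 <- stats::sd(sig[bsel])
  ipk <- which(wsel)[which.max(sig[wsel])]
  peak <- sig[ipk] - m0
  if (peak <= 4 * s0 || peak <= 0)
    stop("below detection: no release above baseline + 4 SD")
  ttp <- t[ipk] - trace$t_stim

  # half-time with linear interpolation; censored if never reached in-record
  half <- m0 + peak / 2
  after <- seq(ipk, length(x))
  below <- after[sig[after] <= half]
  censored <- !length(below)
  thalf <- NA_real_
  if (!censored) {
    j <- below[1]
    if (j == ipk) thalf <- 0
    else {
      x1 <- sig[j - 1]; x2 <- sig[j]
      w <- if (x1 == x2) 0 else (x1 - half) / (x1 - x2)
      thalf <- (t[j - 1] + w / fs) - t[ipk]
    }
  }
  method <- "direct"

  if (!noiseless) {
    # refine by template fit (direct max on noisy data is selection-biased)
    fsel <- t <= trace$t_stim + search_window_s
    tt <- t[fsel]; xx <- x[fsel]
    rss <- function(p)
      sum((xx - fscv_template(tt, trace$t_stim, exp(p[1]), exp(p[2]),
                              exp(p[3]), p[4]))^2)
    init <- c(log(peak), log(max(ttp, 2 / fs)),
              log(max(if (censored) ttp else thalf, 2 / fs)), m0)
    best <- NULL
    for (pert in list(c(0, 0, 0, 0), c(0.3, 0.3, -0.3, 0),
                      c(-0.3, -0.3, 0.3, 0), c(0.2, -0.2, 0.2, 0))) {
      fit <- try(stats::optim(init + pert, rss,
                              method = "Nelder-Mead",
                              control = list(maxit = 2000,
                                             reltol = 1e-12)),
                 silent = TRUE)
      if (!inherits(fit, "try-error") &&
          (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (!is.null(best)) {
      peak <- exp(best$par[1])
      ttp <- exp(best$par[2])
      if (!censored) thalf <- exp(best$par[3])
      m0 <- best$par[4]
      method <- "template_fit"
    }
  }

  structure(list(peak_uM = peak, ttp_s = ttp, thalf_s = thalf,
                 censored = censored, baseline_mean = m0, method = method),
            class = "fscv_kinetics")
}

#' @export
print.fscv_kinetics <- function(x, ...) {
  cat(sprintf(
    "<fscv_kinetics: peak %.4g uM, TTP %.4g s, t1/2 %s s (%s)>\n",
    x$peak_uM, x$ttp_s,
    if (x$censored) "censored" else sprintf("%.4g", x$thalf_s), x$method))
  invisible(x)
}

#' Autoreceptor disinhibition as percent of baseline
#'
#' Paired measure of D2-autoreceptor tone: evoked peak with the D2
#' antagonist on board expressed as a percentage of the pre-drug baseline
#' peak from the same recording site.
#'
#' @param peak_with_antagonist,peak_baseline evoked peak concentrations, uM,
#'   both positive.
#' @return Percent of baseline (100 = no disinhibition).
#' @export
disinhibition_percent <- function(peak_with_antagonist, peak_baseline) {
  if (any(peak_baseline <= 0) || any(peak_with_antagonist <= 0))
    stop("peaks must be positive")
  100 * peak_with_antagonist / peak_baseline
}

#' Regional penetrance as percent of wild-type mean
#'
#' Normalizes each mutant value to the mean of the matched-region wild-type
#' group, as percent, and summarizes with mean and SEM.
#'
#' @param mut_values,wt_values numeric vectors (uM or any common unit);
#'   `wt_values` must be non-empty.
#' @return List with `percent` (per mutant value), `mean`, `sem`.
#' @export
region_penetrance <- function(mut_values, wt_values) {
  if (!length(wt_values)) stop("empty wild-type group")
  if (!length(mut_values)) stop("empty mutant group")
  pc <- 100 * mut_values / mean(wt_values)
  list(percent = pc, mean = mean(pc),
       sem = if (length(pc) > 1) stats::sd(pc) / sqrt(length(pc)) else NA_real_)
}

#' Average site-level kinetics within slices
#'
#' Slice-level aggregation: recording sites are averaged within each slice
#' before any genotype-level statistic, matching the per-slice reporting of
#' evoked-release measurements.
#'
#' @param df data frame with columns `slice` and one or more numeric measure
#'   columns.
#' @param measures names of the measure columns to average.
#' @return Data frame with one row per slice.
#' @export
aggregate_sites <- function(df, measures = setdiff(names(df),
                                                   c("slice", "site"))) {
  stopifnot("slice" %in% names(df))
  out <- stats::aggregate(df[measures], by = list(slice = df$slice),
                          FUN = mean, na.rm = TRUE)
  out
}
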