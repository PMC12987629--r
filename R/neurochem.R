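#' Saturation-uptake dataset
#'
#' Replicate-resolved dopamine uptake rates across a concentration row, the
#' input to Michaelis--Menten fitting. At least four distinct concentrations
#' are required for a fit.
#'
#' @param conc_uM concentrations, uM (> 0).
#' @param rate uptake rates (normalized units), same length.
#' @param replicate replicate index per row.
#' @param pair_id label pairing a WT and a mutant dataset.
#' @param truth optional generator ground truth.
#' @return Object of class `uptake_dataset`.
#' @export
uptake_dataset <- function(conc_uM, rate, replicate = 1L, pair_id = NA,
                           truth = NULL) {
  stopifnot(length(conc_uM) == length(rate))
  if (any(conc_uM <= 0)) stop("concentrations must be positive")
  structure(list(conc_uM = conc_uM, rate = rate,
                 replicate = rep_len(replicate, length(rate)),
                 pair_id = pair_id, truth = truth),
            class = "uptake_dataset")
}

#' @export
print.uptake_dataset <- function(x, ...) {
  cat(sprintf("<uptake_dataset: %d points, %d concentration(s)>\n",
              length(x$rate), length(unique(x$conc_uM))))
  invisible(x)
}

#' Fit Michaelis-Menten uptake kinetics
#'
#' Nonlinear least squares of `v = Vmax * C / (Km + C)` to a saturation
#' uptake dataset. Starting values come from the Lineweaver--Burk
#' linearization (ordinary regression of `1/v` on `1/C` over positive
#' rates), plus three multiplicatively perturbed restarts; the
#' Levenberg--Marquardt fit with the lowest residual sum of squares is
#' returned, with asymptotic standard errors from the Jacobian at the
#' optimum. A fitted `Km` more than a decade outside the sampled
#' concentration range triggers an extrapolation warning.
#'
#' @param d an [uptake_dataset()] with >= 4 distinct concentrations.
#' @return Object of class `mm_fit` with `vmax`, `km_uM`, `se_vmax`,
#'   `se_km`, `rss`, and the underlying `nls` object.
#' @export
fit_michaelis_menten <- function(d) {
  stopifnot(inherits(d, "uptake_dataset"))
  if (length(unique(d$conc_uM)) < 4)
    stop("need >= 4 distinct concentrations")
  df <- data.frame(C = d$conc_uM, v = d$rate)
  if (all(df$v == 0)) stop("all rates zero: nothing to fit")
  pos <- df$v > 0
  if (sum(pos) >= 2) {
    lb <- stats::lm(I(1 / v) ~ I(1 / C), data = df[pos, ])
    vmax0 <- unname(1 / stats::coef(lb)[1])
    km0 <- unname(stats::coef(lb)[2]) * vmax0
  } else {
    vmax0 <- max(df$v); km0 <- stats::median(df$C)
  }
  if (!is.finite(vmax0) || vmax0 <= 0) vmax0 <- max(df$v)
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(df$C)
  starts <- list(c(vmax0, km0), c(2 * vmax0, km0), c(vmax0, 3 * km0),
                 c(0.5 * vmax0, 0.3 * km0))
  best <- NULL
  for (s in starts) {
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      v ~ vmax * C / (km + C), data = df,
      start = list(vmax = s[1], km = s[2]),
      lower = c(1e-12, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200))), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("Michaelis-Menten fit failed from all starts")
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) c(vmax = NA_real_, km = NA_real_))
  if (cf[["km"]] < min(df$C) / 10 || cf[["km"]] > max(df$C) * 10)
    warning("fitted Km outside [conc_min/10, conc_max*10]: extrapolation")
  structure(list(vmax = unname(cf[["vmax"]]), km_uM = unname(cf[["km"]]),
                 se_vmax = unname(se[["vmax"]]), se_km = unname(se[["km"]]),
                 rss = best$rss, nls = best$fit, data = df,
                 pair_id = d$pair_id),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit: Vmax %.4g (SE %.2g), Km %.4g uM (SE %.2g), RSS %.3g>\n",
              x$vmax, x$se_vmax, x$km_uM, x$se_km, x$rss))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) c(vmax = object$vmax, km = object$km_uM)

#' @export
predict.mm_fit <- function(object, conc_uM = object$data$C, ...)
  object$vmax * conc_uM / (object$km_uM + conc_uM)

#' Relative maximal uptake velocity of a mutant/WT pair
#'
#' @param fit_mut,fit_wt paired [fit_michaelis_menten()] results.
#' @return List with `fraction` (`vmax_mut / vmax_wt`) and
#'   `reduction_percent` (`100 * (1 - fraction)`).
#' @export
relative_vmax <- function(fit_mut, fit_wt) {
  stopifnot(inherits(fit_mut, "mm_fit"), inherits(fit_wt, "mm_fit"))
  if (fit_wt$vmax <= 0) stop("non-positive wild-type Vmax")
  fr <- fit_mut$vmax / fit_wt$vmax
  list(fraction = fr, reduction_percent = 100 * (1 - fr))
}

#' Microdialysis fraction series
#'
#' Dialysate dopamine concentrations per collection fraction, with the drug
#' administration time and the pre-drug baseline window (40 minutes by
#' default).
#'
#' @param t_min fraction midpoint times, minutes, strictly increasing.
#' @param da dopamine concentration per fraction (arbitrary or nM).
#' @param t_drug drug administration time, minutes.
#' @param baseline_window_min baseline window length (ending at `t_drug`).
#' @param truth optional generator ground truth.
#' @return Object of class `microdialysis_series`.
#' @export
microdialysis_series <- function(t_min, da, t_drug,
                                 baseline_window_min = 40, truth = NULL) {
  stopifnot(length(t_min) == length(da))
  if (any(diff(t_min) <= 0)) stop("fraction times must be increasing")
  if (baseline_window_min <= 0 || baseline_window_min > t_drug)
    stop("baseline window must be positive and wholly pre-drug")
  structure(list(t_min = t_min, da = da, t_drug = t_drug,
                 baseline_window_min = baseline_window_min, truth = truth),
            class = "microdialysis_series")
}

#' @export
print.microdialysis_series <- function(x, ...) {
  cat(sprintf("<microdialysis_series: %d fractions, drug at %g min>\n",
              length(x$da), x$t_drug))
  invisible(x)
}

#' Baseline and drug-response summary of a microdialysis series
#'
#' Baseline dialysate dopamine is the mean over the pre-drug baseline window
#' (>= 3 fractions required); the drug response is the maximum post-drug
#' fraction expressed as a fold of baseline, with the time of that peak.
#' `peak_fold` is invariant to multiplicative recalibration of the series.
#'
#' @param s a [microdialysis_series()].
#' @return List with `baseline_mean`, `peak_fold`, `t_peak` (min).
#' @export
microdialysis_summary <- function(s) {
  stopifnot(inherits(s, "microdialysis_series"))
  bsel <- s$t_min > s$t_drug - s$baseline_window_min - 1e-9 &
    s$t_min < s$t_drug
  if (sum(bsel) < 3) stop("need >= 3 baseline fractions")
  bl <- mean(s$da[bsel])
  if (bl <= 0) stop("non-positive baseline mean")
  post <- s$t_min > s$t_drug
  if (!any(post)) {
    return(list(baseline_mean = bl, peak_fold = 1, t_peak = NA_real_))
  }
  ipk <- which(post)[which.max(s$da[post])]
  list(baseline_mean = bl, peak_fold = max(s$da[post]) / bl,
       t_peak = s$t_min[ipk])
}

#' Baselines as percent of the wild-type group mean
#'
#' @param baselines numeric baseline means.
#' @param wt_baselines wild-type baseline means (non-empty).
#' @return Percent-of-WT-mean values.
#' @export
baseline_percent_of_wt <- function(baselines, wt_baselines) {
  if (!length(wt_baselines)) stop("empty wild-type group")
  100 * baselines / mean(wt_baselines)
}
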