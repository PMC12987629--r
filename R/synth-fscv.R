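#' Generate a synthetic evoked FSCV dopamine trace
#'
#' Emulates a single-pulse stimulated dopamine transient recorded by
#' fast-scan cyclic voltammetry in a striatal slice, using the
#' phenomenological release shape that the kinetics extractor measures:
#' zero before the stimulus, a linear rise from the stimulus to the peak at
#' `t_stim + ttp`, then a monoexponential decay with half-time `thalf`,
#' plus additive Gaussian noise. The shape is parameterized directly by
#' (peak, time-to-peak, half-time) so genotype fold-changes are exact
#' generator parameters and recovery is well-posed; a mechanistic
#' release/clearance model is deliberately out of scope.
#'
#' @param kin list with `peak_uM`, `ttp_s`, `thalf_s` — typically one region
#'   entry of `genotype_params(g)$fscv`.
#' @param noise_sd additive noise standard deviation, uM.
#' @param rng an [make_rng()] stream.
#' @param fs sampling rate, Hz (>= 100).
#' @param t_stim stimulus time, s from record start.
#' @param duration_s record length, s.
#' @param region,genotype,site,slice metadata labels.
#' @return An [fscv_trace()] whose `truth` holds the generating kinetics.
#' @export
gen_fscv_trace <- function(kin, noise_sd = 0, rng = make_rng(1, "fscv"),
                           fs = 100, t_stim = 2, duration_s = 12,
                           region = "DS", genotype = "WT",
                           site = 1L, slice = 1L) {
  stopifnot(fs >= 100, kin$peak_uM > 0)
  if (kin$ttp_s <= 2 / fs || kin$thalf_s <= 2 / fs)
    stop("kinetics unresolvable at this sampling rate (ttp or thalf <= 2/fs)")
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  x <- fscv_template(t, t_stim, kin$peak_uM, kin$ttp_s, kin$thalf_s)
  if (noise_sd > 0)
    x <- x + rng_draw(rng, stats::rnorm(n, 0, noise_sd))
  fscv_trace(
    ts = time_series(x, fs = fs, unit = "uM"),
    t_stim = t_stim, stim_kind = "single",
    region = region, genotype = genotype, site = site, slice = slice,
    truth = list(peak_uM = kin$peak_uM, ttp_s = kin$ttp_s,
                 thalf_s = kin$thalf_s, noise_sd = noise_sd))
}

# Canonical evoked-release shape: linear rise, exponential fall (base offset 0).
fscv_template <- function(t, t_stim, peak, ttp, thalf, baseline = 0) {
  dt <- t - t_stim
  x <- numeric(length(t))
  rise <- dt > 0 & dt <= ttp
  fall <- dt > ttp
  x[rise] <- peak * dt[rise] / ttp
  x[fall] <- peak * 2^(-(dt[fall] - ttp) / thalf)
  x + baseline
}
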