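#' Generate a synthetic saturation-uptake dataset
#'
#' Simulates a tritiated-dopamine synaptosomal uptake experiment: a six-point
#' two-fold dilution row (1 to 0.031 uM) with Michaelis--Menten rates
#' `v(C) = Vmax * C / (Km + C)` and multiplicative Gaussian noise
#' `v * (1 + eps)`, `eps ~ N(0, noise_cv)`.
#'
#' @param params a [genotype_params()] list (its `uptake` component is used).
#' @param n_replicates replicates per concentration.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param rng an [make_rng()] stream.
#' @param conc_uM concentration row, uM.
#' @return An [uptake_dataset()] with `truth` holding the generating
#'   `vmax` and `km_uM`.
#' @export
gen_uptake_dataset <- function(params, n_replicates = 3, noise_cv = 0.05,
                               rng = make_rng(1, "uptake"),
                               conc_uM = 1 / 2^(0:5)) {
  stopifnot(noise_cv >= 0, n_replicates >= 1)
  up <- params$uptake
  conc <- rep(conc_uM, each = n_replicates)
  v <- up$vmax * conc / (up$km_uM + conc)
  eps <- rng_draw(rng, stats::rnorm(length(conc), 0, noise_cv))
  uptake_dataset(
    conc_uM = conc, rate = v * (1 + eps),
    replicate = rep(seq_len(n_replicates), times = length(conc_uM)),
    truth = list(vmax = up$vmax, km_uM = up$km_uM, noise_cv = noise_cv))
}

#' Generate a synthetic microdialysis fraction series
#'
#' Emulates slow-flow microdialysis in anesthetized mice: a pre-drug baseline
#' sampled in fixed-length fractions over a 40-minute window, then an
#' amphetamine (AMPH) challenge producing a gamma-shaped dialysate dopamine
#' response whose maximum over the sampled fractions equals
#' `amph_peak_fold * baseline`. Baseline fractions carry multiplicative
#' Gaussian noise with coefficient of variation `noise_cv`; the post-drug
#' fractions follow the response shape itself, so the realized peak fold is
#' the generating parameter rather than a noise-selected maximum (the
#' summary statistic is a maximum over fractions, which would otherwise be
#' systematically inflated).
#'
#' The response peak is placed on a fraction midpoint (25 min after the drug
#' at the 10-min default fraction length) so the peak fold is realized
#' exactly by the sampled series, keeping recovery targets well-posed.
#'
#' @param genotype `"WT"` or `"MUT"` (selects [genotype_params()]).
#' @param n_fractions total number of fractions.
#' @param fraction_min fraction length, minutes.
#' @param noise_cv multiplicative noise CV (>= 0).
#' @param rng an [make_rng()] stream.
#' @param baseline_window_min pre-drug baseline window, minutes; the drug is
#'   administered at its end.
#' @return A [microdialysis_series()] with generator truth attached.
#' @export
gen_microdialysis_series <- function(genotype = c("WT", "MUT"),
                                     n_fractions = 10, fraction_min = 10,
                                     noise_cv = 0.1,
                                     rng = make_rng(1, "dialysis"),
                                     baseline_window_min = 40) {
  genotype <- match.arg(genotype)
  stopifnot(noise_cv >= 0)
  if (n_fractions * fraction_min <= baseline_window_min)
    stop("series must extend beyond the baseline window")
  dz <- genotype_params(genotype)$dialysis
  t_mid <- fraction_min * (seq_len(n_fractions) - 0.5)
  t_drug <- baseline_window_min
  tau_peak <- 2.5 * fraction_min   # midpoint of the 3rd post-drug fraction
  shape <- 2
  g <- ifelse(t_mid > t_drug,
              ((t_mid - t_drug) / tau_peak *
                 exp(1 - (t_mid - t_drug) / tau_peak))^shape,
              0)
  da <- dz$baseline * (1 + (dz$amph_peak_fold - 1) * g)
  eps <- rng_draw(rng, stats::rnorm(n_fractions, 0, noise_cv))
  eps[t_mid > t_drug] <- 0
  microdialysis_series(
    t_min = t_mid, da = da * (1 + eps), t_drug = t_drug,
    baseline_window_min = baseline_window_min,
    truth = list(genotype = genotype, baseline = dz$baseline,
                 amph_peak_fold = dz$amph_peak_fold))
}
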