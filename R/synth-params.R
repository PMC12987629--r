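#' Genotype effect-size parameter sets for the synthetic generators
#'
#' Returns the per-genotype parameters that the generators realize. Mutant
#' effects are stored as folds relative to wild type (WT), never re-derived:
#' a ~75% reduction in maximal uptake velocity with Km 0.16 uM (WT) vs
#' 0.25 uM (mutant); evoked-release peak penetrance of 6% of WT in dorsal
#' striatum (DS) and 22% in ventral striatum (VS), with dorsal time-to-peak
#' prolonged ~2.5-fold and clearance half-time ~5-fold; a 0.35 s DS-to-VS
#' photometry lag; amphetamine photometry responses of ~10 (DS) and ~35 (VS)
#' baseline SDs in WT; a 2.8-fold elevated mutant dialysate baseline; and
#' amphetamine dialysate peaks of 17-fold (WT) vs 1.6-fold (mutant) over
#' baseline.
#'
#' WT absolute kinetic anchors (peak 1.0 uM, time-to-peak 0.3 s, clearance
#' half-time 0.2 s; VS peak 0.6 uM) and the photometry event rates/kernels
#' are plausible design defaults for striatal slice and sensor data; only the
#' mutant/WT folds and the DS-to-VS lag are effect-size anchors. Mutant VS
#' kinetic folds default to (1.8x, 3x), smaller than the dorsal folds,
#' reflecting the weaker ventral penetrance.
#'
#' @param genotype `"WT"` or `"MUT"`.
#' @return Nested list with components `uptake`, `fscv`, `photometry`,
#'   `dialysis`.
#' @export
genotype_params <- function(genotype = c("WT", "MUT")) {
  genotype <- match.arg(genotype)
  wt <- list(
    uptake = list(vmax = 1.0, km_uM = 0.16),
    fscv = list(
      DS = list(peak_uM = 1.0, ttp_s = 0.3, thalf_s = 0.2),
      VS = list(peak_uM = 0.6, ttp_s = 0.3, thalf_s = 0.2)),
    photometry = list(
      event_rate_hz = 4, kernel_rise_s = 0.05, kernel_decay_s = 0.4,
      event_amp = 1.0, slow_wave_tau_s = 45, slow_wave_sd = 0,
      ds_vs_delay_s = 0.35, vs_gain = 0.5,
      vs_rate_hz = 1.5, vs_kernel_decay_s = 1.0, vs_event_amp = 0.7,
      amph_peak_in_baseline_sd = c(DS = 10, VS = 35)),
    dialysis = list(baseline = 1.0, amph_peak_fold = 17))
  if (genotype == "WT") return(wt)
  mut <- wt
  mut$uptake <- list(vmax = 0.25, km_uM = 0.25)
  mut$fscv$DS <- list(peak_uM = 0.06 * wt$fscv$DS$peak_uM,
                      ttp_s = 2.5 * wt$fscv$DS$ttp_s,
                      thalf_s = 5 * wt$fscv$DS$thalf_s)
  mut$fscv$VS <- list(peak_uM = 0.22 * wt$fscv$VS$peak_uM,
                      ttp_s = 1.8 * wt$fscv$VS$ttp_s,
                      thalf_s = 3 * wt$fscv$VS$thalf_s)
  mut$photometry$event_amp <- 0.1 * wt$photometry$event_amp
  mut$photometry$vs_event_amp <- 0.1 * wt$photometry$vs_event_amp
  mut$photometry$slow_wave_sd <- 1.0
  mut$photometry$amph_peak_in_baseline_sd <- c(DS = 10, VS = 5)
  mut$dialysis <- list(baseline = 2.8, amph_peak_fold = 1.6)
  mut
}
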