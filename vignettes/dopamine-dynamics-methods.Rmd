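---
title: "Methods: quantifying striatal dopamine dysfunction with datdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying striatal dopamine dysfunction with datdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(datdyn)
```

# Scope and model of the data

`datdyn` implements the quantitative analyses used to characterize dopamine
(DA) dysfunction in dopamine-transporter (DAT) deficient mice across five
measurement modalities, together with seeded synthetic generators that
produce each input class with known ground truth. The package is organized
around the measurements:

* **Fiber photometry** (dual-site dLight-type sensor recordings in dorsal
  and ventral striatum, DS/VS): isosbestic motion correction, baseline
  z-scoring, zero-phase band-pass filtering, spectral energy density,
  decile-binned first-derivative variance heterogeneity testing, DS-to-VS
  cross-correlation lag estimation, and amphetamine (AMPH) response
  summaries.
* **Fast-scan cyclic voltammetry (FSCV)**: peak evoked concentration,
  time-to-peak (TTP), clearance half-time, D2-autoreceptor disinhibition
  and regional penetrance.
* **Synaptosomal uptake**: Michaelis–Menten fitting of saturation-uptake
  curves, paired mutant/wild-type Vmax comparison.
* **Microdialysis**: 40-minute baseline quantification and peak
  drug-response folds.
* **Confocal fiber imaging**: line-grid intercept density of labeled axons.

Every analysis stage can be exercised end to end on synthetic data: the
generators are parameterized by the genotype effect sizes the analyses are
meant to recover (`genotype_params()`), so estimator-against-truth agreement
is the package's core test surface.

# Photometry preprocessing

## Isosbestic correction

The 415 nm isosbestic channel tracks motion and bleaching but not dopamine.
`isosbestic_correct()` fits the isosbestic channel to the 470 nm signal
channel by affine least squares and reports
$\Delta F/F = (F_{470} - f(F_{415}))/f(F_{415})$ with
$f(x) = \hat a x + \hat b$. Because the fit is affine, the result is
invariant to affine transforms of the control channel; a constant control
falls back to intercept-only subtraction with a warning rather than
failing, since a flat isosbestic channel simply means there is no artifact
to remove.

## Filtering and normalization

Rapid DA fluctuations are isolated in the 0.01–10 Hz band
(`analysis_config()` defaults). `bandpass()` is a frequency-domain filter
with raised-cosine transition edges rather than a forward–backward IIR
cascade: at a 0.01 Hz low edge a recursive filter's poles sit extremely
close to the unit circle and its transients span minutes, whereas the FFT
implementation is exactly zero-phase (no bias in time-to-peak or lag
estimates), has unit passband gain, removes DC exactly, and behaves
identically at every band setting. Signals are reflect-padded by three
low-edge time constants before transforming, which suppresses wrap-around
artifacts; no additional edge-exclusion window is needed. When a recording
is sampled at 20 Hz the nominal 10 Hz upper edge sits at the Nyquist
frequency; `fast_amplitude()` clamps the upper edge to $0.45 f_s$ and
records the clamp, so the default band remains usable on the default
sampling rate.

`zscore_to_baseline()` normalizes to the mean and SD of a designated
baseline window, so drug responses are expressed in baseline-SD units.
Whether published spectra were computed on z-scored ΔF/F or raw
fluorescence is not always stated; this package z-scores ΔF/F and records
the choice in each trace's provenance field.

# Dopamine dynamics analytics

## Spectral energy density

`spectral_energy_density()` is an averaged-periodogram (Welch) estimate:
Hann-windowed, mean-detrended segments (60 s, 50 % overlap by default),
normalized so that $\int E(f)\,df$ equals the signal variance (checked to
5 % as a test invariant). Densities are rebinned onto a fixed log-spaced
grid by integral-conserving aggregation, so sessions share a grid and can
be compared bin-wise. Group comparison (`compare_spectra()`) uses bin-wise
two-sample t tests on log density with Holm–Šidák step-down adjustment.
The choice of a Welch estimator over multitaper alternatives is recorded
here as a package decision; at the 600–1800 s record lengths involved the
averaged periodogram has ample segments for stable estimates.

## Heterogeneity of DA fluctuations

If DA release were a homogeneous (constant-rate) shot-noise process, the
variance of the one-sample first difference $d(i) = x(i{+}1) - x(i)$,
conditioned on the current signal level, would be the same at every level.
`decile_variance_profile()` bins interior samples into signal-intensity
deciles (empirical quantiles with stable ranking; ties go to the lower
bin) and estimates the conditional increment variance per bin, normalized
to the bottom decile.

One estimator detail matters. Within a bin, the increment retains a
deterministic linear dependence on the level (for any mean-reverting
signal $E[d \mid x] \propto -x$; for i.i.d. noise $E[d \mid x] = \mu - x$).
The plain within-bin variance therefore conflates mean structure with
increment variance, and the wide tail deciles would read high even for
i.i.d. noise. The estimator removes the within-bin linear level dependence
(per-bin least-squares residual variance), which restores exact flatness
for i.i.d. noise and for homogeneous shot noise while leaving genuine
state-dependent release variance untouched. The differencing interval is
one sample at the analysis rate (20 Hz default); the normalized profile is
interval-invariant under the homogeneous null, which is the property the
test uses.

`heterogeneity_test()` performs, for each decile above the first, a
one-sample t test of $\log v_{\text{norm}}$ against 0 across sessions,
with Benjamini–Hochberg correction across the nine comparisons. This is a
deliberate simplification of a repeated-measures ANOVA followed by
simple-effect contrasts: the decisions that matter are the per-decile
simple effects, and the BH-corrected t tests reproduce them directly. The
test requires at least three sessions. Calibration is verified by
simulation: over 500 groups of nine homogeneous-Poisson sessions
(constant 2 events/s, 0.3 s kernel decay, noise SD 0.05, 10 min at
20 Hz), the family type-I error must stay at or below the nominal 0.05
(plus two Monte-Carlo standard errors); the acceptance script recomputes
this fraction on every run.

## Cross-correlation and drug response

`cross_correlate()` computes the normalized cross-correlation
$r(\tau) = \mathrm{cor}(ds(t),\, vs(t{+}\tau))$ on a symmetric lag grid;
positive peak lag means the DS signal precedes the VS signal. The peak is
refined by a three-point parabolic fit, giving sub-sample resolution.
Group curves are averaged across sessions before peak extraction
(`average_crosscorr()`), matching group-level reporting; per-session peaks
remain available. `drug_response_summary()` re-references the trace to the
pre-injection baseline and reports the trapezoidal area under the curve
(no smoothing), the peak in baseline-SD units, and fast-component
amplitudes over equal-length pre/post windows.

# FSCV kinetics

The evoked transient is summarized by peak concentration above baseline,
TTP, and clearance half-time — the first time after the peak at which the
signal falls to baseline plus half the peak (linear interpolation between
samples). Measuring the half-time to *baseline plus* half peak, rather
than to an absolute half peak, makes the readout invariant to constant
baseline offsets.

The peak estimator adapts to the noise level. On a noiseless trace the
sample maximum is exact and is used directly. On a noisy trace the sample
maximum is biased upward by noise selection — severely so for the small
mutant DS transients, where the bias would roughly double a 0.06 µM peak
at 0.02 µM noise — so the readouts are refined by least-squares fitting of
the canonical linear-rise/exponential-fall transient template (free
baseline offset), initialized from a lightly smoothed trace and restarted
from perturbed initializations. The recovery contract, checked in the test
suite, is a median absolute relative error below 5 % at noise equal to 5 %
of the wild-type peak. Sites whose smoothed post-stimulus signal never
exceeds the baseline mean plus four baseline SDs (of the same smoothed
signal) are below detection and raise an error; callers exclude and log
them rather than imputing zeros, mirroring the paired per-site design.
Traces that never decay to half peak within the record are censored
(`thalf_s = NA`) rather than extrapolated. The peak search window is 5 s
after the stimulus.

`region_penetrance()` expresses mutant values as percent of the matched
wild-type regional mean; `disinhibition_percent()` is the paired
antagonist/baseline peak ratio; `aggregate_sites()` averages recording
sites within a slice before any genotype statistic.

# Michaelis–Menten uptake and microdialysis

`fit_michaelis_menten()` fits $v = V_{\max} C / (K_m + C)$ by
Levenberg–Marquardt least squares, started from the Lineweaver–Burk
linearization plus three perturbed restarts (the linearization is
noise-sensitive but an excellent starting point), with asymptotic standard
errors from the Jacobian at the optimum. Fits are scale-equivariant in the
rates, and a fitted $K_m$ more than a decade outside the sampled
concentration range triggers an extrapolation warning. Paired genotype
comparison (`relative_vmax()`) normalizes within pairs before any group
aggregation. No outlier screen is applied by default.

`microdialysis_summary()` reports the mean dialysate DA over the 40-minute
pre-drug window and the maximum post-drug fraction as a fold of that
baseline — a measure invariant to multiplicative recalibration. Baselines
convert to percent-of-wild-type with `baseline_percent_of_wt()`; both raw
and percent scales are reported because published units are
presentation-dependent.

# Fiber-density imaging

`area_density()` lays a grid of horizontal and vertical scan lines
(25 µm spacing by default, half-spacing border offset) over a calibrated
image, counts intensity peaks along each line, and reports crossings per
100 µm of scanned line. A crossing is a local maximum of the
PSF-scale-smoothed profile (0.5 µm Gaussian) exceeding the profile mean
plus one SD, with maxima closer than 1 µm merged. Peak counting (rather
than threshold-crossing counting) was chosen because it is robust to fiber
thickness; the pre-smoothing suppresses shot-noise ripples along fibers
that run nearly parallel to a scan line, which would otherwise split one
anatomical crossing into several counts. All parameters are exposed.
Counts are invariant to intensity rescaling because both the smoothing and
the threshold are linear in intensity. Image-level and animal-level
summaries are both supported, and for synthetic images
`true_crossings()` computes the exact polyline–grid intersections for
recall/precision scoring (true crossings closer than the detector
resolution are counted once, since the merge rule is part of the
detector's contract).

# The synthetic generators

The generators realize the genotype effect sizes as exact parameters so
that recovery targets are well-posed:

* **Uptake** (`gen_uptake_dataset()`): six-point two-fold dilution row
  (1–0.031 µM) with multiplicative Gaussian noise; wild type
  $V_{\max} = 1$ (normalized), $K_m = 0.16$ µM; mutant
  $V_{\max} = 0.25$, $K_m = 0.25$ µM.
* **FSCV** (`gen_fscv_trace()`): phenomenological linear-rise /
  exponential-fall transient parameterized directly by peak, TTP and
  half-time, rather than a mechanistic release–clearance model — the
  fold-changes are then exact generator parameters. Wild-type anchors
  (DS peak 1.0 µM, VS 0.6 µM, TTP 0.3 s, half-time 0.2 s) are plausible
  slice-recording defaults; the mutant DS folds (peak 6 % of WT,
  TTP ×2.5, half-time ×5) and VS peak penetrance (22 %) are the anchored
  effect sizes. Mutant VS kinetic folds default to (×1.8, ×3), smaller
  than DS, reflecting the weaker ventral penetrance; since exact ventral
  folds are unspecified they are not recovery-tested.
* **Photometry** (`gen_photometry_session()`): wild-type DS is shot noise
  from a log-Gaussian doubly stochastic rate (4 events/s mean, 2 s rate
  correlation time) through a 0.05 s-rise / 0.4 s-decay kernel; VS is a
  half-gain, smoothed copy of DS delayed by 0.35 s plus an independent
  slower shot-noise component (1 s decay). The mutant scales event
  amplitudes by 0.1 and superimposes a dominating Ornstein–Uhlenbeck slow
  wave, implemented as the simplest stationary process with a single
  timescale knob (45 s correlation time). Both recorded channels are
  synthesized from the latent DA signal with a shared low-frequency
  artifact and independent white noise, so isosbestic correction is
  exercised end to end; in the homogeneous (constant-rate,
  single-exponential-kernel) null mode the artifact and slow wave are off
  and the effective noise on the DA scale equals the stated noise SD
  exactly. An optional AMPH event adds a saturating response scaled in
  measured pre-injection baseline SDs (wild type ~10 in DS, ~35 in VS).
  Sensor kinetics and the 20 Hz default rate are assumptions, flagged in
  the session metadata.
* **Microdialysis** (`gen_microdialysis_series()`): 10-minute fractions
  (a slow-flow default), a 40-minute baseline window with multiplicative
  Gaussian fraction noise, then a gamma-shaped response whose peak falls
  exactly on a fraction midpoint 2.5 fractions after the drug, so the
  sampled series realizes the peak fold (17× wild type, 1.6× mutant)
  exactly; the mutant baseline is 2.8× the wild type. Noise is applied to
  the baseline fractions: since the summary statistic is a maximum over
  post-drug fractions, noisy post-drug fractions would make the realized
  peak fold a noise-selected maximum, systematically above the generating
  parameter.
* **Fiber images** (`gen_fiber_image()`): unit-speed random walks with
  small angular diffusion, fixed line intensity, Gaussian PSF blur and
  Poisson-like shot noise, with every polyline recorded for exact
  crossing-truth computation.

What the generators do *not* emulate: mechanistic D2-autoreceptor
feedback, AMPH pharmacokinetics, sensor saturation, bleaching trends
beyond the shared artifact, behavioral-state dependence of release, and
optical bleed-through. Passing recovery tests therefore demonstrates that
the estimators are correct and calibrated on signals with the right
first- and second-order structure — not that they are robust to every
artifact of real recordings.

# Numerical choices and problem sizes

Deterministic seeding routes every draw through labelled streams
(`make_rng()`): identical (seed, label) pairs are bit-reproducible, and
distinct stages never share a stream, so adding draws to one stage cannot
perturb another. Event times are converted to sample indices by rounding
to the nearest sample; interleaved photometry channels are aligned by
linear interpolation onto the isosbestic timestamps (the reference grid),
with constant extension at the record edges. Unit tags (`au`, `dff`, `z`,
`uM`) travel with every series and mismatches are errors, never silent
conversions.

The test suite and the acceptance script use problem sizes chosen to make
Monte-Carlo tolerances meaningful while keeping a full run to a few
minutes: 4 uptake pairs, 8 FSCV traces per genotype and region, 7 + 6
microdialysis sessions, 8 thirty-minute photometry pairs, and 500
nine-session groups for the null calibration (150 groups in the unit test,
with the Monte-Carlo tolerance widened accordingly).

# Known limitations

The FSCV template fit assumes the canonical single-transient shape and is
not designed for train-stimulation overflow curves with complex shapes;
the spectral comparison assumes a shared sampling rate and window across
sessions; the line-grid density is a proxy for areal fiber density and
saturates as fibers become dense enough to overlap within the PSF; and
the photometry generator's mutant slow wave is a descriptive, not
mechanistic, account of the slow DA oscillations.
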