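# datdyn

Quantitative analysis of striatal dopamine dysfunction in
dopamine-transporter (DAT) deficient mouse models.

Loss-of-function DAT variants cause dopamine transporter deficiency
syndrome; its atypical, adult-onset form combines parkinsonism with
neuropsychiatric features. Characterizing such models requires a battery
of neurochemical measurements, each with its own quantitative pipeline.
`datdyn` implements those pipelines as tested, reusable R functions, for
researchers analyzing:

* **dual-site fiber photometry** (dorsal/ventral striatum, DS/VS):
  isosbestic motion correction, baseline z-scoring, zero-phase 0.01–10 Hz
  band-pass filtering, Welch-style spectral energy density with
  Holm–Šidák group comparison, a decile-binned first-derivative variance
  **heterogeneity test** (Benjamini–Hochberg across deciles), DS→VS
  **cross-correlation lag** estimation with sub-sample peak refinement,
  and amphetamine (AMPH) response summaries (AUC, peak in baseline-SD
  units, fast-component amplitude);
* **fast-scan cyclic voltammetry (FSCV)**: peak evoked [DA], time to peak
  (TTP), clearance half-time t½, D2-autoreceptor disinhibition, regional
  penetrance as percent of wild type;
* **synaptosomal uptake**: Michaelis–Menten fitting
  (v = Vmax·C/(Km+C), Levenberg–Marquardt with Lineweaver–Burk multistart)
  and paired relative-Vmax comparison;
* **microdialysis**: 40-minute baseline quantification and peak
  drug-response folds;
* **confocal fiber imaging**: line-grid intercept density of DAT/TH-labeled
  axons (crossings per 100 µm of scan line).

A seeded synthetic-data module (`gen_*` functions) generates every input
class with known ground truth, parameterized by genotype effect sizes
(`genotype_params()`): ~75 % Vmax reduction, 6 %/22 % DS/VS release
penetrance, 2.5×/5× DS kinetic folds, a 0.35 s DS→VS coupling lag, 2.8×
baseline dialysate elevation and 17×/1.6× AMPH response folds. Every
analysis stage is validated by recovering these parameters from generated
data.

## Worked example

Simulate a wild-type photometry session, preprocess both regions, and
measure the DS→VS coupling and signal heterogeneity:

```r
library(datdyn)

pair <- gen_photometry_session("WT", duration_s = 600, fs = 20,
                               rng = make_rng(1, "demo"))
zd <- zscore_to_baseline(isosbestic_correct(pair$DS$raw470, pair$DS$raw415),
                         c(0, 60))
zv <- zscore_to_baseline(isosbestic_correct(pair$VS$raw470, pair$VS$raw415),
                         c(0, 60))
cross_correlate(zd, zv, max_lag_s = 5)
#> <crosscorr: peak r=0.773 at lag 0.351 s (201 lags)>
decile_variance_profile(zd)
#> <decile_variance_profile>
#>   v_norm: 1.000 1.134 1.212 1.421 1.431 1.599 1.944 2.465 2.845 3.891
```

The positive 0.35 s peak lag says the dorsal signal leads the ventral
signal by about a third of a second, and the rising variance profile
(top decile ≈ 3.9× the bottom) says the increments of the DA signal grow
with signal intensity — the signature of structured, state-dependent
release; a homogeneous Poisson process would give a flat profile near 1.

Fit saturation-uptake kinetics and compare genotypes:

```r
wt <- fit_michaelis_menten(gen_uptake_dataset(genotype_params("WT"), 3,
                                              0.05, make_rng(1, "demo_up")))
mut <- fit_michaelis_menten(gen_uptake_dataset(genotype_params("MUT"), 3,
                                               0.05, make_rng(2, "demo_up")))
wt
#> <mm_fit: Vmax 0.9948 (SE 0.02), Km 0.1506 uM (SE 0.009), RSS 0.0104>
relative_vmax(mut, wt)
#> $fraction
#> [1] 0.2524 ...   # ~75% reduction in maximal uptake velocity
```

Here the fitted wild-type Km (~0.15 µM against a generating value of
0.16 µM) and the mutant/wild-type Vmax fraction (~0.25) recover the
generator's genotype parameters from noisy six-point dilution curves.

See the methods vignette
(`vignettes/dopamine-dynamics-methods.Rmd`) for the models, estimator
details, and the design decisions behind each stage.

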