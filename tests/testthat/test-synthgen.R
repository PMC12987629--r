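test_that("uptake generator reproduces Michaelis-Menten values exactly at zero noise", {
  d <- gen_uptake_dataset(genotype_params("WT"), n_replicates = 1,
                          noise_cv = 0, rng = make_rng(1, "u0"))
  # C = Km = 0.16 uM gives exactly Vmax / 2
  at_km <- mm_rate(0.16, 1, 0.16)
  expect_equal(at_km, 0.5)
  # closed-form at C = 1 uM: 1 * 1 / (1 + 0.16)
  expect_equal(round(d$rate[d$conc_uM == 1], 4), 0.8621)
  expect_equal(d$conc_uM, 1 / 2^(0:5))
  d2 <- gen_uptake_dataset(genotype_params("WT"), n_replicates = 1,
                           noise_cv = 0, rng = make_rng(1, "u0"))
  expect_identical(d$rate, d2$rate)
})

test_that("fscv generator realizes the requested kinetics exactly", {
  kin <- genotype_params("WT")$fscv$DS
  tr <- gen_fscv_trace(kin, noise_sd = 0)
  i <- which.max(tr$ts$x)
  expect_equal(max(tr$ts$x), 1.0)
  expect_equal(tr$ts$t[i] - tr$t_stim, 0.3)
  # half-time definition: value at t_stim + ttp + thalf is half the peak
  j <- which.min(abs(tr$ts$t - (tr$t_stim + 0.3 + 0.2)))
  expect_equal(tr$ts$x[j], 0.5)
  # mutant folds are generator parameters
  mkin <- genotype_params("MUT")$fscv$DS
  expect_equal(mkin$ttp_s / kin$ttp_s, 2.5)
  expect_equal(mkin$thalf_s / kin$thalf_s, 5)
  expect_error(gen_fscv_trace(list(peak_uM = 1, ttp_s = 0.01, thalf_s = 0.2)),
               "unresolvable")
})

test_that("photometry generator is seed-deterministic", {
  a <- gen_photometry_session("WT", duration_s = 60, fs = 20,
                              rng = make_rng(5, "det"))
  b <- gen_photometry_session("WT", duration_s = 60, fs = 20,
                              rng = make_rng(5, "det"))
  expect_identical(a$DS$raw470$x, b$DS$raw470$x)
  expect_identical(a$VS$raw415$x, b$VS$raw415$x)
})

test_that("homogeneous mode realizes the nominal Poisson event count", {
  s <- gen_photometry_session("WT", duration_s = 600, fs = 20,
                              rng = make_rng(11, "pois"),
                              mode = "homogeneous", event_rate_hz = 2)
  # mean 1200 events; 4 SD Poisson bound
  expect_lt(abs(s$DS$truth$n_events - 1200), 4 * sqrt(1200))
})

test_that("WT has more high-frequency spectral energy than MUT at matched seed", {
  fr <- sapply(c("WT", "MUT"), function(g) {
    s <- gen_photometry_session(g, duration_s = 600, fs = 20,
                                rng = make_rng(3, "spec_pair"))
    z <- zscore_to_baseline(
      isosbestic_correct(s$DS$raw470, s$DS$raw415), c(0, 60))
    spectral_fraction_above(spectral_energy_density(z), 0.5)
  })
  expect_gt(fr[["WT"]], fr[["MUT"]])
})

test_that("shot-noise convolution is linear in event amplitude", {
  # doubling amplitude doubles the noiseless event component
  p1 <- genotype_params("WT"); p2 <- genotype_params("WT")
  p2$photometry$event_amp <- 2 * p1$photometry$event_amp
  p2$photometry$vs_event_amp <- 2 * p1$photometry$vs_event_amp
  s1 <- gen_photometry_session("WT", duration_s = 60, fs = 20,
                               rng = make_rng(9, "lin"), params = p1,
                               noise_sd = 0)
  s2 <- gen_photometry_session("WT", duration_s = 60, fs = 20,
                               rng = make_rng(9, "lin"), params = p2,
                               noise_sd = 0)
  expect_equal(s2$DS$truth$da, 2 * s1$DS$truth$da, tolerance = 1e-12)
})

test_that("homogeneous increments have level-independent conditional variance", {
  # premise of the heterogeneity test: across sessions the mean log
  # variance ratio is ~0 in every decile (per-session ratios carry ~6%
  # sampling noise per bin)
  lv <- sapply(1:6, function(sd) {
    s <- gen_photometry_session("WT", duration_s = 600, fs = 20,
                                rng = make_rng(sd, "premise"),
                                mode = "homogeneous", event_rate_hz = 2,
                                kernel_decay_s = 0.3, noise_sd = 0.05)
    z <- zscore_to_baseline(
      isosbestic_correct(s$DS$raw470, s$DS$raw415), c(0, 60))
    log(decile_variance_profile(z)$v_norm)
  })
  expect_true(all(abs(rowMeans(lv)) < 0.1))
})

test_that("microdialysis generator hits its baseline and peak folds exactly", {
  wt <- gen_microdialysis_series("WT", noise_cv = 0,
                                 rng = make_rng(1, "md0"))
  mu <- gen_microdialysis_series("MUT", noise_cv = 0,
                                 rng = make_rng(1, "md0"))
  pre <- wt$t_min < wt$t_drug
  expect_true(all(wt$da[pre] == wt$da[pre][1]))   # flat pre-drug baseline
  expect_equal(max(wt$da[!pre]) / mean(wt$da[pre]), 17)
  expect_equal(mean(mu$da[pre]) / mean(wt$da[pre]), 2.8)
  expect_equal(max(mu$da[!pre]) / mean(mu$da[pre]), 1.6)
  expect_error(gen_microdialysis_series("WT", n_fractions = 3,
                                        fraction_min = 10),
               "beyond the baseline window")
})

test_that("fiber image generator records exact crossing ground truth", {
  # three straight vertical fibers, one horizontal grid line
  f3 <- lapply(c(20, 50, 80), function(x) data.frame(x = c(x, x),
                                                     y = c(1, 100)))
  img <- gen_fiber_image(0, size_px = 100, um_per_px = 1, psf_sigma_px = 1,
                         noise_level = 0, rng = make_rng(1, "ff"),
                         fibers = f3)
  tc <- true_crossings(img, spacing_um = 60, orientations = "horizontal")
  expect_true(all(tc$n_true == 3))
  expect_equal(sort(tc$hit_px[[1]]), c(20, 50, 80))
  # empty image: pure noise, zero true crossings
  img0 <- gen_fiber_image(0, size_px = 64, rng = make_rng(2, "ff0"))
  expect_equal(sum(true_crossings(img0)$n_true), 0)
  expect_true(all(img0$pixels >= 0))
  # determinism
  a <- gen_fiber_image(7, size_px = 64, rng = make_rng(5, "ffd"))
  b <- gen_fiber_image(7, size_px = 64, rng = make_rng(5, "ffd"))
  expect_identical(a$pixels, b$pixels)
})
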