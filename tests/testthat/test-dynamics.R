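test_that("spectral energy density satisfies Parseval normalization", {
  expect_equal(spectral_energy_density(
    time_series(rep(0, 12000), fs = 20))$e, rep(0, 48))
  set.seed(5)
  wn <- time_series(rnorm(12000), fs = 20, unit = "z")  # 600 s at 20 Hz
  sd_obj <- spectral_energy_density(wn)
  tot <- sum(sd_obj$e * sd_obj$df)
  expect_gt(tot, 0.95); expect_lt(tot, 1.05)
  # and on generator output
  s <- gen_photometry_session("WT", duration_s = 300, fs = 20,
                              rng = make_rng(6, "pars"))
  z <- zscore_to_baseline(isosbestic_correct(s$DS$raw470, s$DS$raw415),
                          c(0, 60))
  so <- spectral_energy_density(z)
  expect_lt(abs(sum(so$e * so$df) / stats::var(z$ts$x) - 1), 0.05)
})

test_that("a pure sinusoid concentrates its energy in one reporting bin", {
  s <- make_sine(1, 20, 600)
  so <- spectral_energy_density(s)
  k <- which.min(abs(so$f - 1))
  expect_gt(so$e[k] * so$df[k] / sum(so$e * so$df), 0.9)
  expect_error(spectral_energy_density(make_sine(1, 20, 30)),
               "shorter than one Welch window")
})

test_that("spectra comparison rejects nothing on copied groups and needs n >= 2", {
  g <- lapply(1:4, function(s) {
    set.seed(s)
    spectral_energy_density(time_series(rnorm(12000), fs = 20, unit = "z"))
  })
  res <- compare_spectra(g, g)
  expect_equal(sum(res$reject), 0L)
  expect_error(compare_spectra(g[1], g), ">= 2 sessions")
})

test_that("spectra comparison localizes an injected band difference", {
  mk <- function(seed, boost) {
    set.seed(seed)
    x <- rnorm(24000)
    if (boost) {
      t <- seq_len(24000) / 20
      # narrow-band energy near 2 Hz, well inside the grid
      x <- x + 3 * sin(2 * pi * 2 * t + stats::runif(1, 0, 2 * pi))
    }
    spectral_energy_density(time_series(x, fs = 20, unit = "z"))
  }
  ga <- lapply(1:6, mk, boost = FALSE)
  gb <- lapply(7:12, mk, boost = TRUE)
  res <- compare_spectra(ga, gb)
  expect_gt(sum(res$reject), 0)
  # rejections confined to the neighbourhood of 2 Hz
  expect_true(all(abs(res$f[res$reject] - 2) < 0.6))
})

test_that("decile variance profile is flat for i.i.d. noise and normalized", {
  set.seed(7)
  pr <- decile_variance_profile(time_series(rnorm(1e5), fs = 20, unit = "z"))
  expect_equal(pr$v_norm[1], 1)
  expect_true(all(pr$v_norm > 0.9 & pr$v_norm < 1.1))
  expect_equal(sum(pr$n_per_bin), 1e5 - 1)
})

test_that("decile variance profile rises for state-dependent step sizes", {
  # constructed signal: small steps at low values, 10x steps at high values
  set.seed(8)
  n <- 6000
  x <- numeric(n)
  for (i in 2:n) {
    lo <- 0.05; hi <- 3
    step <- if (x[i - 1] < 2) lo else hi
    x[i] <- x[i - 1] + rnorm(1, 0, step) +
      0.02 * (2 - x[i - 1])   # weak mean reversion spanning levels
  }
  pr <- decile_variance_profile(time_series(x, fs = 20, unit = "z"),
                                n_deciles = 5)
  expect_true(all(diff(pr$v_norm) >= 0) || pr$v_norm[5] > 5 * pr$v_norm[1])
  expect_error(decile_variance_profile(time_series(rnorm(50), fs = 1,
                                                   unit = "z")),
               "too few samples")
})

test_that("heterogeneity test needs 3 sessions and detects WT structure", {
  profs <- lapply(1:9, function(s) {
    p <- gen_photometry_session("WT", duration_s = 600, fs = 20,
                                rng = make_rng(s, "het_power"))
    z <- zscore_to_baseline(isosbestic_correct(p$DS$raw470, p$DS$raw415),
                            c(0, 60))
    decile_variance_profile(z)
  })
  expect_error(heterogeneity_test(profs[1:2]), ">= 3 sessions")
  res <- heterogeneity_test(profs)
  expect_true(res$reject[res$decile == 10])
})

test_that("cross-correlation identifies identity, pure delay and independence", {
  set.seed(9)
  x <- as.numeric(stats::filter(rnorm(12000), 0.8, method = "recursive"))
  ds <- time_series(x, fs = 20, unit = "z")
  id <- cross_correlate(ds, ds, max_lag_s = 5)
  expect_equal(id$peak_lag, 0)
  expect_equal(id$peak_r, 1, tolerance = 1e-9)
  # vs = ds delayed by exactly 7 samples at 20 Hz -> 0.35 s
  vs <- time_series(c(rep(x[1], 7), x[1:(12000 - 7)]), fs = 20, unit = "z")
  del <- cross_correlate(ds, vs, max_lag_s = 5)
  expect_lt(abs(del$peak_lag - 0.35), 0.025)
  set.seed(10)
  ind <- cross_correlate(time_series(rnorm(12000), fs = 20, unit = "z"),
                         time_series(rnorm(12000), fs = 20, unit = "z"),
                         max_lag_s = 5)
  expect_lt(abs(ind$peak_r), 0.1)
  expect_error(cross_correlate(ds, vs, max_lag_s = 400), "half the record")
})

test_that("cross-correlation recovers injected lags at low SNR", {
  for (lag_s in c(0.1, 0.35, 1.0)) {
    set.seed(round(lag_s * 100))
    sig <- as.numeric(stats::filter(rnorm(24000), 0.85,
                                    method = "recursive"))
    k <- round(lag_s * 20)
    noise_amp <- stats::sd(sig)   # SNR 1
    a <- sig + rnorm(24000, 0, noise_amp)
    b <- c(rep(0, k), sig[1:(24000 - k)]) + rnorm(24000, 0, noise_amp)
    xc <- cross_correlate(time_series(a, fs = 20, unit = "z"),
                          time_series(b, fs = 20, unit = "z"), max_lag_s = 5)
    expect_lt(abs(xc$peak_lag - lag_s), 0.025)
  }
})

test_that("fast amplitude matches the closed form for an in-band sinusoid", {
  expect_equal(as.numeric(fast_amplitude(
    time_series(rep(0, 6000), fs = 100, unit = "z"), c(10, 50))), 0)
  s <- make_sine(1, 100, 120)
  amp <- as.numeric(fast_amplitude(s, c(20, 100)))
  expect_equal(amp, 2 / pi, tolerance = 0.02)
  neg <- s; neg$x <- -neg$x
  expect_equal(as.numeric(fast_amplitude(neg, c(20, 100))), amp)
  expect_error(fast_amplitude(s, c(50, 50)), "empty window")
})

test_that("drug response summary integrates rectangles and triangles", {
  fs <- 10
  t <- seq(0, 599.9, by = 1 / fs)
  # baseline jitter defines the SD scale; the post-injection segment is
  # deterministic, so the rectangle height in baseline-SD units is exact
  set.seed(11)
  base_sd <- 0.01
  pre <- t <= 300
  x <- numeric(length(t))
  x[pre] <- rnorm(sum(pre), 0, base_sd)
  rect <- t > 300 & t <= 400
  x[rect] <- 5 * base_sd
  dr <- drug_response_summary(time_series(x, fs = fs, unit = "z"),
                              t_inject = 300)
  expect_equal(dr$auc, 500, tolerance = 0.03)
  expect_equal(dr$peak_z, 5, tolerance = 0.03)
  # triangle rising to 10 SD over 60 s then back
  y <- numeric(length(t))
  y[pre] <- rnorm(sum(pre), 0, base_sd)
  tri <- pmax(0, 1 - abs(t - 360) / 60)
  y[!pre] <- 10 * base_sd * tri[!pre]
  dt <- drug_response_summary(time_series(y, fs = fs, unit = "z"),
                              t_inject = 300)
  expect_equal(dt$auc, 600, tolerance = 0.03)
  expect_error(drug_response_summary(time_series(y, fs = fs, unit = "z"),
                                     t_inject = 700), "outside record")
})

test_that("amphetamine event produces the configured baseline-SD response", {
  s <- gen_photometry_session("WT", duration_s = 1200, fs = 20,
                              rng = make_rng(12, "amph"),
                              amph_time_s = 400)
  z <- zscore_to_baseline(isosbestic_correct(s$VS$raw470, s$VS$raw415),
                          c(0, 390))
  dr <- drug_response_summary(z, t_inject = 400,
                              baseline_window = c(0, 390))
  expect_gt(dr$auc, 0)
  expect_gt(dr$peak_z, 15)   # VS target is ~35 baseline SDs at saturation
})
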