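test_that("rng streams are reproducible and separated by seed and label", {
  d1 <- rng_draw(make_rng(1, "photometry"), stats::runif(10))
  d2 <- rng_draw(make_rng(1, "photometry"), stats::runif(10))
  d3 <- rng_draw(make_rng(1, "fscv"), stats::runif(10))
  d4 <- rng_draw(make_rng(2, "photometry"), stats::runif(10))
  expect_identical(d1, d2)
  expect_false(identical(d1, d3))
  expect_false(identical(d1, d4))
})

test_that("rng streams advance but do not disturb the global RNG", {
  r <- make_rng(7, "x")
  a <- rng_draw(r, stats::rnorm(5))
  b <- rng_draw(r, stats::rnorm(5))
  expect_false(identical(a, b))   # stream advances across calls
  set.seed(99)
  ref <- stats::runif(3)
  set.seed(99)
  rng_draw(make_rng(1, "y"), stats::runif(100))
  expect_identical(stats::runif(3), ref)
})

test_that("time_series enforces its grid invariants", {
  ts <- time_series(1:100, fs = 20)
  expect_equal(length(ts), 100L)
  expect_true(all(abs(diff(ts$t) - 0.05) < 1e-9))
  bad <- ts
  bad$t[50] <- bad$t[50] + 1e-3
  expect_error(validate_time_series(bad), "non-uniform")
  expect_error(time_series(1:5, fs = -1))
})

test_that("unit tags are checked at stage boundaries", {
  ts <- time_series(rnorm(50), fs = 10, unit = "au")
  expect_error(processed_trace(ts), "unit mismatch")
  expect_silent(processed_trace(time_series(rnorm(50), fs = 10, unit = "dff")))
})

test_that("default configuration carries the study parameters and validates", {
  cfg <- load_config(NULL, quiet = TRUE)
  expect_equal(cfg$band_lo_hz, 0.01)
  expect_equal(cfg$band_hi_hz, 10)
  expect_equal(cfg$alpha, 0.05)
  expect_equal(cfg$n_deciles, 10L)
  expect_error(analysis_config(band_lo_hz = 10, band_hi_hz = 0.01),
               "band_lo_hz < band_hi_hz")
})

test_that("partial config files override only their keys", {
  p <- tempfile(fileext = ".yaml")
  writeLines("max_lag_s: 5.5", p)
  cfg <- load_config(p, quiet = TRUE)
  expect_equal(cfg$max_lag_s, 5.5)
  expect_equal(cfg$band_lo_hz, 0.01)
  expect_equal(cfg$alpha, 0.05)
  pj <- tempfile(fileext = ".json")
  writeLines('{"alpha": 0.01}', pj)
  expect_equal(load_config(pj, quiet = TRUE)$alpha, 0.01)
  pb <- tempfile(fileext = ".yaml")
  writeLines("nonsense_key: 1", pb)
  expect_error(load_config(pb, quiet = TRUE), "unknown config key")
})

test_that("photometry CSV demultiplexes alternating channel flags", {
  # 6 rows alternating 415/470 with constant per-channel values
  p <- write_phot_csv(time = seq(0, 0.125, by = 0.025),
                      channel = rep(c(415, 470), 3),
                      value = rep(c(1, 2), 3))
  s <- read_photometry_csv(p)
  expect_equal(s$raw415$x, c(1, 1, 1))
  expect_equal(s$raw470$x, c(2, 2, 2))
})

test_that("interleaved channels are linearly interpolated onto the 415 grid", {
  # 415 frames at 0.00 and 0.05 s; 470 frames at 0.025 and 0.075 s
  p <- write_phot_csv(time = c(0, 0.025, 0.05, 0.075),
                      channel = c(415, 470, 415, 470),
                      value = c(10, 4, 20, 8))
  s <- read_photometry_csv(p)
  expect_equal(s$raw415$fs, 20)
  expect_equal(s$raw415$x, c(10, 20))
  # hand-computed: 470 at t=0 extends the first value (edge rule);
  # at t=0.05, midway between 4 (0.025 s) and 8 (0.075 s) -> 6
  expect_equal(s$raw470$x, c(4, 6))
})

test_that("malformed photometry files raise format errors", {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time = 1:4, value = 1:4), p, row.names = FALSE)
  expect_error(read_photometry_csv(p), "missing column")
  p2 <- write_phot_csv(time = seq(0, 0.9, by = 0.1),
                       channel = c(rep(415, 8), rep(470, 2)),
                       value = 1:10)
  expect_error(read_photometry_csv(p2), "corrupt interleave")
})

test_that("photometry and results tables round-trip through CSV", {
  set.seed(42)
  ses <- gen_photometry_session("WT", duration_s = 60, fs = 20,
                                rng = make_rng(3, "io_roundtrip"))$DS
  p <- tempfile(fileext = ".csv")
  write_photometry_csv(ses, p)
  back <- read_photometry_csv(p)
  expect_equal(back$raw470$x, ses$raw470$x, tolerance = 1e-12)
  expect_equal(back$raw415$x, ses$raw415$x, tolerance = 1e-12)
  expect_equal(back$raw470$fs, ses$raw470$fs, tolerance = 1e-9)
  df <- data.frame(session = c("a", "b"), measure = c("auc", "auc"),
                   value = c(1.25, -3.5e-4))
  p2 <- tempfile(fileext = ".csv")
  write_results_table(df, p2)
  expect_identical(read_results_table(p2), df)
})

test_that("fiber images round-trip through 16-bit TIFF", {
  img <- gen_fiber_image(5, size_px = 64, rng = make_rng(1, "tiffio"))
  p <- tempfile(fileext = ".tif")
  write_fiber_tiff(img, p)
  back <- read_fiber_tiff(p, um_per_px = img$um_per_px)
  # stored at 16-bit resolution of the [0, max] range
  expect_equal(dim(back$pixels), dim(img$pixels))
  expect_gt(stats::cor(as.numeric(back$pixels), as.numeric(img$pixels)),
            0.9999)
})
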