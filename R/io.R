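#' Read a long-format two-channel photometry CSV
#'
#' Acquisition software writes interleaved frames as long-format rows with a
#' timestamp, a channel flag (415 for the isosbestic channel, 470 for the
#' dopamine-sensitive channel) and a fluorescence value. The two channels are
#' demultiplexed and aligned onto a common uniform grid: the 415 timestamps
#' serve as the reference grid and the 470 values are linearly interpolated
#' onto them (constant extension at the record edges, so no polynomial
#' extrapolation ever occurs).
#'
#' @param path CSV file with columns `time` (s), `channel` (415 or 470) and
#'   `value`; extra metadata columns `region`, `genotype` are honoured if
#'   present.
#' @param fs_expected optional expected sampling rate of the aligned grid,
#'   Hz; a mismatch beyond 1% is an error.
#' @param region,genotype metadata overrides when the file carries none.
#' @return A [photometry_session()].
#' @export
read_photometry_csv <- function(path, fs_expected = NULL,
                                region = "DS", genotype = "WT") {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "channel", "value")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("photometry CSV format error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (!all(d$channel %in% c(415, 470)))
    stop("photometry CSV format error: channel flag must be 415 or 470")
  d415 <- d[d$channel == 415, ]
  d470 <- d[d$channel == 470, ]
  if (nrow(d415) < 2 || nrow(d470) < 2)
    stop("photometry CSV format error: need >= 2 rows per channel")
  ratio <- nrow(d470) / nrow(d415)
  if (ratio < 0.9 || ratio > 1.1)
    stop("corrupt interleave: channel length ratio ", round(ratio, 3),
         " outside [0.9, 1.1]")
  tt <- d415$time
  if (any(diff(tt) <= 0)) stop("photometry CSV: timestamps not increasing")
  fs <- 1 / stats::median(diff(tt))
  if (!is.null(fs_expected) && abs(fs - fs_expected) > 0.01 * fs_expected)
    stop(sprintf("sampling rate %.4g Hz differs from expected %.4g Hz",
                 fs, fs_expected))
  # regularize the reference grid (timestamps can carry jitter at print precision)
  tgrid <- tt[1] + (seq_along(tt) - 1L) / fs
  x415 <- stats::approx(tt, d415$value, xout = tgrid, rule = 2)$y
  x470 <- stats::approx(d470$time, d470$value, xout = tgrid, rule = 2)$y
  if ("region" %in% names(d)) region <- as.character(d$region[1])
  if ("genotype" %in% names(d)) genotype <- as.character(d$genotype[1])
  photometry_session(
    region = region, genotype = genotype,
    raw470 = time_series(x470, fs = fs, t0 = tgrid[1], unit = "au"),
    raw415 = time_series(x415, fs = fs, t0 = tgrid[1], unit = "au"))
}

#' Write a photometry session as long-format CSV
#'
#' Inverse of [read_photometry_csv()]: emits one row per (sample, channel).
#' Because both channels already live on the shared grid, reading the file
#' back reproduces the session values exactly (up to float printing, which
#' uses full precision).
#'
#' @param session a [photometry_session()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_photometry_csv <- function(session, path) {
  stopifnot(inherits(session, "photometry_session"))
  n <- length(session$raw470$x)
  d <- data.frame(
    time = rep(session$raw470$t, 2L),
    channel = rep(c(470, 415), each = n),
    value = c(session$raw470$x, session$raw415$x),
    region = session$region, genotype = session$genotype)
  d <- d[order(d$time, d$channel), ]
  utils::write.csv(format(d, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a tidy results table
#'
#' Results tables are long-format CSV with one row per (session, measure).
#' The pair is value-identical under a round trip.
#'
#' @param df data frame of results.
#' @param path CSV path.
#' @return `write_results_table`: `path` invisibly; `read_results_table`: the
#'   data frame.
#' @export
write_results_table <- function(df, path) {
  stopifnot(is.data.frame(df))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read / write a grayscale fiber image as TIFF
#'
#' 8- or 16-bit grayscale TIFF in, numeric intensity matrix out (values on
#' the native integer scale). Calibration (micrometres per pixel) is supplied
#' by the caller; analysis is intensity-scale invariant so the bit depth does
#' not matter downstream.
#'
#' @param path TIFF path.
#' @param um_per_px spatial calibration, micrometres per pixel.
#' @return A [fiber_image()].
#' @export
read_fiber_tiff <- function(path, um_per_px) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  fiber_image(pixels = img, um_per_px = um_per_px)
}

#' @rdname read_fiber_tiff
#' @param img a [fiber_image()]; intensities are rescaled to 16-bit for
#'   storage.
#' @export
write_fiber_tiff <- function(img, path) {
  stopifnot(inherits(img, "fiber_image"))
  px <- img$pixels
  mx <- max(px)
  if (mx <= 0) mx <- 1
  tiff::writeTIFF(px / mx, path, bits.per.sample = 16L)
  invisible(path)
}
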