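#' Uniformly sampled time series
#'
#' Light container used throughout the pipeline: a numeric signal on a uniform
#' time grid with a sampling rate and a unit tag. Units ("au", "dff", "z",
#' "uM") are carried as metadata and checked at stage boundaries; a unit
#' mismatch is an error, never a silent conversion.
#'
#' @param x numeric signal values.
#' @param fs sampling rate, Hz.
#' @param t0 time of first sample, seconds from session start.
#' @param unit unit tag, one of `"au"`, `"dff"`, `"z"`, `"uM"`.
#' @return Object of class `time_series` with fields `t`, `x`, `fs`, `unit`.
#' @export
time_series <- function(x, fs, t0 = 0, unit = "au") {
  stopifnot(is.numeric(x), length(x) >= 1L, is.numeric(fs), fs > 0)
  unit <- match.arg(unit, c("au", "dff", "z", "uM"))
  ts <- structure(
    list(t = t0 + (seq_along(x) - 1L) / fs, x = as.numeric(x),
         fs = fs, unit = unit),
    class = "time_series")
  validate_time_series(ts)
  ts
}

#' Validate time-series invariants
#'
#' Checks equal lengths, strictly increasing time, and grid uniformity
#' (`|dt - 1/fs| < 1e-9` for every consecutive pair).
#'
#' @param ts a `time_series`.
#' @return `ts`, invisibly; errors if an invariant is violated.
#' @export
validate_time_series <- function(ts) {
  stopifnot(inherits(ts, "time_series"))
  if (length(ts$t) != length(ts$x))
    stop("time_series: t and x lengths differ")
  dt <- diff(ts$t)
  if (length(dt) && any(dt <= 0))
    stop("time_series: t must be strictly increasing")
  if (length(dt) && any(abs(dt - 1 / ts$fs) >= 1e-9))
    stop("time_series: non-uniform sampling (|dt - 1/fs| >= 1e-9)")
  invisible(ts)
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series n=%d fs=%g Hz unit=%s span=[%.3f, %.3f] s>\n",
              length(x$x), x$fs, x$unit, x$t[1], x$t[length(x$t)]))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$x)

# Stop unless units match; used at stage boundaries.
check_unit <- function(ts, expected) {
  if (!ts$unit %in% expected)
    stop(sprintf("unit mismatch: got \"%s\", expected %s", ts$unit,
                 paste(sprintf("\"%s\"", expected), collapse = " or ")))
  invisible(ts)
}

# Convert an absolute event time to the index of the nearest sample.
time_to_index <- function(ts, time_s) {
  i <- round((time_s - ts$t[1]) * ts$fs) + 1L
  if (any(i < 1L | i > length(ts$x))) stop("time outside record")
  as.integer(i)
}

#' Photometry session container
#'
#' Pairs the 470 nm (dopamine-sensitive) and 415 nm (isosbestic) channels of a
#' fiber photometry recording with region/genotype metadata, event markers
#' (e.g. drug injections) and, for synthetic sessions, the generator ground
#' truth.
#'
#' @param region `"DS"` (dorsal) or `"VS"` (ventral striatum).
#' @param genotype `"WT"` or `"MUT"`.
#' @param raw470,raw415 `time_series` of equal length and sampling rate.
#' @param events data frame with columns `label`, `time` (s), possibly empty.
#' @param truth optional list of generator ground truth.
#' @return Object of class `photometry_session`.
#' @export
photometry_session <- function(region, genotype, raw470, raw415,
                               events = data.frame(label = character(),
                                                   time = numeric()),
                               truth = NULL) {
  region <- match.arg(region, c("DS", "VS"))
  genotype <- match.arg(genotype, c("WT", "MUT"))
  validate_time_series(raw470)
  validate_time_series(raw415)
  if (length(raw470$x) != length(raw415$x) || raw470$fs != raw415$fs)
    stop("photometry_session: channels must share fs and length")
  stopifnot(is.data.frame(events), all(c("label", "time") %in% names(events)))
  if (nrow(events)) {
    t0 <- raw470$t[1]; tN <- raw470$t[length(raw470$t)]
    if (any(events$time < t0 | events$time > tN))
      stop("photometry_session: event time outside record")
  }
  structure(list(region = region, genotype = genotype, raw470 = raw470,
                 raw415 = raw415, events = events, truth = truth),
            class = "photometry_session")
}

#' @export
print.photometry_session <- function(x, ...) {
  cat(sprintf("<photometry_session %s %s: %d samples @ %g Hz, %d event(s)>\n",
              x$genotype, x$region, length(x$raw470$x), x$raw470$fs,
              nrow(x$events)))
  invisible(x)
}
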