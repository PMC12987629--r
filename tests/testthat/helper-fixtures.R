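# Shared fixtures and small independent oracles used across test files.

# Sinusoid time series.
make_sine <- function(freq_hz, fs, duration_s, amp = 1, unit = "z") {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  time_series(amp * sin(2 * pi * freq_hz * t), fs = fs, unit = unit)
}

# Closed-form Michaelis-Menten rate.
mm_rate <- function(conc, vmax, km) vmax * conc / (km + conc)

# Independent grid-search oracle for the Michaelis-Menten optimum.
mm_grid_oracle <- function(conc, rate, vmax_grid, km_grid) {
  best <- c(vmax = NA, km = NA, rss = Inf)
  for (v in vmax_grid) for (k in km_grid) {
    r <- sum((rate - mm_rate(conc, v, k))^2)
    if (r < best["rss"]) best <- c(vmax = v, km = k, rss = r)
  }
  best
}

# Brute-force peak picker oracle: all local maxima above a threshold, then
# greedy merge by decreasing height.
peaks_oracle <- function(x, thr, min_sep) {
  pk <- integer()
  for (i in 2:(length(x) - 1))
    if (x[i] > x[i - 1] && x[i] >= x[i + 1] && x[i] > thr) pk <- c(pk, i)
  keep <- integer()
  for (i in pk[order(x[pk], decreasing = TRUE)])
    if (!length(keep) || all(abs(i - keep) >= min_sep)) keep <- c(keep, i)
  sort(keep)
}

# Cluster 1-D positions closer than sep (sub-resolution crossings count once).
cluster_1d <- function(v, sep) {
  v <- sort(v)
  if (!length(v)) return(numeric())
  g <- cumsum(c(1, diff(v) > sep))
  as.numeric(tapply(v, g, mean))
}

# Long-format photometry CSV fixture writer.
write_phot_csv <- function(time, channel, value, path = tempfile(fileext = ".csv")) {
  utils::write.csv(data.frame(time = time, channel = channel, value = value),
                   path, row.names = FALSE)
  path
}
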