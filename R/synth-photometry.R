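#' Generate a paired DS/VS synthetic photometry session
#'
#' Emulates dual-site dopamine-sensor fiber photometry in dorsal (DS) and
#' ventral (VS) striatum. The wild-type DS dopamine signal is a shot-noise
#' process: events drawn from a log-Gaussian doubly stochastic rate are
#' convolved with a fixed double-exponential sensor kernel (0.05 s rise,
#' 0.4 s decay). The wild-type VS signal is a damped, smoothed copy of the DS
#' signal delayed by the DS-to-VS coupling lag (0.35 s) plus an independent
#' slower shot-noise component (1 s decay). The mutant genotype scales the
#' event amplitudes down ten-fold and superimposes a dominating
#' Ornstein--Uhlenbeck slow wave (45 s correlation time) in each region,
#' reproducing the long irregular dopamine waves of the mutant.
#'
#' Both recorded channels are synthesized from the latent dopamine signal:
#' the 470 nm channel couples to dopamine and to a shared low-frequency
#' motion/bleaching artifact, the 415 nm isosbestic channel couples only to
#' the artifact, and each channel carries independent white measurement
#' noise — so the isosbestic correction stage is exercised end to end.
#'
#' `mode = "homogeneous"` replaces the doubly stochastic rate with a constant
#' rate and a single-exponential kernel and disables the artifact and slow
#' wave: the homogeneous-Poisson null for calibrating the heterogeneity test.
#' In that mode the effective additive noise on the dopamine scale equals
#' `noise_sd` exactly.
#'
#' An optional amphetamine event at `amph_time_s` adds a slow saturating
#' dopamine response scaled in units of the pre-injection baseline SD, per
#' region (wild type: ~10 SD in DS, ~35 SD in VS).
#'
#' @param genotype `"WT"` or `"MUT"`.
#' @param duration_s record length, s (>= 60).
#' @param fs sampling rate, Hz (>= 20).
#' @param rng an [make_rng()] stream.
#' @param mode `"natural"` or `"homogeneous"`.
#' @param event_rate_hz override of the DS event rate (used by the
#'   homogeneous null).
#' @param kernel_decay_s override of the kernel decay time.
#' @param noise_sd additive noise SD on the dopamine scale.
#' @param amph_time_s optional injection time, s.
#' @param params parameter list from [genotype_params()].
#' @return List with elements `DS` and `VS`, each a [photometry_session()]
#'   whose `truth` holds the latent dopamine signal, event times, rate path
#'   and injected coupling lag.
#' @export
gen_photometry_session <- function(genotype = c("WT", "MUT"),
                                   duration_s = 600, fs = 20,
                                   rng = make_rng(1, "photometry"),
                                   mode = c("natural", "homogeneous"),
                                   event_rate_hz = NULL,
                                   kernel_decay_s = NULL,
                                   noise_sd = 0.05,
                                   amph_time_s = NULL,
                                   params = genotype_params(genotype)) {
  genotype <- match.arg(genotype)
  mode <- match.arg(mode)
  stopifnot(fs >= 20, duration_s >= 60)
  ph <- params$photometry
  if (!is.null(event_rate_hz)) ph$event_rate_hz <- event_rate_hz
  if (!is.null(kernel_decay_s)) ph$kernel_decay_s <- kernel_decay_s
  n <- round(duration_s * fs)
  dt <- 1 / fs

  rng_draw(rng, {
    if (mode == "homogeneous") {
      rate_ds <- rep(ph$event_rate_hz, n)
      ev_ds <- stats::rpois(n, rate_ds * dt)
      da_ds <- ph$event_amp *
        shot_filter(ev_ds, fs, rise_s = 0, decay_s = ph$kernel_decay_s)
      ev_vs <- stats::rpois(n, rate_ds * dt)
      da_vs <- ph$event_amp *
        shot_filter(ev_vs, fs, rise_s = 0, decay_s = ph$kernel_decay_s)
      slow_ds <- slow_vs <- numeric(n)
      art <- numeric(n)
    } else {
      # doubly stochastic log-Gaussian rate (mean-one lognormal modulation)
      lograte <- ou_process(n, dt, tau = 2, sd = 0.7)
      rate_ds <- ph$event_rate_hz * exp(lograte - 0.7^2 / 2)
      ev_ds <- stats::rpois(n, rate_ds * dt)
      da_ds <- ph$event_amp *
        shot_filter(ev_ds, fs, rise_s = ph$kernel_rise_s,
                    decay_s = ph$kernel_decay_s)
      ev_vs <- stats::rpois(n, ph$vs_rate_hz * dt)
      da_vs_own <- ph$vs_event_amp *
        shot_filter(ev_vs, fs, rise_s = ph$kernel_rise_s,
                    decay_s = ph$vs_kernel_decay_s)
      d_smp <- round(ph$ds_vs_delay_s * fs)
      da_vs <- ph$vs_gain *
        delay_samples(gaussian_smooth(da_ds, fs, sigma_s = 0.1), d_smp) +
        da_vs_own
      if (ph$slow_wave_sd > 0) {
        slow_ds <- ou_process(n, dt, tau = ph$slow_wave_tau_s,
                              sd = ph$slow_wave_sd)
        slow_vs <- ou_process(n, dt, tau = ph$slow_wave_tau_s,
                              sd = ph$slow_wave_sd)
      } else slow_ds <- slow_vs <- numeric(n)
      da_ds <- da_ds + slow_ds
      da_vs <- da_vs + slow_vs
      art <- ou_process(n, dt, tau = 20, sd = 1)
    }

    events <- data.frame(label = character(), time = numeric())
    if (!is.null(amph_time_s)) {
      if (amph_time_s <= 0 || amph_time_s >= duration_s)
        stop("amph_time_s outside record")
      t <- (seq_len(n) - 1L) * dt
      pre <- t < amph_time_s
      sat <- ifelse(pre, 0, 1 - exp(-(t - amph_time_s) / 300))
      da_ds <- da_ds + ph$amph_peak_in_baseline_sd[["DS"]] *
        stats::sd(da_ds[pre]) * sat
      da_vs <- da_vs + ph$amph_peak_in_baseline_sd[["VS"]] *
        stats::sd(da_vs[pre]) * sat
      events <- data.frame(label = "AMPH", time = amph_time_s)
    }

    ses <- function(region, da) {
      f0 <- 100; g0 <- 50; alpha <- 0.05
      if (mode == "homogeneous") {
        x470 <- f0 * (1 + alpha * da) +
          stats::rnorm(n, 0, noise_sd * f0 * alpha)
        x415 <- g0 + stats::rnorm(n, 0, 1e-3 * g0)
      } else {
        x470 <- f0 * (1 + alpha * da + 0.01 * art) +
          stats::rnorm(n, 0, noise_sd * f0 * alpha)
        x415 <- g0 * (1 + 0.02 * art) + stats::rnorm(n, 0, 1e-3 * g0)
      }
      photometry_session(
        region = region, genotype = genotype,
        raw470 = time_series(x470, fs = fs, unit = "au"),
        raw415 = time_series(x415, fs = fs, unit = "au"),
        events = events,
        truth = list(da = da, mode = mode, genotype = genotype,
                     rate_hz = if (region == "DS") rate_ds else NULL,
                     n_events = if (region == "DS") sum(ev_ds) else sum(ev_vs),
                     ds_vs_delay_s = ph$ds_vs_delay_s,
                     noise_sd = noise_sd))
    }
    list(DS = ses("DS", da_ds), VS = ses("VS", da_vs))
  })
}

# Convolve a count train with a (double-)exponential kernel, peak-normalized
# to 1, via one-pole recursive filters. rise_s = 0 gives a pure decay kernel
# whose jump amplitude is exactly 1.
shot_filter <- function(counts, fs, rise_s, decay_s) {
  ad <- exp(-1 / (fs * decay_s))
  xd <- stats::filter(counts, ad, method = "recursive")
  if (rise_s <= 0) return(as.numeric(xd))
  ar <- exp(-1 / (fs * rise_s))
  xr <- stats::filter(counts, ar, method = "recursive")
  tpk <- log(decay_s / rise_s) * rise_s * decay_s / (decay_s - rise_s)
  pk <- exp(-tpk / decay_s) - exp(-tpk / rise_s)
  as.numeric(xd - xr) / pk
}

# Stationary Ornstein-Uhlenbeck path: AR(1) with matched correlation time.
ou_process <- function(n, dt, tau, sd) {
  a <- exp(-dt / tau)
  as.numeric(stats::filter(stats::rnorm(n, 0, sd * sqrt(1 - a^2)),
                           a, method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

# Right-shift by d samples with edge replication.
delay_samples <- function(x, d) {
  if (d <= 0) return(x)
  n <- length(x)
  c(rep(x[1], d), x[seq_len(n - d)])
}

# Zero-phase FIR Gaussian smoothing with edge renormalization.
gaussian_smooth <- function(x, fs, sigma_s) {
  s <- sigma_s * fs
  if (s <= 0) return(x)
  half <- max(1L, ceiling(3 * s))
  w <- exp(-0.5 * ((-half:half) / s)^2)
  w <- w / sum(w)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, w, sides = 2))[(half + 1):(half + n)]
}
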