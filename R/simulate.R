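#' Configuration for the two-state LFP / haemodynamics simulator
#'
#' Describes a urethane-style recording in which the cortex alternates
#' between a synchronised state (large-amplitude, delta-dominated LFP) and a
#' desynchronised state (low-amplitude LFP with relatively elevated beta and
#' gamma), with coupled shifts in baseline haemoglobin concentrations and,
#' optionally, stimulus-evoked responses whose amplitude depends on state.
#'
#' @param duration_s Recording length in seconds (> 0).
#' @param sample_rate_lfp LFP sampling rate in Hz. Default 24414.0625/16 =
#'   1525.879 Hz, i.e. a 24.414 kHz acquisition downsampled 16-fold.
#' @param sample_rate_hemo Haemodynamic sampling rate in Hz. Default 8 Hz
#'   (a 32 Hz camera cycling four illumination wavelengths).
#' @param n_channels Number of electrode channels (default 16, a linear
#'   depth array; deeper channels carry more low-frequency power).
#' @param dwell State dwell-time model: a list with \code{mean_s} (mean visit
#'   duration; either a single number or a vector named by state, allowing
#'   uneven state occupancy) and \code{min_s} (hard lower truncation).
#'   Visits are drawn as \code{min_s + Exp(mean_s - min_s)} so the mean is
#'   \code{mean_s} and no visit is shorter than \code{min_s}. Defaults 120 s
#'   and 35 s, the truncation guaranteeing that >30 s stable periods exist.
#' @param sync_params,desync_params Per-state generative parameters: a list
#'   with \code{profile} (named nonnegative relative power in the five EEG
#'   bands, not all zero) and \code{rms_scale} (overall RMS amplitude,
#'   arbitrary voltage units). The synchronised \code{rms_scale} must exceed
#'   the desynchronised one.
#' @param amplitude_drift Standard deviation of a slow multiplicative
#'   log-gain drift (Ornstein--Uhlenbeck, time constant
#'   \code{drift_tau_s}) shared by all channels and bands, emulating slow
#'   changes in anaesthetic depth and electrode coupling. Default 0.2;
#'   set 0 to disable.
#' @param drift_tau_s Time constant of the gain drift in seconds (default 60).
#' @param noise_floor Broadband white measurement noise RMS, as a fraction of
#'   the synchronised \code{rms_scale} (default 0.02), independent per channel.
#' @param hemo_baseline_shift Named numeric: desynchronised-minus-synchronised
#'   baseline offsets in micromolar for \code{hbo}, \code{hbr}, \code{hbt}.
#'   Defaults +8.56, -5.56, +2.00.
#' @param hemo_lag_s First-order lag (seconds) between a state transition and
#'   the haemodynamic baseline plateau (default 5).
#' @param hemo_noise_sd Additive Gaussian noise on each haemoglobin series,
#'   micromolar (default 0.5).
#' @param evoked_params Per-state stimulus-evoked haemodynamic kernel: a list
#'   with elements \code{synchronised} and \code{desynchronised}, each a list
#'   of \code{amplitude} (named micromolar peak amplitudes for hbo/hbr/hbt)
#'   and \code{peak_s} (gamma-variate kernel peak latency). Defaults: robust
#'   synchronised response peaking near 5 s; attenuated desynchronised
#'   response with maximum near 16 s.
#' @param lfp_pulse_amp Amplitude of the evoked LFP deflection per stimulus
#'   pulse, relative to the synchronised RMS scale (default 3).
#' @param stim_schedule Optional list with \code{n_trials}, \code{iti_s},
#'   \code{onset_in_trial_s}, \code{duration_s}, \code{pulse_rate_hz}. Use
#'   \code{default_stim_schedule()} for the 30-trial, 70 s inter-trial,
#'   16 s at 5 Hz protocol.
#' @param start_state State of the first dwell (default "synchronised").
#' @param rng_seed Integer seed; every generator is deterministic given it.
#' @return An object of class \code{sim_config}.
#' @seealso [simulate_lfp()], [simulate_hemodynamics()],
#'   [simulate_stimulus_trials()]
#' @export
sim_config <- function(duration_s,
                       sample_rate_lfp = 24414.0625 / 16,
                       sample_rate_hemo = 8,
                       n_channels = 16,
                       dwell = list(mean_s = 120, min_s = 35),
                       sync_params = list(
                         profile = c(delta = 0.58, theta = 0.19, alpha = 0.09,
                                     beta = 0.10, gamma = 0.04),
                         rms_scale = 1.0),
                       desync_params = list(
                         profile = c(delta = 0.15, theta = 0.10, alpha = 0.10,
                                     beta = 0.25, gamma = 0.40),
                         rms_scale = 0.4),
                       amplitude_drift = 0.2,
                       drift_tau_s = 60,
                       noise_floor = 0.02,
                       hemo_baseline_shift = c(hbo = 8.56, hbr = -5.56,
                                               hbt = 2.00),
                       hemo_lag_s = 5,
                       hemo_noise_sd = 0.5,
                       evoked_params = list(
                         synchronised = list(
                           amplitude = c(hbo = 6, hbr = -2, hbt = 4),
                           peak_s = 5),
                         desynchronised = list(
                           amplitude = c(hbo = 1.8, hbr = -0.6, hbt = 1.2),
                           peak_s = 16)),
                       lfp_pulse_amp = 3,
                       stim_schedule = NULL,
                       start_state = "synchronised",
                       rng_seed = 1L) {
  stopifnot(duration_s > 0, sample_rate_lfp > 0, sample_rate_hemo > 0,
            n_channels >= 1)
  if (!is.list(dwell) || any(dwell$mean_s <= 0) || dwell$min_s < 0 ||
      any(dwell$min_s >= dwell$mean_s))
    stop("dwell must satisfy 0 <= min_s < mean_s")
  if (length(dwell$mean_s) > 1L && !all(cortical_states() %in% names(dwell$mean_s)))
    stop("per-state dwell means must be named by state")
  for (p in list(sync_params, desync_params)) {
    pr <- p$profile
    if (length(pr) != 5L || any(pr < 0) || sum(pr) == 0)
      stop("per-state band profiles must be 5 nonnegative weights, not all zero")
    if (p$rms_scale <= 0) stop("rms_scale must be positive")
  }
  if (sync_params$rms_scale < desync_params$rms_scale)
    stop("synchronised rms_scale must not be below the desynchronised one ",
         "(large-amplitude low-frequency vs low-amplitude high-frequency)")
  if (!start_state %in% cortical_states())
    stop("unknown start_state")
  if (!is.null(stim_schedule)) {
    s <- stim_schedule
    stopifnot(all(c("n_trials", "iti_s", "onset_in_trial_s", "duration_s",
                    "pulse_rate_hz") %in% names(s)))
    if (s$n_trials > 0 && s$n_trials * s$iti_s > duration_s + 1e-9)
      stop("stimulus trials exceed configured duration: need at least ",
           s$n_trials * s$iti_s, " s")
  }
  structure(list(duration_s = duration_s, sample_rate_lfp = sample_rate_lfp,
                 sample_rate_hemo = sample_rate_hemo, n_channels = n_channels,
                 dwell = dwell, sync_params = sync_params,
                 desync_params = desync_params,
                 amplitude_drift = amplitude_drift, drift_tau_s = drift_tau_s,
                 noise_floor = noise_floor,
                 hemo_baseline_shift = hemo_baseline_shift,
                 hemo_lag_s = hemo_lag_s, hemo_noise_sd = hemo_noise_sd,
                 evoked_params = evoked_params, lfp_pulse_amp = lfp_pulse_amp,
                 stim_schedule = stim_schedule, start_state = start_state,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' The default whisker-pad stimulation protocol
#'
#' 30 trials with a 70 s inter-trial interval, stimulus onset 10 s into each
#' trial, 16 s stimulation at 5 Hz (2100 s total).
#' @param n_trials,iti_s,onset_in_trial_s,duration_s,pulse_rate_hz Overrides.
#' @return A stimulus-schedule list for [sim_config()].
#' @export
default_stim_schedule <- function(n_trials = 30, iti_s = 70,
                                  onset_in_trial_s = 10, duration_s = 16,
                                  pulse_rate_hz = 5) {
  list(n_trials = n_trials, iti_s = iti_s, onset_in_trial_s = onset_in_trial_s,
       duration_s = duration_s, pulse_rate_hz = pulse_rate_hz)
}

# Draw alternating state dwell intervals covering [0, duration_s].
draw_state_intervals <- function(config) {
  d <- config$dwell
  starts <- numeric(0); ends <- numeric(0); states <- character(0)
  t <- 0
  state <- config$start_state
  other <- setdiff(cortical_states(), state)
  while (t < config$duration_s) {
    mean_s <- if (length(d$mean_s) > 1L) d$mean_s[[state]] else d$mean_s
    dur <- d$min_s + stats::rexp(1L, rate = 1 / (mean_s - d$min_s))
    e <- min(t + dur, config$duration_s)
    starts <- c(starts, t); ends <- c(ends, e); states <- c(states, state)
    t <- e
    tmp <- state; state <- other; other <- tmp
  }
  data.frame(start_s = starts, end_s = ends, state = states,
             stringsAsFactors = FALSE)
}

# Unit-variance band-limited Gaussian noise, synthesised in the frequency
# domain: independent complex Gaussian coefficients on the bins inside
# [lo, hi] Hz, Hermitian-mirrored, inverse transformed. Flat spectrum inside
# the band, exactly zero outside it.
band_limited_noise <- function(n, rate, lo, hi) {
  nfft <- stats::nextn(n)
  half <- nfft %/% 2L
  k <- 1:half
  f <- k * rate / nfft
  sel <- k[f >= lo & f <= hi]
  if (length(sel) == 0L)
    stop("band [", lo, ", ", hi, "] Hz contains no frequency bins ",
         "at this length/rate")
  z <- complex(real = stats::rnorm(length(sel)),
               imaginary = stats::rnorm(length(sel)))
  W <- complex(length.out = nfft)
  W[sel + 1L] <- z
  W[nfft - sel + 1L] <- Conj(z)  # Hermitian symmetry -> real signal
  x <- Re(stats::fft(W, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}

# Slow multiplicative gain drift: exp of a stationary OU process sampled at
# 1 Hz and linearly interpolated to the LFP rate.
gain_drift <- function(n, rate, sd_log, tau_s) {
  if (sd_log <= 0) return(rep(1, n))
  m <- max(2L, ceiling(n / rate) + 1L)
  rho <- exp(-1 / tau_s)
  eps <- stats::rnorm(m, sd = sd_log * sqrt(1 - rho^2))
  g <- numeric(m)
  g[1] <- stats::rnorm(1L, sd = sd_log)
  for (k in 2:m) g[k] <- rho * g[k - 1L] + eps[k]
  t <- (seq_len(n) - 1L) / rate
  exp(stats::approx(x = 0:(m - 1L), y = g, xout = t, rule = 2)$y)
}

#' Draw the hidden state sequence of a simulated recording
#'
#' Generates the alternating synchronised/desynchronised dwell intervals and
#' the per-sample label track without synthesising the LFP itself. Given the
#' same configuration (and seed), [simulate_lfp()] produces exactly this
#' state sequence; use this directly when only the state timing and the
#' haemodynamics are needed.
#'
#' @param config A [sim_config()].
#' @param label_rate Sampling rate of the per-sample label track; defaults
#'   to the configured LFP rate.
#' @return A [ground_truth()].
#' @export
simulate_state_track <- function(config, label_rate = config$sample_rate_lfp) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  n <- round(config$duration_s * label_rate)
  ground_truth(draw_state_intervals(config), label_rate, n)
}

#' Simulate a two-state multichannel LFP recording
#'
#' Each EEG band contributes band-limited Gaussian noise whose amplitude is
#' switched per sample according to the hidden state: amplitude =
#' \code{rms_scale * sqrt(profile / sum(profile))} for the active state, so
#' realised band powers track the configured relative profile. Channels share
#' the band processes' statistics but have independent noise realisations; a
#' linear depth-gain profile gives the deeper channels the largest
#' low-frequency (delta/theta) amplitude. If a stimulus schedule is present,
#' evoked LFP deflections are added at each stimulation pulse with
#' state-dependent adaptation (synchronised: large first response decaying to
#' a plateau; desynchronised: small first response growing gradually).
#'
#' @param config A [sim_config()].
#' @return A list with elements \code{lfp} (an [lfp_recording()]) and
#'   \code{truth} (a [ground_truth()]); deterministic given
#'   \code{config$rng_seed}.
#' @export
simulate_lfp <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  n <- round(config$duration_s * config$sample_rate_lfp)
  rate <- config$sample_rate_lfp
  intervals <- draw_state_intervals(config)
  truth <- ground_truth(intervals, rate, n)
  desync <- truth$labels == "desynchronised"

  bands <- eeg_bands()
  amp_for <- function(p) p$rms_scale * sqrt(p$profile / sum(p$profile))
  a_sync <- amp_for(config$sync_params)
  a_desync <- amp_for(config$desync_params)

  drift <- gain_drift(n, rate, config$amplitude_drift, config$drift_tau_s)

  nc <- config$n_channels
  # depth gain on the low-frequency bands: shallow channels attenuated
  depth_gain <- matrix(1, nrow = nc, ncol = 5L)
  if (nc > 1L) {
    g <- seq(0.6, 1.0, length.out = nc)
    depth_gain[, 1:2] <- g
  }

  samples <- matrix(0, nrow = nc, ncol = n)
  for (ch in seq_len(nc)) {
    x <- numeric(n)
    for (b in seq_len(5L)) {
      env <- ifelse(desync, a_desync[b], a_sync[b]) * depth_gain[ch, b]
      x <- x + env * band_limited_noise(n, rate, bands$lo_hz[b], bands$hi_hz[b])
    }
    x <- x * drift
    if (config$noise_floor > 0)
      x <- x + stats::rnorm(n, sd = config$noise_floor *
                              config$sync_params$rms_scale)
    samples[ch, ] <- x
  }

  if (!is.null(config$stim_schedule) && config$stim_schedule$n_trials > 0) {
    trials <- simulate_stimulus_trials(config)
    pulse <- evoked_pulse_kernel(rate)
    base_amp <- config$lfp_pulse_amp * config$sync_params$rms_scale
    for (i in seq_len(nrow(trials))) {
      onset <- trials$onset_s[i]
      state <- state_at_time(truth, onset)
      np <- trials$n_pulses[i]
      tp <- onset + (seq_len(np) - 1L) / trials$pulse_rate_hz[i]
      el <- (tp - onset)  # elapsed time of each pulse
      amp <- if (identical(state, "desynchronised")) {
        0.5 * base_amp * (1 - 0.7 * exp(-el / 5))
      } else {
        base_amp * (1 + 2 * exp(-el / 2)) / 3
      }
      idx0 <- round(tp * rate) + 1L
      for (p in seq_along(idx0)) {
        j <- idx0[p]:min(idx0[p] + length(pulse) - 1L, n)
        samples[, j] <- samples[, j] +
          rep(amp[p] * pulse[seq_along(j)], each = nc)
      }
    }
  }

  lfp <- lfp_recording(samples, rate, channel_ids = seq_len(nc))
  list(lfp = lfp, truth = truth)
}

# Brief biphasic evoked deflection (~40 ms damped sine), unit peak.
evoked_pulse_kernel <- function(rate) {
  t <- seq(0, 0.04, by = 1 / rate)
  k <- sin(2 * pi * 25 * t) * exp(-t / 0.015)
  k / max(abs(k))
}

#' Build the stimulus trial set from a configuration
#'
#' Trial onsets are \code{onset_in_trial_s + (0:(n_trials-1)) * iti_s}; each
#' trial delivers \code{round(duration_s * pulse_rate_hz)} pulses.
#'
#' @param config A [sim_config()] with a \code{stim_schedule}.
#' @return A data frame of class \code{trial_set} with columns
#'   \code{trial}, \code{onset_s}, \code{duration_s}, \code{pulse_rate_hz},
#'   \code{n_pulses}.
#' @export
simulate_stimulus_trials <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  s <- config$stim_schedule
  if (is.null(s)) stop("config has no stim_schedule")
  if (s$n_trials == 0) {
    out <- data.frame(trial = integer(0), onset_s = numeric(0),
                      duration_s = numeric(0), pulse_rate_hz = numeric(0),
                      n_pulses = integer(0))
    class(out) <- c("trial_set", "data.frame")
    return(out)
  }
  onset <- s$onset_in_trial_s + (seq_len(s$n_trials) - 1L) * s$iti_s
  if (max(onset) + s$duration_s > config$duration_s + 1e-9)
    stop("stimulation extends beyond the configured duration")
  out <- data.frame(trial = seq_len(s$n_trials), onset_s = onset,
                    duration_s = s$duration_s, pulse_rate_hz = s$pulse_rate_hz,
                    n_pulses = as.integer(round(s$duration_s * s$pulse_rate_hz)))
  class(out) <- c("trial_set", "data.frame")
  out
}

#' Simulate concurrent haemodynamics coupled to the cortical state
#'
#' Baseline Hbo/Hbr/Hbt follow the hidden state with a first-order lag:
#' after each transition the baseline relaxes exponentially (time constant
#' \code{hemo_lag_s}) towards the state's plateau, the desynchronised
#' plateau sitting at \code{hemo_baseline_shift} micromolar relative to the
#' synchronised one. If the configuration carries a stimulus schedule,
#' state-dependent gamma-variate evoked responses are added (synchronised
#' trials larger and earlier-peaking than desynchronised ones). Gaussian
#' measurement noise is controlled by the configuration seed (offset so the
#' haemodynamic noise stream is independent of the LFP stream).
#'
#' @param config A [sim_config()].
#' @param truth The [ground_truth()] returned by [simulate_lfp()]; must cover
#'   the configured duration.
#' @return A \code{hemo_recording}: data frame with columns \code{time},
#'   \code{hbo}, \code{hbr}, \code{hbt} (micromolar) at
#'   \code{sample_rate_hemo}.
#' @export
simulate_hemodynamics <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  if (abs(max(truth$intervals$end_s) - config$duration_s) > 1e-6)
    stop("ground truth does not cover the configured duration")
  set.seed(config$rng_seed + 7901L)
  rate <- config$sample_rate_hemo
  n <- round(config$duration_s * rate)
  t <- (seq_len(n) - 1L) / rate
  s <- as.numeric(state_at_time(truth, t) == "desynchronised")

  # first-order lag towards the state plateau
  alpha <- (1 / rate) / config$hemo_lag_s
  alpha <- min(alpha, 1)
  lagged <- numeric(n)
  lagged[1] <- s[1]
  for (k in 2:n) lagged[k] <- lagged[k - 1L] + alpha * (s[k] - lagged[k - 1L])

  shift <- config$hemo_baseline_shift
  out <- sapply(c("hbo", "hbr", "hbt"), function(sp) shift[[sp]] * lagged)

  if (!is.null(config$stim_schedule) && config$stim_schedule$n_trials > 0) {
    trials <- simulate_stimulus_trials(config)
    for (i in seq_len(nrow(trials))) {
      onset <- trials$onset_s[i]
      state <- state_at_time(truth, onset)
      ev <- config$evoked_params[[state]]
      rel <- t - onset
      k <- gamma_variate_kernel(rel, ev$peak_s)
      for (sp in c("hbo", "hbr", "hbt"))
        out[, sp] <- out[, sp] + ev$amplitude[[sp]] * k
    }
  }
  if (config$hemo_noise_sd > 0)
    out <- out + matrix(stats::rnorm(3L * n, sd = config$hemo_noise_sd),
                        nrow = n)
  hemo_recording(t, out[, "hbo"], out[, "hbr"], out[, "hbt"], rate)
}

# Gamma-variate kernel with unit peak at `peak_s`, zero for t <= 0.
gamma_variate_kernel <- function(t, peak_s, shape = 3) {
  k <- numeric(length(t))
  pos <- t > 0
  u <- t[pos] / peak_s
  k[pos] <- (u * exp(1 - u))^shape
  k
}

#' Haemodynamic recording container
#'
#' @param time Times in seconds.
#' @param hbo,hbr,hbt Oxy-, deoxy- and total haemoglobin concentration
#'   changes in micromolar; equal lengths.
#' @param sample_rate Sampling rate in Hz.
#' @return A data frame of class \code{hemo_recording}.
#' @export
hemo_recording <- function(time, hbo, hbr, hbt, sample_rate) {
  stopifnot(length(time) == length(hbo), length(hbo) == length(hbr),
            length(hbr) == length(hbt), sample_rate > 0)
  out <- data.frame(time = time, hbo = hbo, hbr = hbr, hbt = hbt)
  attr(out, "sample_rate") <- sample_rate
  class(out) <- c("hemo_recording", "data.frame")
  out
}
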