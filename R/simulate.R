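#' Simulate a single-channel EGG recording with ground truth
#'
#' Generates an observed bipolar EGG signal as the exact sum of labelled
#' components, each returned alongside the observation so every downstream
#' stage can be checked against ground truth:
#'
#' * a gastric slow wave: a sinusoid at `slow_wave_freq_cpm` (default 3 cpm
#'   = 0.05 Hz) with amplitude `slow_wave_amp_uv` (default 100 uV, the
#'   middle of the physiological 50-200 uV range), amplitude-modulated by a
#'   smoothed log-normal contraction envelope;
#' * motion-artifact bursts: raised-cosine-edged pulses of random polarity
#'   carrying high broadband power (a DC offset plus wideband noise under
#'   the envelope, mimicking the spectrally flat bursts that mask the slow
#'   wave), Poisson-placed at `artifact_rate_per_hour`, with durations of a
#'   few seconds or less and mV-scale amplitudes;
#' * baseline drift: band-limited noise below `1 / drift_timescale_s` Hz;
#' * measurement noise with the 1/f spectral character of skin-electrode
#'   recordings (RMS `noise_rms_uv`).
#'
#' All randomness is fixed by `seed`.
#'
#' @param duration_s Record length in seconds.
#' @param fs Sampling rate in Hz (default 5, the analysis rate).
#' @param slow_wave_freq_cpm Slow-wave frequency in cycles per minute;
#'   either a scalar or a per-sample vector (for circadian profiles).
#' @param slow_wave_amp_uv Slow-wave amplitude in uV.
#' @param amp_scale Optional per-sample amplitude multiplier (e.g. a meal
#'   gain profile); scalar or vector.
#' @param envelope_sd_log Standard deviation of the log contraction
#'   envelope (0 disables amplitude modulation).
#' @param envelope_timescale_s Smoothing timescale of the envelope in s.
#' @param noise_rms_uv RMS of the measurement noise in uV.
#' @param drift_amp_uv RMS of the baseline drift in uV.
#' @param drift_timescale_s Drift timescale in s (band limit `1/timescale`).
#' @param artifact_rate_per_hour Expected number of artifact bursts per hour.
#' @param artifact_count Exact number of bursts to place; overrides the
#'   Poisson draw implied by `artifact_rate_per_hour`.
#' @param artifact_duration_range_s Burst duration range in s.
#' @param artifact_amp_range_mv Burst amplitude range in mV.
#' @param baseline_shift_frac Size of the post-burst baseline shift as a
#'   fraction of the burst amplitude (electrode motion perturbs the skin
#'   half-cell potential, which then recovers); 0 disables it. The recovery
#'   tail is bookkept in the `drift` component.
#' @param baseline_shift_tau_s Recovery time constant of the post-burst
#'   baseline shift in s.
#' @param noise_color `"pink"` (1/f, the spectral character of
#'   skin-electrode biopotential noise at these frequencies; default) or
#'   `"white"`. RMS is `noise_rms_uv` either way.
#' @param seed Integer seed fixing all randomness; `NULL` leaves the RNG
#'   state alone.
#' @return A tibble with per-sample columns `time`, `observed`,
#'   `clean_egg`, `artifact`, `drift`, `noise`, `envelope`,
#'   `artifact_mask`, with attributes `fs` and `config`. The identity
#'   `observed = clean_egg + artifact + drift + noise` holds exactly.
#' @export
#' @examples
#' sim <- simulate_egg(duration_s = 3600, seed = 42)
#' summary(sim$observed)
simulate_egg <- function(duration_s,
                         fs = 5,
                         slow_wave_freq_cpm = 3,
                         slow_wave_amp_uv = 100,
                         amp_scale = 1,
                         envelope_sd_log = 0.25,
                         envelope_timescale_s = 600,
                         noise_rms_uv = 20,
                         drift_amp_uv = 50,
                         drift_timescale_s = 100,
                         artifact_rate_per_hour = 12,
                         artifact_count = NULL,
                         artifact_duration_range_s = c(0.5, 5),
                         artifact_amp_range_mv = c(1, 5),
                         baseline_shift_frac = 0.3,
                         baseline_shift_tau_s = 120,
                         noise_color = c("pink", "white"),
                         seed = NULL) {
  noise_color <- match.arg(noise_color)
  if (duration_s <= 0 || fs <= 0) stop("invalid duration or fs", call. = FALSE)
  if (any(slow_wave_freq_cpm / 60 >= fs / 2)) {
    stop("slow-wave frequency must be below Nyquist", call. = FALSE)
  }
  if (slow_wave_amp_uv < 0 || noise_rms_uv < 0 || drift_amp_uv < 0 ||
      artifact_rate_per_hour < 0) {
    stop("amplitudes and rates must be non-negative", call. = FALSE)
  }
  if (diff(artifact_duration_range_s) < 0 || diff(artifact_amp_range_mv) < 0) {
    stop("invalid artifact parameter range", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  time <- (seq_len(n) - 1) / fs
  f_hz <- rep_len(slow_wave_freq_cpm / 60, n)
  phase <- 2 * pi * cumsum(f_hz) / fs

  envelope <- if (envelope_sd_log > 0) {
    z <- stats::rnorm(n)
    L <- max(3L, round(envelope_timescale_s * fs))
    if (L %% 2 == 0) L <- L + 1L
    L <- min(L, if (n %% 2 == 0) n - 1L else n)
    zs <- local_moments(z, L)$local_mean
    zs <- if (stats::sd(zs) > 0) (zs - mean(zs)) / stats::sd(zs) else zs * 0
    exp(envelope_sd_log * zs)
  } else rep(1, n)

  clean_egg <- slow_wave_amp_uv * rep_len(amp_scale, n) * envelope * sin(phase)

  drift <- if (drift_amp_uv > 0) {
    cutoff <- min(1 / drift_timescale_s, 0.45 * fs)
    bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
    d <- signal::filtfilt(bf, stats::rnorm(n))
    if (stats::sd(d) > 0) d * drift_amp_uv / stats::sd(d) else d
  } else rep(0, n)

  artifact <- rep(0, n)
  drift_tail <- rep(0, n)
  n_bursts <- if (!is.null(artifact_count)) {
    as.integer(artifact_count)
  } else if (artifact_rate_per_hour > 0) {
    stats::rpois(1, artifact_rate_per_hour * duration_s / 3600)
  } else 0L
  if (n_bursts > 0) {
    onset <- stats::runif(n_bursts, 0, duration_s)
    dur <- stats::runif(n_bursts, artifact_duration_range_s[1],
                        artifact_duration_range_s[2])
    amp <- stats::runif(n_bursts, artifact_amp_range_mv[1],
                        artifact_amp_range_mv[2]) * 1000   # mV -> uV
    pol <- sample(c(-1, 1), n_bursts, replace = TRUE)
    # movement dynamics are slow: the within-burst carrier is noise
    # band-limited below ~0.25 Hz, so burst power lands on top of the
    # 0.02-0.20 Hz analysis band and masks the slow wave, matching the
    # broadband vertical stripes such bursts leave in a spectrogram
    bf_burst <- signal::butter(2, min(0.25, 0.45 * fs) / (fs / 2), "low")
    for (b in seq_len(n_bursts)) {
      i0 <- floor(onset[b] * fs) + 1L
      m <- max(2L, round(dur[b] * fs))
      i1 <- min(i0 + m - 1L, n)
      idx <- i0:i1
      env <- raised_cosine_pulse(length(idx))
      carrier <- stats::rnorm(length(idx))
      if (length(idx) > 12) {   # filtfilt needs a few filter lengths
        carrier <- signal::filtfilt(bf_burst, carrier)
        carrier <- carrier / max(stats::sd(carrier), 1e-12)
      }
      artifact[idx] <- artifact[idx] + pol[b] * amp[b] * env *
        (0.6 + 0.4 * carrier)
      if (baseline_shift_frac > 0) {
        # electrode motion perturbs the skin half-cell potential: the
        # baseline recovers exponentially after the burst; bookkept as
        # drift (a baseline phenomenon), not as the burst itself
        tl <- min(n - i1, round(6 * baseline_shift_tau_s * fs))
        if (tl > 0) {
          j <- i1 + seq_len(tl)
          drift_tail[j] <- drift_tail[j] + pol[b] * baseline_shift_frac *
            amp[b] * exp(-seq_len(tl) / (baseline_shift_tau_s * fs))
        }
      }
    }
  }
  drift <- drift + drift_tail
  noise <- if (noise_rms_uv > 0) {
    if (noise_color == "pink") pink_noise(n, noise_rms_uv)
    else stats::rnorm(n, sd = noise_rms_uv)
  } else rep(0, n)

  cfg <- list(duration_s = duration_s, fs = fs,
              slow_wave_freq_cpm = slow_wave_freq_cpm,
              slow_wave_amp_uv = slow_wave_amp_uv,
              envelope_sd_log = envelope_sd_log,
              envelope_timescale_s = envelope_timescale_s,
              noise_rms_uv = noise_rms_uv, drift_amp_uv = drift_amp_uv,
              drift_timescale_s = drift_timescale_s,
              artifact_rate_per_hour = artifact_rate_per_hour,
              artifact_duration_range_s = artifact_duration_range_s,
              artifact_amp_range_mv = artifact_amp_range_mv,
              baseline_shift_frac = baseline_shift_frac,
              baseline_shift_tau_s = baseline_shift_tau_s,
              noise_color = noise_color,
              seed = seed)
  structure(
    tibble::tibble(
      time = time,
      observed = clean_egg + artifact + drift + noise,
      clean_egg = clean_egg,
      artifact = artifact,
      drift = drift,
      noise = noise,
      envelope = envelope,
      artifact_mask = artifact != 0
    ),
    fs = fs, config = cfg,
    class = class(tibble::tibble())
  )
}

# 1/f-shaped Gaussian noise with the requested RMS, via spectral shaping
pink_noise <- function(n, rms) {
  X <- stats::fft(stats::rnorm(n))
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)          # symmetric frequency index
  shape <- ifelse(f > 0, 1 / sqrt(f), 0)
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

# unit-peak envelope with raised-cosine on/off ramps over a quarter of the
# length on each side
raised_cosine_pulse <- function(m, ramp_frac = 0.25) {
  r <- max(1L, round(ramp_frac * m))
  ramp <- 0.5 * (1 - cos(pi * seq_len(r) / r))
  core <- rep(1, max(0L, m - 2L * r))
  out <- c(ramp, core, rev(ramp))
  out[seq_len(m)]
}

#' Simulate antral manometry coupled to the gastric envelope
#'
#' Generates a pressure trace whose contraction peaks share the simulated
#' gastric contraction envelope: a train of 3 cpm-locked pressure bumps
#' scaled by `coupling_gain_mmHg` times the envelope, on top of a
#' sub-threshold baseline, plus measurement noise. With the defaults the
#' windowed motility index of the output correlates positively with the
#' envelope by construction; with `coupling_gain_mmHg = 0` the pressure
#' never crosses the 9 mmHg threshold and the index sits at its floor.
#'
#' @param gt Ground-truth tibble from [simulate_egg()] (needs `time` and
#'   `envelope`).
#' @param fs_p Pressure sampling rate in Hz.
#' @param baseline_mmHg Baseline pressure in mmHg (below the 9 mmHg
#'   threshold).
#' @param coupling_gain_mmHg Peak contraction pressure per unit envelope.
#' @param pressure_noise_mmHg RMS of added white noise.
#' @param contraction_freq_cpm Contraction frequency in cpm.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return Tibble with columns `time` and `pressure` (mmHg), attribute `fs`.
#' @export
simulate_coupled_manometry <- function(gt, fs_p = 2, baseline_mmHg = 5,
                                       coupling_gain_mmHg = 10,
                                       pressure_noise_mmHg = 0.5,
                                       contraction_freq_cpm = 3,
                                       seed = NULL) {
  stopifnot(all(c("time", "envelope") %in% names(gt)))
  if (!is.null(seed)) set.seed(seed)
  t_p <- seq(0, max(gt$time), by = 1 / fs_p)
  env_p <- stats::approx(gt$time, gt$envelope, xout = t_p, rule = 2)$y
  bumps <- pmax(sin(2 * pi * contraction_freq_cpm / 60 * t_p), 0)^2
  noise <- if (pressure_noise_mmHg > 0) {
    stats::rnorm(length(t_p), sd = pressure_noise_mmHg)
  } else 0
  structure(
    tibble::tibble(time = t_p,
                   pressure = baseline_mmHg +
                     coupling_gain_mmHg * env_p * bumps + noise),
    fs = fs_p,
    class = class(tibble::tibble())
  )
}

#' Simulate a 24-hour ambulatory EGG day with meals and sleep
#'
#' Builds a day-long recording on top of [simulate_egg()] with two
#' superimposed physiological profiles:
#'
#' * a circadian frequency profile: the slow wave runs at
#'   `freq_night_cpm` (default 2.74 cpm) while asleep and `freq_day_cpm`
#'   (default 2.91 cpm) while awake;
#' * a meal response: each meal multiplies the slow-wave amplitude by
#'   `meal_gain_db` (power dB) at meal completion, decaying linearly in dB
#'   back to baseline over `meal_decay_s` (default 3.5 h, so the response
#'   has returned to baseline between 3 and 4 h post-meal). Overlapping
#'   meal responses add in dB, with a warning.
#'
#' The returned event log contains the meal anchors and the sleep/wake
#' transitions, time-synchronized with the recording.
#'
#' @inheritParams simulate_egg
#' @param meal_times_s Meal completion times in seconds from record start.
#' @param meal_gain_db Post-meal power gain in dB.
#' @param meal_decay_s Time for the meal gain to decay back to 0 dB, in s.
#' @param wake_s,sleep_onset_s Wake and sleep-onset times in seconds from
#'   record start (the subject is asleep before `wake_s` and after
#'   `sleep_onset_s`).
#' @param freq_day_cpm,freq_night_cpm Daytime and night-time slow-wave
#'   frequencies in cpm.
#' @param ... Further arguments passed to [simulate_egg()] (noise, drift,
#'   artifact and envelope settings).
#' @return A list with elements `recording` (ground-truth tibble from
#'   [simulate_egg()]), `events` (event tibble) and `config`.
#' @export
simulate_ambulatory_day <- function(duration_s = 24 * 3600, fs = 5,
                                    meal_times_s = c(8, 13.25, 18.5) * 3600,
                                    meal_gain_db = 6,
                                    meal_decay_s = 3.5 * 3600,
                                    wake_s = 7 * 3600,
                                    sleep_onset_s = 23.75 * 3600,
                                    freq_day_cpm = 2.91,
                                    freq_night_cpm = 2.74,
                                    seed = NULL, ...) {
  if (length(meal_times_s) > 0 &&
      (min(meal_times_s) < 0 || max(meal_times_s) > duration_s)) {
    stop("meal times must lie within the record", call. = FALSE)
  }
  n <- round(duration_s * fs)
  time <- (seq_len(n) - 1) / fs
  asleep <- time < wake_s | time >= sleep_onset_s
  freq_profile <- ifelse(asleep, freq_night_cpm, freq_day_cpm)

  gain_db <- rep(0, n)
  active <- rep(0L, n)
  for (tm in meal_times_s) {
    g <- meal_gain_db * pmax(0, 1 - (time - tm) / meal_decay_s)
    g[time < tm] <- 0
    gain_db <- gain_db + g
    active <- active + (g > 0)
  }
  if (any(active > 1L)) {
    warning("overlapping meal responses; gains added in dB", call. = FALSE)
  }
  amp_scale <- 10^(gain_db / 20)    # power dB -> amplitude factor

  recording <- simulate_egg(duration_s = duration_s, fs = fs,
                            slow_wave_freq_cpm = freq_profile,
                            amp_scale = amp_scale, seed = seed, ...)
  events <- dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(time = as.numeric(meal_times_s), tag = "meal",
                   note = "meal completion"),
    tibble::tibble(time = wake_s, tag = "wake_onset", note = ""),
    tibble::tibble(time = sleep_onset_s, tag = "sleep_onset", note = "")
  ), .data$time)
  list(recording = recording, events = events,
       config = c(attr(recording, "config"),
                  list(meal_times_s = meal_times_s,
                       meal_gain_db = meal_gain_db,
                       meal_decay_s = meal_decay_s,
                       wake_s = wake_s, sleep_onset_s = sleep_onset_s,
                       freq_day_cpm = freq_day_cpm,
                       freq_night_cpm = freq_night_cpm)))
}

#' Simulate a multichannel recording around a shared gastric source
#'
#' Wraps [simulate_egg()] to emit an `egg_recording` whose channels share
#' one gastric source with channel-specific attenuation plus independent
#' noise, on a square electrode grid. Useful for exercising
#' re-referencing, layout-based pair selection and [best_pair()].
#'
#' @param duration_s Record length in s.
#' @param fs Sampling rate in Hz.
#' @param n_side Grid side (n_side^2 channels).
#' @param spacing_cm Center-to-center electrode spacing in cm.
#' @param source_channel Label of the channel over the stomach (receives
#'   the gastric source at full amplitude).
#' @param attenuation Amplitude fraction of the source reaching the other
#'   channels.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_egg()].
#' @return A list: `recording` (an `egg_recording` with layout) and
#'   `ground_truth` (the [simulate_egg()] tibble of the source).
#' @export
simulate_array_recording <- function(duration_s = 7200, fs = 5, n_side = 3,
                                     spacing_cm = 2, source_channel = NULL,
                                     attenuation = 0.1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  gt <- simulate_egg(duration_s = duration_s, fs = fs, seed = NULL, ...)
  labs <- paste0("ch", seq_len(n_side^2))
  grid <- expand.grid(col = seq_len(n_side), row = seq_len(n_side))
  mid <- (n_side + 1) / 2
  layout <- tibble::tibble(
    channel = labs,
    x = (grid$col - mid) * spacing_cm,
    y = (mid - grid$row) * spacing_cm
  )
  source_channel <- source_channel %||% labs[[1]]
  n <- nrow(gt)
  data <- tibble::tibble(time = gt$time)
  for (ch in labs) {
    a <- if (ch == source_channel) 1 else attenuation
    data[[ch]] <- a * (gt$clean_egg + gt$artifact + gt$drift) +
      stats::rnorm(n, sd = attr(gt, "config")$noise_rms_uv)
  }
  list(recording = new_recording(data, fs = fs, layout = layout,
                                 reference = labs[[length(labs)]]),
       ground_truth = gt)
}
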