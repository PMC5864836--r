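make_sine <- function(freq_hz, duration_s, fs = 5, amp = 100, phase = 0) {
  t <- (0:(duration_s * fs - 1)) / fs
  amp * sin(2 * pi * freq_hz * t + phase)
}

test_that("spectrogram framing follows the window/hop arithmetic", {
  x <- make_sine(0.05, 7200)           # 2 h at 5 Hz = 36000 samples
  spec <- compute_spectrogram(x, fs = 5)
  expect_equal(length(spec$times), floor((36000 - 1200) / 300) + 1)  # 117
  expect_equal(diff(spec$times), rep(60, 116))   # hop = 240 * 0.25 s
  # frequency-resolution law: adjacent bins differ by exactly 1/window_s
  expect_equal(diff(spec$freqs), rep(1 / 240, length(spec$freqs) - 1))
  expect_error(compute_spectrogram(make_sine(0.05, 100), fs = 5), "shorter")
  expect_error(compute_spectrogram(x, fs = 5, overlap_frac = 1), "overlap")
})

test_that("each window's periodogram matches an independent single-window oracle", {
  set.seed(41)
  x <- rnorm(3000, sd = 40)
  spec <- compute_spectrogram(x, fs = 5, window_s = 120, overlap_frac = 0.5)
  w <- as.numeric(signal::hamming(600))
  for (k in c(1, 5, 9)) {
    start <- 1 + (k - 1) * 300
    expect_equal(spec$power[k, ],
                 oracle_window_power(x[start:(start + 599)], w),
                 tolerance = 1e-12)
  }
})

test_that("per-window linear power satisfies Parseval against the tapered segment", {
  set.seed(42)
  x <- rnorm(2400)
  spec <- compute_spectrogram(x, fs = 5, window_s = 240, overlap_frac = 0)
  w <- as.numeric(signal::hamming(1200))
  for (k in seq_along(spec$times)) {
    seg <- x[(1 + (k - 1) * 1200):(k * 1200)]
    xw <- (seg - mean(seg)) * w
    expect_equal(sum(spec$power[k, ]), mean(xw^2) / mean(w^2),
                 tolerance = 1e-10)
  }
})

test_that("sinusoid dominant frequency is recovered within one bin", {
  for (f in c(0.025, 0.05, 0.0833, 0.13, 0.19)) {
    spec <- compute_spectrogram(make_sine(f, 3600), fs = 5)
    dom <- eggwave:::dominant_freqs(spec)
    expect_true(all(abs(dom - f) <= 1 / 240 + 1e-12))
  }
})

test_that("white-noise spectrum is flat within 3 dB when averaged over windows", {
  set.seed(43)
  x <- rnorm(5 * 3600 * 4)             # 4 h at 5 Hz: 59 windows
  spec <- compute_spectrogram(x, fs = 5)
  avg_db <- 10 * log10(colMeans(spec$power))
  band <- spec$freqs > 0.02 & spec$freqs < 2.4
  expect_lt(diff(range(avg_db[band])), 3)
})

test_that("SNR separates in-band signal from out-of-band signal", {
  dur <- 7200
  strong <- make_sine(0.05, dur, amp = 100)
  set.seed(44)
  noise <- rnorm(dur * 5, sd = 5)      # 20:1 amplitude ratio
  expect_gt(egg_snr(compute_spectrogram(strong + noise, fs = 5)), 10)
  # a 0.10 Hz sinusoid lands its power in the "noise" band
  off <- make_sine(0.10, dur, amp = 100)
  expect_lt(egg_snr(compute_spectrogram(off + noise, fs = 5)), 0)
})

test_that("white-noise SNR is near zero and SNR is scale invariant", {
  set.seed(45)
  x <- rnorm(5 * 3600 * 7)             # 105 windows
  spec <- compute_spectrogram(x, fs = 5)
  expect_lt(abs(egg_snr(spec)), 1)
  y <- make_sine(0.05, 7200, amp = 80) + rnorm(36000, sd = 30)
  s1 <- egg_snr(compute_spectrogram(y, fs = 5))
  s2 <- egg_snr(compute_spectrogram(13 * y, fs = 5))
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("percent normal scores sinusoids by their dominant rhythm", {
  expect_equal(percent_normal(compute_spectrogram(make_sine(3 / 60, 3600),
                                                  fs = 5)), 100)
  expect_equal(percent_normal(compute_spectrogram(make_sine(5 / 60, 3600),
                                                  fs = 5)), 0)
  # amplitude scaling cannot change an argmax-based metric
  mix <- make_sine(3 / 60, 3600) + 0.5 * make_sine(5.5 / 60, 3600)
  p1 <- percent_normal(compute_spectrogram(mix, fs = 5))
  expect_equal(percent_normal(compute_spectrogram(20 * mix, fs = 5)), p1)
})

test_that("percent normal of a 3:1 mixture of rhythms counts windows by construction", {
  x <- c(make_sine(3 / 60, 3 * 3600), make_sine(6 / 60, 3600))
  pn <- percent_normal(compute_spectrogram(x, fs = 5))
  # 3 h normal + 1 h tachygastric; windows straddling the boundary may fall
  # either way, so allow one window's worth (100/237) of slack around 75%
  n_win <- floor((length(x) - 1200) / 300) + 1
  expect_lt(abs(pn - 75), 2 * 100 / n_win)
})

test_that("doubling the amplitude raises band power by 20 log10(2) dB", {
  base <- make_sine(0.05, 7200, amp = 90)
  f1 <- egg_features(compute_spectrogram(base, fs = 5))
  f2 <- egg_features(compute_spectrogram(2 * base, fs = 5))
  expect_equal(mean(f2$band_power_db - f1$band_power_db), 20 * log10(2),
               tolerance = 0.1)
})

test_that("normalized white-noise power is near zero and features are consistent", {
  set.seed(46)
  spec <- compute_spectrogram(rnorm(5 * 3600 * 7), fs = 5)
  f <- egg_features(spec)
  expect_lt(abs(mean(f$normalized_power_db)), 1)
  expect_equal(100 * mean(f$is_normal), percent_normal(spec))
  expect_true(all(f$dominant_freq_hz >= 0.02 & f$dominant_freq_hz <= 0.20))
})

test_that("dominant frequency tracks a circadian-style frequency step", {
  half <- 4 * 3600 * 5
  freq_profile <- rep(c(2.74, 2.91) / 60, each = half)
  sim <- simulate_egg(duration_s = 8 * 3600, slow_wave_freq_cpm = 60 * freq_profile,
                      envelope_sd_log = 0, noise_rms_uv = 5, drift_amp_uv = 0,
                      artifact_rate_per_hour = 0, seed = 47)
  f <- egg_features(compute_spectrogram(sim, value = observed))
  early <- f$dominant_freq_hz[f$time < 3.5 * 3600]
  late <- f$dominant_freq_hz[f$time > 4.5 * 3600]
  expect_true(all(abs(early - 2.74 / 60) <= 1 / 240 + 1e-12))
  expect_true(all(abs(late - 2.91 / 60) <= 1 / 240 + 1e-12))
})

test_that("best pair finds the channel pair containing the source", {
  set.seed(48)
  n <- 7200 * 5
  t <- (0:(n - 1)) / 5
  s <- 100 * sin(2 * pi * 0.05 * t)
  rec <- new_recording(
    tibble::tibble(time = t,
                   A = s + rnorm(n, sd = 20),
                   B = rnorm(n, sd = 20),
                   C = rnorm(n, sd = 20)),
    fs = 5
  )
  bp <- best_pair(rec)
  expect_true(setequal(c(bp$measurement, bp$reference), c("A", "B")) ||
                setequal(c(bp$measurement, bp$reference), c("A", "C")))
  expect_gt(bp$snr_db, 5)
})

test_that("best pair handles two channels and identical channels", {
  t <- (0:(1500 * 5 - 1)) / 5
  x <- 100 * sin(2 * pi * 0.05 * t)
  rec2 <- new_recording(tibble::tibble(time = t, A = x, B = 0 * x), fs = 5)
  bp <- best_pair(rec2)
  expect_equal(sort(c(bp$measurement, bp$reference)), c("A", "B"))
  rec_same <- new_recording(tibble::tibble(time = t, A = x, B = x, C = x),
                            fs = 5)
  expect_warning(bp2 <- best_pair(rec_same), "identical")
  expect_equal(c(bp2$measurement, bp2$reference), c("A", "B"))
})

test_that("event alignment reduces to identity and zero spread in degenerate cases", {
  feats <- tibble::tibble(time = seq(0, 7200, by = 60),
                          normalized_power_db = sin(seq(0, 7200, by = 60) / 800))
  al <- align_by_event(feats, 3600, pre_s = 0, post_s = 0, grid_dt_s = 60)
  expect_equal(nrow(al$aligned), 1)
  expect_equal(al$aligned$value,
               feats$normalized_power_db[feats$time == 3600])
  # two identical anchors: zero across-event standard deviation
  al2 <- align_by_event(feats, c(3000, 3000), pre_s = 600, post_s = 600)
  expect_true(all(al2$summary$sd == 0))
  expect_warning(
    align_by_event(feats, c(3600, 7100), pre_s = 600, post_s = 600),
    "dropped"
  )
})

test_that("a synthetic post-meal power step appears at aligned time zero", {
  hop <- 60
  times <- seq(0, 10 * 3600, by = hop)
  power <- ifelse(times >= 4 * 3600 & times < 7 * 3600, 16, 10)
  feats <- tibble::tibble(time = times, normalized_power_db = power)
  al <- align_by_event(feats, 4 * 3600, pre_s = 3600, post_s = 4 * 3600)
  s <- al$summary
  expect_lt(max(abs(s$mean[s$rel_time < 0] - 10)), 1e-9)
  expect_lt(max(abs(s$mean[s$rel_time > hop & s$rel_time < 3 * 3600] - 16)),
            1e-9)
})

test_that("isolated meals require five quiet hours on both sides", {
  lone <- tibble::tibble(time = 6 * 3600, tag = "meal", note = "")
  expect_equal(nrow(find_isolated_meals(lone)), 1)
  snack <- dplyr::bind_rows(lone,
                            tibble::tibble(time = 7 * 3600, tag = "snack",
                                           note = ""))
  expect_equal(nrow(find_isolated_meals(snack)), 0)
  close_meals <- tibble::tibble(time = c(6, 10) * 3600,
                                tag = "meal", note = c("", ""))
  expect_equal(nrow(find_isolated_meals(close_meals)), 0)
  far_meals <- tibble::tibble(time = c(6, 12.5) * 3600,
                              tag = "meal", note = c("", ""))
  expect_equal(nrow(find_isolated_meals(far_meals)), 2)
})
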