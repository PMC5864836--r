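#' Short-time Fourier spectrogram of an EGG signal
#'
#' Splits the record into consecutive windows (default four minutes with 75%
#' overlap), removes each segment's mean, applies a Hamming taper, and
#' computes the one-sided periodogram of every segment. Power is reported in
#' dB (10 log10 of linear power, floored at -120 dB); all downstream features
#' are dB differences, so no absolute reference is needed. Frequency
#' resolution is `1 / window_s` (1/240 Hz at the defaults).
#'
#' Linear bin powers are scaled so their sum equals the variance of the
#' taper-corrected, mean-removed segment (Parseval), which makes band powers
#' comparable across taper choices.
#'
#' @param data Data frame with `time` and a signal column, or a bare numeric
#'   vector.
#' @param value Signal column (tidyselect); defaults to `value`, falling
#'   back to `egg` then `observed`.
#' @param fs Sampling rate in Hz; taken from the `fs` attribute when present.
#' @param window_s Window length in seconds.
#' @param overlap_frac Fractional overlap between consecutive windows, in
#'   `[0, 1)`.
#' @param taper `"hamming"`, `"hann"` or `"rectangular"`.
#' @return An object of class `egg_spectrogram`: window-center `times` (s),
#'   `freqs` (Hz), a windows-by-frequencies `power_db` matrix (and `power`,
#'   linear), plus the framing metadata. `tidy()` gives the long
#'   time/frequency/power tibble.
#' @export
#' @examples
#' sim <- simulate_egg(duration_s = 1800, artifact_rate_per_hour = 0, seed = 1)
#' spec <- compute_spectrogram(sim, value = observed)
#' percent_normal(spec)
compute_spectrogram <- function(data, value = NULL, fs = NULL,
                                window_s = 240, overlap_frac = 0.75,
                                taper = c("hamming", "hann", "rectangular")) {
  taper <- match.arg(taper)
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stop("overlap_frac must be in [0, 1)", call. = FALSE)
  }
  if (is.numeric(data) && is.null(dim(data))) {
    y <- data
    if (is.null(fs)) stop("fs required for a bare vector", call. = FALSE)
    time <- (seq_along(y) - 1) / fs
  } else {
    data_tb <- tibble::as_tibble(data)
    fs <- fs %||% attr(data, "fs")
    if (is.null(fs)) stop("sampling rate `fs` is required", call. = FALSE)
    quo <- rlang::enquo(value)
    col <- if (rlang::quo_is_null(quo)) {
      cand <- intersect(c("value", "egg", "observed"), names(data_tb))
      if (length(cand) == 0) stop("no signal column found; use `value =`",
                                  call. = FALSE)
      cand[[1]]
    } else rlang::as_name(quo)
    y <- data_tb[[col]]
    time <- data_tb[["time"]] %||% ((seq_along(y) - 1) / fs)
  }
  W <- round(window_s * fs)
  if (length(y) < W) {
    stop("record shorter than one spectral window (", window_s, " s)",
         call. = FALSE)
  }
  hop <- max(1L, round(W * (1 - overlap_frac)))
  starts <- seq(1L, length(y) - W + 1L, by = hop)
  w <- switch(taper,
              hamming = as.numeric(signal::hamming(W)),
              hann = as.numeric(signal::hanning(W)),
              rectangular = rep(1, W))
  seg <- vapply(starts, function(s) y[s:(s + W - 1L)], numeric(W))
  seg <- sweep(seg, 2, colMeans(seg))        # per-segment mean removal
  seg <- seg * w
  X <- stats::mvfft(seg)
  nk <- floor(W / 2) + 1L
  scale <- rep(2, nk)
  scale[1] <- 1
  if (W %% 2 == 0) scale[nk] <- 1
  # linear power per one-sided bin; sums to taper-corrected segment variance
  p <- t(abs(X[seq_len(nk), , drop = FALSE])^2) *
    rep(scale / (W^2 * mean(w^2)), each = length(starts))
  freqs <- (seq_len(nk) - 1L) * fs / W
  times <- time[starts] + (W - 1) / (2 * fs)
  structure(
    list(times = times, freqs = freqs,
         power = p, power_db = 10 * log10(pmax(p, 1e-12)),
         window_s = window_s, overlap_frac = overlap_frac,
         taper = taper, fs = fs),
    class = "egg_spectrogram"
  )
}

#' @export
print.egg_spectrogram <- function(x, ...) {
  cat("<egg_spectrogram>\n")
  cat(sprintf("  %d windows of %g s (%.0f%% overlap, %s taper), %d bins to %g Hz\n",
              length(x$times), x$window_s, 100 * x$overlap_frac, x$taper,
              length(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Tidy a spectrogram into a long tibble
#'
#' @param x An `egg_spectrogram`.
#' @param ... Unused.
#' @return Tibble with columns `time`, `freq`, `power_db`.
#' @export
tidy.egg_spectrogram <- function(x, ...) {
  tibble::tibble(
    time = rep(x$times, times = length(x$freqs)),
    freq = rep(x$freqs, each = length(x$times)),
    power_db = as.vector(x$power_db)
  )
}

band_cols <- function(spec, band) {
  which(spec$freqs >= band[1] & spec$freqs <= band[2])
}

#' Slow-wave signal-to-noise ratio of a spectrogram
#'
#' The mean power (dB) in the gastric signal band (0.04-0.06 Hz) minus the
#' mean power at all other frequencies of the 0.02-0.20 Hz analysis band,
#' averaged over all windows. With `average = "linear"` the powers are
#' averaged on the linear scale before conversion to dB.
#'
#' @param spec An `egg_spectrogram` covering the analysis band.
#' @param signal_band,analysis_band Frequency bands in Hz (closed intervals
#'   on bin centers).
#' @param average `"db"` (average the dB values) or `"linear"`.
#' @return SNR in dB.
#' @export
egg_snr <- function(spec, signal_band = c(0.04, 0.06),
                    analysis_band = c(0.02, 0.20),
                    average = c("db", "linear")) {
  average <- match.arg(average)
  sig <- band_cols(spec, signal_band)
  ana <- band_cols(spec, analysis_band)
  noise <- setdiff(ana, sig)
  if (length(sig) == 0 || length(noise) == 0) {
    stop("frequency resolution too coarse for the requested bands",
         call. = FALSE)
  }
  if (average == "db") {
    mean(spec$power_db[, sig]) - mean(spec$power_db[, noise])
  } else {
    10 * log10(mean(spec$power[, sig]) / mean(spec$power[, noise]))
  }
}

dominant_freqs <- function(spec, analysis_band = c(0.02, 0.20)) {
  ana <- band_cols(spec, analysis_band)
  if (length(ana) == 0) stop("analysis band empty at this resolution",
                             call. = FALSE)
  spec$freqs[ana[max.col(spec$power_db[, ana, drop = FALSE],
                         ties.method = "first")]]
}

#' Percent normal gastric slow-wave activity
#'
#' The percentage of analysis windows whose dominant frequency (the argmax
#' of spectral power over the 0.02-0.20 Hz analysis band) falls in the
#' normal gastric range of 2-4 cpm. In humans, values below 70% are
#' conventionally considered abnormal.
#'
#' @param spec An `egg_spectrogram`.
#' @param normal_band Normal range in Hz (default 2-4 cpm).
#' @param analysis_band Analysis band in Hz.
#' @return Percentage in `[0, 100]`.
#' @export
percent_normal <- function(spec, normal_band = c(2, 4) / 60,
                           analysis_band = c(0.02, 0.20)) {
  dom <- dominant_freqs(spec, analysis_band)
  100 * mean(dom >= normal_band[1] & dom <= normal_band[2])
}

#' Per-window EGG spectral features
#'
#' Computes, for every spectrogram window: the mean dB power in the gastric
#' signal band (0.04-0.06 Hz); the normalized power (signal band minus the
#' 0.06-0.10 Hz background band, controlling for noise-floor differences
#' between recordings and channels); the dominant frequency over the
#' 0.02-0.20 Hz analysis band; and whether that dominant frequency is in the
#' normal 2-4 cpm range.
#'
#' @inheritParams egg_snr
#' @param background_band Background band in Hz for power normalization.
#' @param normal_band Normal gastric range in Hz.
#' @return Tibble with columns `time`, `band_power_db`,
#'   `normalized_power_db`, `dominant_freq_hz`, `is_normal`, carrying the
#'   window hop (s) as attribute `hop_s`.
#' @export
egg_features <- function(spec, signal_band = c(0.04, 0.06),
                         background_band = c(0.06, 0.10),
                         analysis_band = c(0.02, 0.20),
                         normal_band = c(2, 4) / 60,
                         average = c("db", "linear")) {
  average <- match.arg(average)
  sig <- band_cols(spec, signal_band)
  bg <- band_cols(spec, background_band)
  if (length(sig) == 0 || length(bg) == 0) {
    stop("frequency resolution too coarse for the requested bands",
         call. = FALSE)
  }
  if (average == "db") {
    bp <- rowMeans(spec$power_db[, sig, drop = FALSE])
    bgp <- rowMeans(spec$power_db[, bg, drop = FALSE])
  } else {
    bp <- 10 * log10(rowMeans(spec$power[, sig, drop = FALSE]))
    bgp <- 10 * log10(rowMeans(spec$power[, bg, drop = FALSE]))
  }
  dom <- dominant_freqs(spec, analysis_band)
  structure(
    tibble::tibble(
      time = spec$times,
      band_power_db = bp,
      normalized_power_db = bp - bgp,
      dominant_freq_hz = dom,
      is_normal = dom >= normal_band[1] & dom <= normal_band[2]
    ),
    hop_s = spec$window_s * (1 - spec$overlap_frac),
    class = class(tibble::tibble())
  )
}

#' Select the electrode pair with the highest slow-wave SNR
#'
#' Evaluates every unordered pair of channels: forms the bipolar difference,
#' computes its spectrogram, and scores it with [egg_snr()]. Returns the
#' best-scoring pair; ties break deterministically toward the earlier pair
#' in channel order.
#'
#' @param rec An `egg_recording` with at least two channels.
#' @param ... Passed to [compute_spectrogram()] and [egg_snr()] (e.g.
#'   `window_s`, `signal_band`).
#' @return One-row tibble with `measurement`, `reference`, `snr_db`.
#' @export
best_pair <- function(rec, ...) {
  chans <- recording_channels(rec)
  if (length(chans) < 2L) stop("need at least two channels", call. = FALSE)
  dots <- list(...)
  spec_args <- dots[names(dots) %in% names(formals(compute_spectrogram))]
  snr_args <- dots[names(dots) %in% names(formals(egg_snr))]
  pairs <- utils::combn(chans, 2, simplify = FALSE)
  scores <- purrr::map_dbl(pairs, function(p) {
    sig <- rereference(rec, p[1], p[2])
    spec <- do.call(compute_spectrogram,
                    c(list(data = sig), spec_args))
    do.call(egg_snr, c(list(spec = spec), snr_args))
  })
  zero_var <- purrr::map_lgl(pairs, function(p) {
    stats::sd(rec[[p[1]]] - rec[[p[2]]]) == 0
  })
  if (all(zero_var)) {
    warning("all channel pairs are identical; returning the first pair",
            call. = FALSE)
  }
  best <- which.max(scores)   # first max in pair order
  tibble::tibble(measurement = pairs[[best]][1],
                 reference = pairs[[best]][2],
                 snr_db = scores[best])
}

#' Align a feature series on logged events
#'
#' Resamples a per-window feature series onto a common relative-time grid
#' around each anchor event (e.g. meal completion), by linear interpolation,
#' and averages across events. Events whose window extends beyond the
#' recorded feature series are dropped with a warning.
#'
#' @param features Feature tibble from [egg_features()] (any tibble with a
#'   `time` column works).
#' @param events Event tibble with `time` and `tag` columns, or a numeric
#'   vector of anchor times (s).
#' @param anchor_tag Tag selecting the anchor events (ignored for a numeric
#'   `events`).
#' @param pre_s,post_s Seconds before/after each anchor to include.
#' @param value Feature column to align (tidyselect; default
#'   `normalized_power_db`).
#' @param grid_dt_s Spacing of the relative-time grid in seconds; defaults
#'   to the feature hop.
#' @return An object of class `egg_alignment`: `aligned` (tibble `event`,
#'   `rel_time`, `value`) and `summary` (tibble `rel_time`, `mean`, `sd`,
#'   `n`). `tidy()` returns the per-event rows.
#' @export
align_by_event <- function(features, events, anchor_tag = "meal",
                           pre_s = 3600, post_s = 5 * 3600,
                           value = NULL, grid_dt_s = NULL) {
  quo <- rlang::enquo(value)
  col <- if (rlang::quo_is_null(quo)) "normalized_power_db"
         else rlang::as_name(quo)
  if (!col %in% names(features)) {
    stop("feature column not found: ", col, call. = FALSE)
  }
  anchors <- if (is.numeric(events)) events
             else events$time[events$tag == anchor_tag]
  if (length(anchors) == 0) stop("no anchor events found", call. = FALSE)
  grid_dt_s <- grid_dt_s %||% attr(features, "hop_s") %||%
    stats::median(diff(features$time))
  rel <- seq(-pre_s, post_s, by = grid_dt_s)
  tmin <- min(features$time); tmax <- max(features$time)
  keep <- anchors - pre_s >= tmin & anchors + post_s <= tmax
  if (any(!keep)) {
    warning(sum(!keep), " event(s) dropped: window extends beyond the record",
            call. = FALSE)
  }
  anchors <- anchors[keep]
  if (length(anchors) == 0) stop("no event fully covered by the record",
                                 call. = FALSE)
  aligned <- purrr::map_dfr(seq_along(anchors), function(i) {
    v <- stats::approx(features$time, features[[col]],
                       xout = anchors[i] + rel, rule = 1)$y
    tibble::tibble(event = i, rel_time = rel, value = v)
  })
  summary <- aligned |>
    dplyr::group_by(.data$rel_time) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  structure(list(aligned = aligned, summary = summary,
                 anchors = anchors, feature = col),
            class = "egg_alignment")
}

#' @export
print.egg_alignment <- function(x, ...) {
  cat(sprintf("<egg_alignment> %d event(s), feature `%s`, %d grid points\n",
              length(x$anchors), x$feature, nrow(x$summary)))
  invisible(x)
}

#' @rdname align_by_event
#' @param x An `egg_alignment`.
#' @param ... Unused.
#' @export
tidy.egg_alignment <- function(x, ...) x$aligned

#' Pool event alignments across recordings
#'
#' Combines the per-event rows of several [align_by_event()] results (e.g.
#' one per recording day) onto their common relative-time grid and
#' recomputes the across-event mean and standard deviation, the way a
#' multi-day meal-response or sleep-aligned average is built.
#'
#' @param alignments List of `egg_alignment` objects sharing a grid.
#' @return An `egg_alignment` over the pooled events.
#' @export
combine_alignments <- function(alignments) {
  stopifnot(length(alignments) > 0)
  grid <- alignments[[1]]$aligned$rel_time
  offset <- 0
  aligned <- purrr::map_dfr(alignments, function(a) {
    if (!isTRUE(all.equal(sort(unique(a$aligned$rel_time)),
                          sort(unique(grid))))) {
      stop("alignments do not share a relative-time grid", call. = FALSE)
    }
    out <- dplyr::mutate(a$aligned, event = .data$event + offset)
    offset <<- offset + length(a$anchors)
    out
  })
  summary <- aligned |>
    dplyr::group_by(.data$rel_time) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  structure(list(aligned = aligned, summary = summary,
                 anchors = seq_len(offset),
                 feature = alignments[[1]]$feature),
            class = "egg_alignment")
}

#' Find isolated meals in an event log
#'
#' An isolated meal is a logged meal preceded by at least `fast_before_s`
#' seconds with no other logged event and followed by `quiet_after_s`
#' seconds with no other logged event (default five hours on each side).
#' These are the meals clean enough to average into a gastric meal-response
#' curve.
#'
#' @param events Event tibble with `time` and `tag` columns.
#' @param fast_before_s,quiet_after_s Exclusion windows in seconds.
#' @return Tibble of the isolated meal events (possibly empty).
#' @export
find_isolated_meals <- function(events, fast_before_s = 5 * 3600,
                                quiet_after_s = 5 * 3600) {
  events <- dplyr::arrange(tibble::as_tibble(events), .data$time)
  meals <- which(events$tag == "meal")
  iso <- purrr::map_lgl(meals, function(i) {
    t0 <- events$time[i]
    others <- events$time[-i]
    !any(others > t0 - fast_before_s & others < t0 + quiet_after_s)
  })
  events[meals[iso], ]
}
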