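#' Default analysis configuration
#'
#' All tunable thresholds of the pipeline in one list: the 0.02-0.20 Hz
#' analysis band, the 0.04-0.06 Hz gastric signal band, the 0.06-0.10 Hz
#' background band, the 2-4 cpm normal range, four-minute windows with 75%
#' overlap, a 0.05 Hz nominal peak frequency for the LMMSE window, the
#' 9 mmHg manometry threshold and the 0.01 significance level.
#'
#' @param ... Named overrides of any default.
#' @return A named list of parameters.
#' @export
egg_config <- function(...) {
  cfg <- list(
    analysis_band = c(0.02, 0.20),
    signal_band = c(0.04, 0.06),
    background_band = c(0.06, 0.10),
    normal_band = c(2, 4) / 60,
    window_s = 240,
    overlap_frac = 0.75,
    peak_freq = 0.05,
    motility_threshold = 9,
    alpha = 0.01
  )
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(cfg)))
  cfg[names(dots)] <- dots
  stopifnot(cfg$overlap_frac > 0, cfg$overlap_frac < 1)
  for (b in c("signal_band", "background_band", "normal_band")) {
    if (cfg[[b]][1] < cfg$analysis_band[1] || cfg[[b]][2] > cfg$analysis_band[2]) {
      stop(b, " must be nested within the analysis band", call. = FALSE)
    }
  }
  cfg
}

#' Run the validation pipeline on one subject
#'
#' Reproduces the three-condition comparison used to validate the EGG
#' against simultaneous antral manometry: (1) the traditional electrode
#' pair (midline reference, measurement 4 cm to the subject's left), (2)
#' the channel pair with the highest slow-wave SNR, and (3) the best-SNR
#' pair after LMMSE artifact removal. For every condition it reports the
#' percent of windows with normal 2-4 cpm activity, and — when manometry is
#' supplied — the regression of motility index on EGG band power per
#' pressure channel, with Bonferroni adjustment over channels.
#'
#' @param rec An `egg_recording`. Without a layout the traditional-pair
#'   condition is skipped with a warning.
#' @param pressure Optional manometry input: a tibble with `time` +
#'   pressure column (single channel) or a named list of such tibbles.
#' @param config Parameter list from [egg_config()].
#' @return An object of class `egg_validation_report`: tibbles
#'   `percent_normal` (condition x value), `correlations` (condition x
#'   channel), `pairs`, and `snr` per condition.
#' @export
run_validation_pipeline <- function(rec, pressure = NULL,
                                    config = egg_config()) {
  conds <- list()
  if (!is.null(recording_layout(rec))) {
    tp <- traditional_pair(rec)
    conds$traditional <- list(pair = tp, clean = FALSE)
  } else {
    warning("no electrode layout: traditional-pair condition skipped",
            call. = FALSE)
  }
  bp <- best_pair(rec, window_s = config$window_s,
                  overlap_frac = config$overlap_frac,
                  signal_band = config$signal_band,
                  analysis_band = config$analysis_band)
  conds$best_snr <- list(pair = list(measurement = bp$measurement,
                                     reference = bp$reference),
                         clean = FALSE)
  conds$best_snr_cleaned <- list(pair = conds$best_snr$pair, clean = TRUE)

  mi_list <- NULL
  if (!is.null(pressure)) {
    if (is.data.frame(pressure)) pressure <- list(p1 = pressure)
    mi_list <- purrr::map(pressure, function(p) {
      motility_index(p, threshold = config$motility_threshold,
                     window_s = config$window_s,
                     overlap_frac = config$overlap_frac)
    })
  }

  rows <- purrr::imap(conds, function(cond, name) {
    sig <- rereference(rec, cond$pair$measurement, cond$pair$reference)
    if (cond$clean) {
      fit <- remove_artifacts(sig, fs = recording_fs(rec),
                              peak_freq = config$peak_freq)
      sig <- tidy(fit) |> dplyr::select("time", value = "egg")
      attr(sig, "fs") <- recording_fs(rec)
    }
    spec <- compute_spectrogram(sig, fs = recording_fs(rec),
                                window_s = config$window_s,
                                overlap_frac = config$overlap_frac)
    feats <- egg_features(spec, signal_band = config$signal_band,
                          background_band = config$background_band,
                          analysis_band = config$analysis_band,
                          normal_band = config$normal_band)
    pn <- percent_normal(spec, normal_band = config$normal_band,
                         analysis_band = config$analysis_band)
    snr_db <- egg_snr(spec, signal_band = config$signal_band,
                      analysis_band = config$analysis_band)
    cors <- NULL
    if (!is.null(mi_list)) {
      cors <- purrr::imap_dfr(mi_list, function(mi, ch) {
        nw <- min(nrow(feats), nrow(mi))
        res <- correlate_egg_manometry(
          tibble::tibble(band_power_db = feats$band_power_db[seq_len(nw)],
                         mi = mi$mi[seq_len(nw)]),
          n_channels = length(mi_list)
        )
        dplyr::mutate(glance(res, alpha = config$alpha),
                      condition = name, channel = ch, .before = 1)
      })
    }
    list(
      percent_normal = tibble::tibble(condition = name, percent_normal = pn,
                                      snr_db = snr_db,
                                      measurement = cond$pair$measurement,
                                      reference = cond$pair$reference,
                                      cleaned = cond$clean),
      correlations = cors
    )
  })
  out <- list(
    percent_normal = purrr::map_dfr(rows, "percent_normal"),
    correlations = if (is.null(mi_list)) NULL
                   else purrr::map_dfr(rows, "correlations"),
    config = config
  )
  class(out) <- "egg_validation_report"
  out
}

#' @export
print.egg_validation_report <- function(x, ...) {
  cat("<egg_validation_report>\n\nPercent normal slow-wave activity:\n")
  print(x$percent_normal)
  if (!is.null(x$correlations)) {
    cat("\nEGG-manometry correlations:\n")
    print(x$correlations)
  }
  invisible(x)
}

#' Paired comparisons of validation conditions across subjects
#'
#' Given one [run_validation_pipeline()] report per subject, runs the
#' paired two-sided t-tests between conditions (traditional vs best-SNR vs
#' cleaned) for percent-normal activity and, when available, for the
#' EGG-manometry correlation coefficient.
#'
#' @param reports List of `egg_validation_report` objects, one per subject.
#' @return Tibble with one row per metric and condition contrast.
#' @export
summarise_validation <- function(reports) {
  pn <- purrr::imap_dfr(reports, function(r, i) {
    dplyr::mutate(r$percent_normal, subject = i)
  })
  metrics <- list(percent_normal = pn |>
                    dplyr::select("subject", "condition",
                                  value = "percent_normal"))
  if (!purrr::some(reports, ~ is.null(.x$correlations))) {
    rr <- purrr::imap_dfr(reports, function(r, i) {
      r$correlations |>
        dplyr::group_by(.data$condition) |>
        dplyr::summarise(value = mean(.data$r), .groups = "drop") |>
        dplyr::mutate(subject = i)
    })
    metrics$correlation_r <- rr
  }
  contrasts <- list(c("traditional", "best_snr"),
                    c("best_snr", "best_snr_cleaned"),
                    c("traditional", "best_snr_cleaned"))
  purrr::imap_dfr(metrics, function(m, metric) {
    wide <- tidyr::pivot_wider(m, names_from = "condition",
                               values_from = "value")
    purrr::map_dfr(contrasts, function(ct) {
      if (!all(ct %in% names(wide))) return(NULL)
      res <- tryCatch(
        paired_comparison(wide[[ct[1]]], wide[[ct[2]]]),
        error = function(e) {
          # identical values in both conditions: no contrast to test
          tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                         df = length(wide[[ct[1]]]) - 1,
                         n = length(wide[[ct[1]]]),
                         mean_difference = mean(wide[[ct[2]]] - wide[[ct[1]]]))
        }
      )
      dplyr::mutate(res, metric = metric, from = ct[1], to = ct[2],
                    .before = 1)
    })
  })
}

#' Run the ambulatory pipeline on a day-long recording
#'
#' Cleans the signal with the LMMSE artifact filter, computes the
#' spectrogram and per-window features, finds isolated meals in the event
#' log (at least five quiet hours on both sides), aligns normalized power
#' on meal completion, and aligns the dominant-frequency series on sleep
#' onset.
#'
#' @param data Tibble with `time` and the observed signal (e.g. from
#'   [simulate_ambulatory_day()]`$recording` or [rereference()]).
#' @param events Event tibble (`time`, `tag`, `note`).
#' @param value Signal column (tidyselect), defaulting as in
#'   [remove_artifacts()].
#' @param fs Sampling rate in Hz (attribute fallback).
#' @param config Parameter list from [egg_config()].
#' @param meal_pre_s,meal_post_s Meal alignment window in s (default 1 h
#'   before to 5 h after completion).
#' @param sleep_pre_s,sleep_post_s Sleep-onset alignment window in s.
#' @return A list of class `egg_ambulatory_report`: `cleaned`
#'   (`egg_lmmse`), `spectrogram`, `features`, `isolated_meals`,
#'   `meal_aligned` (`egg_alignment` or `NULL`), `sleep_aligned`
#'   (`egg_alignment` or `NULL`).
#' @export
run_ambulatory_pipeline <- function(data, events, value = NULL, fs = NULL,
                                    config = egg_config(),
                                    meal_pre_s = 3600,
                                    meal_post_s = 5 * 3600,
                                    sleep_pre_s = 2 * 3600,
                                    sleep_post_s = 4 * 3600) {
  fs <- fs %||% attr(data, "fs")
  fit <- remove_artifacts(data, value = {{ value }}, fs = fs,
                          peak_freq = config$peak_freq)
  cleaned <- tidy(fit) |> dplyr::select("time", value = "egg")
  attr(cleaned, "fs") <- fit$fs
  spec <- compute_spectrogram(cleaned, fs = fit$fs,
                              window_s = config$window_s,
                              overlap_frac = config$overlap_frac)
  feats <- egg_features(spec, signal_band = config$signal_band,
                        background_band = config$background_band,
                        analysis_band = config$analysis_band,
                        normal_band = config$normal_band)
  meals <- find_isolated_meals(events)
  meal_aligned <- NULL
  if (nrow(meals) > 0) {
    meal_aligned <- tryCatch(
      align_by_event(feats, meals$time, pre_s = meal_pre_s,
                     post_s = meal_post_s),
      error = function(e) NULL
    )
  } else {
    message("no isolated meals in the event log; meal section empty")
  }
  align_freq <- function(tag) {
    if (!any(events$tag == tag)) return(NULL)
    tryCatch(
      suppressWarnings(
        align_by_event(feats, events$time[events$tag == tag],
                       pre_s = sleep_pre_s, post_s = sleep_post_s,
                       value = dominant_freq_hz)
      ),
      error = function(e) NULL
    )
  }
  out <- list(cleaned = fit, spectrogram = spec, features = feats,
              isolated_meals = meals, meal_aligned = meal_aligned,
              sleep_aligned = align_freq("sleep_onset"),
              wake_aligned = align_freq("wake_onset"), config = config)
  class(out) <- "egg_ambulatory_report"
  out
}

#' @export
print.egg_ambulatory_report <- function(x, ...) {
  cat("<egg_ambulatory_report>\n")
  cat(sprintf("  %d feature windows; percent normal %.1f%%\n",
              nrow(x$features), 100 * mean(x$features$is_normal)))
  cat(sprintf("  isolated meals: %d; sleep-aligned: %s\n",
              nrow(x$isolated_meals),
              if (is.null(x$sleep_aligned)) "no" else "yes"))
  invisible(x)
}
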