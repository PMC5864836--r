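#' Construct a multichannel EGG recording
#'
#' A recording is a tibble with a `time` column (seconds from record start)
#' and one column of biopotential samples (microvolts) per channel. Sampling
#' rate, electrode layout and the recording reference travel as attributes so
#' the recording can be piped straight into [downsample()], [rereference()]
#' or [best_pair()].
#'
#' @param data Data frame with a `time` column and one numeric column per
#'   channel, in microvolts.
#' @param fs Sampling rate in Hz. If `NULL`, inferred from the median spacing
#'   of the `time` column.
#' @param layout Optional tibble with columns `channel`, `x`, `y`: electrode
#'   positions in cm on the abdominal grid. The convention is x positive
#'   toward the subject's left, y positive toward the head, origin at the
#'   midline reference electrode.
#' @param reference Optional label of the channel used as recording reference.
#' @param start_time Optional absolute `POSIXct` timestamp of the first sample.
#'
#' @return A tibble of class `egg_recording` with attributes `fs`, `layout`,
#'   `reference` and `start_time`.
#' @export
#' @examples
#' rec <- new_recording(
#'   tibble::tibble(time = seq(0, 1.8, by = 0.2), ch1 = rnorm(10), ch2 = rnorm(10)),
#'   fs = 5
#' )
#' recording_fs(rec)
new_recording <- function(data, fs = NULL, layout = NULL, reference = NULL,
                          start_time = NULL) {
  data <- tibble::as_tibble(data)
  if (!"time" %in% names(data)) {
    stop("recording must have a `time` column", call. = FALSE)
  }
  chans <- setdiff(names(data), "time")
  if (length(chans) == 0L) stop("recording has no channel columns", call. = FALSE)
  if (anyDuplicated(chans)) stop("channel labels must be unique", call. = FALSE)
  if (is.unsorted(data$time, strictly = TRUE)) {
    stop("time column must be strictly increasing", call. = FALSE)
  }
  if (is.null(fs)) {
    dt <- stats::median(diff(data$time))
    if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate", call. = FALSE)
    fs <- 1 / dt
  }
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (!is.null(layout)) {
    layout <- tibble::as_tibble(layout)
    stopifnot(all(c("channel", "x", "y") %in% names(layout)))
    missing <- setdiff(chans, layout$channel)
    if (length(missing) > 0) {
      stop("layout missing channels: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    data,
    fs = fs, layout = layout, reference = reference, start_time = start_time,
    class = c("egg_recording", class(tibble::tibble()))
  )
}

#' @rdname new_recording
#' @param rec An `egg_recording`.
#' @export
recording_fs <- function(rec) attr(rec, "fs")

#' @rdname new_recording
#' @export
recording_channels <- function(rec) setdiff(names(rec), "time")

#' @rdname new_recording
#' @export
recording_layout <- function(rec) attr(rec, "layout")

#' Read and write multichannel recordings
#'
#' Recordings are stored as plain CSV/TSV with a header: a `time` column in
#' seconds plus one column per channel in microvolts. A JSON sidecar (default
#' `<path>.json`) carries the sampling rate, units, electrode layout and
#' reference label. Reading a file written by [write_recording()] reproduces
#' the values exactly.
#'
#' @param path Path to the CSV/TSV file.
#' @param format `"csv"` or `"tsv"`; inferred from the extension when `NULL`.
#' @param config Path to the JSON sidecar. `NULL` falls back to
#'   `<path>.json`; a missing sidecar is allowed if the time column pins down
#'   the sampling rate.
#' @param fs Optional override of the sampling rate (takes precedence over
#'   sidecar and time column).
#' @return [read_recording()] returns an `egg_recording`;
#'   [write_recording()] returns `path` invisibly.
#' @export
read_recording <- function(path, format = NULL, config = NULL, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% if (grepl("\\.tsv$", path)) "tsv" else "csv"
  format <- match.arg(format, c("csv", "tsv"))
  reader <- if (format == "csv") readr::read_csv else readr::read_tsv
  data <- tryCatch(
    reader(path, show_col_types = FALSE, progress = FALSE),
    warning = function(w) stop("malformed recording file: ", conditionMessage(w),
                               call. = FALSE)
  )
  if (!"time" %in% names(data)) {
    stop("recording file must have a `time` column", call. = FALSE)
  }
  if (anyNA(data)) stop("ragged or missing values in recording file", call. = FALSE)
  if (is.unsorted(data$time, strictly = TRUE)) {
    stop("non-monotonic time column", call. = FALSE)
  }
  config <- config %||% paste0(path, ".json")
  layout <- NULL; reference <- NULL
  if (file.exists(config)) {
    cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
    fs <- fs %||% cfg$fs
    reference <- cfg$reference
    if (!is.null(cfg$layout)) layout <- tibble::as_tibble(cfg$layout)
  }
  new_recording(data, fs = fs, layout = layout, reference = reference)
}

#' @rdname read_recording
#' @param rec An `egg_recording` (or plain data frame with a `time` column).
#' @param write_config Write the JSON sidecar alongside the data file.
#' @export
write_recording <- function(rec, path, format = NULL, write_config = TRUE) {
  format <- format %||% if (grepl("\\.tsv$", path)) "tsv" else "csv"
  format <- match.arg(format, c("csv", "tsv"))
  writer <- if (format == "csv") readr::write_csv else readr::write_tsv
  writer(tibble::as_tibble(unclass(rec)), path, progress = FALSE)
  if (write_config) {
    cfg <- list(fs = attr(rec, "fs"), units = "uV")
    if (!is.null(attr(rec, "reference"))) cfg$reference <- attr(rec, "reference")
    if (!is.null(attr(rec, "layout"))) cfg$layout <- attr(rec, "layout")
    jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
  }
  invisible(path)
}

#' Read and write event logs
#'
#' Events (meals, sleep onset, symptoms, ...) are stored as JSON lines: one
#' object per line with fields `time` (seconds from record start), `tag` and
#' optional `note`. Tags outside the controlled vocabulary are coerced to
#' `"other"` with a warning.
#'
#' @param path Path to the JSON-lines file.
#' @return A tibble with columns `time`, `tag`, `note`, sorted by time.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_event_log())
  events <- purrr::map_dfr(lines, function(l) {
    e <- jsonlite::fromJSON(l)
    tibble::tibble(time = as.numeric(e$time), tag = as.character(e$tag),
                   note = as.character(e$note %||% ""))
  })
  validate_event_log(events)
}

#' @rdname read_event_log
#' @param events Tibble with columns `time`, `tag` and optional `note`.
#' @export
write_event_log <- function(events, path) {
  events <- validate_event_log(events)
  lines <- purrr::pmap_chr(events, function(time, tag, note) {
    jsonlite::toJSON(list(time = time, tag = tag, note = note),
                     auto_unbox = TRUE, digits = NA)
  })
  writeLines(lines, path)
  invisible(path)
}

event_tags <- c("meal", "snack", "bowel_movement", "sleep_onset",
                "wake_onset", "symptom", "exercise", "other")

empty_event_log <- function() {
  tibble::tibble(time = numeric(), tag = character(), note = character())
}

validate_event_log <- function(events) {
  events <- tibble::as_tibble(events)
  if (!all(c("time", "tag") %in% names(events))) {
    stop("event log needs `time` and `tag` columns", call. = FALSE)
  }
  if (!"note" %in% names(events)) events$note <- ""
  bad <- !events$tag %in% event_tags
  if (any(bad)) {
    warning("unknown event tags coerced to 'other': ",
            paste(unique(events$tag[bad]), collapse = ", "), call. = FALSE)
    events$tag[bad] <- "other"
  }
  dplyr::arrange(events[, c("time", "tag", "note")], .data$time)
}

#' Downsample a recording with anti-alias filtering
#'
#' Applies a zero-phase low-pass filter (4th-order Butterworth run forward
#' and backward, cutoff `0.4 * target_fs`) to every channel and keeps every
#' `fs / target_fs`-th sample. The factor must be an integer, and the target
#' rate must still resolve the top of the 0.02-0.20 Hz analysis band.
#'
#' @param rec An `egg_recording`.
#' @param target_fs Target sampling rate in Hz (e.g. 5 for 250 Hz input).
#' @return The downsampled `egg_recording`.
#' @export
downsample <- function(rec, target_fs) {
  fs <- recording_fs(rec)
  factor <- fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    stop("target_fs must divide fs evenly (fs = ", fs, ")", call. = FALSE)
  }
  factor <- round(factor)
  if (target_fs < 2 * 0.20) {
    stop("target_fs below Nyquist requirement for the 0.20 Hz band",
         call. = FALSE)
  }
  keep <- seq(1, nrow(rec), by = factor)
  out <- tibble::as_tibble(unclass(rec))
  if (factor > 1L) {
    bf <- signal::butter(4, (0.4 * target_fs) / (fs / 2), type = "low")
    for (ch in setdiff(names(out), "time")) {
      out[[ch]] <- signal::filtfilt(bf, out[[ch]])
    }
  }
  out <- out[keep, ]
  new_recording(out, fs = target_fs, layout = attr(rec, "layout"),
                reference = attr(rec, "reference"),
                start_time = attr(rec, "start_time"))
}

#' Re-reference a recording to a bipolar signal
#'
#' Forms a bipolar measurement by elementwise subtraction of the reference
#' channel from the measurement channel, the standard post-hoc
#' re-referencing for monopolar array recordings.
#'
#' @param rec An `egg_recording`.
#' @param measurement,reference Channel labels.
#' @return A tibble with columns `time` and `value` (microvolts), carrying
#'   attributes `fs`, `measurement_label` and `reference_label`.
#' @export
rereference <- function(rec, measurement, reference) {
  chans <- recording_channels(rec)
  for (lab in c(measurement, reference)) {
    if (!lab %in% chans) stop("unknown channel label: ", lab, call. = FALSE)
  }
  out <- tibble::tibble(time = rec$time,
                        value = rec[[measurement]] - rec[[reference]])
  structure(out, fs = recording_fs(rec), measurement_label = measurement,
            reference_label = reference,
            class = class(tibble::tibble()))
}

#' Locate the traditional EGG electrode pair
#'
#' The traditional cutaneous EGG montage references the electrode on the
#' abdominal midline halfway between the xiphoid process and umbilicus
#' (layout origin) against a measurement electrode 4 cm to the subject's
#' left. Given a layout, this returns the channels nearest those two
#' positions; if the nearest channel is farther from its target than one
#' grid spacing, a warning is raised and the best match is still returned.
#'
#' @param rec An `egg_recording` with a layout attribute.
#' @param left_offset_cm Distance of the measurement electrode from the
#'   midline toward the subject's left, in cm.
#' @return A list with elements `measurement` and `reference` (labels).
#' @export
traditional_pair <- function(rec, left_offset_cm = 4) {
  layout <- recording_layout(rec)
  if (is.null(layout)) {
    stop("recording has no electrode layout; cannot locate traditional pair",
         call. = FALSE)
  }
  if (length(recording_channels(rec)) < 2L) {
    stop("need at least two channels for a bipolar pair", call. = FALSE)
  }
  layout <- layout[layout$channel %in% recording_channels(rec), ]
  d <- function(x0, y0) sqrt((layout$x - x0)^2 + (layout$y - y0)^2)
  spacing <- min(stats::dist(cbind(layout$x, layout$y)))
  ref_d <- d(0, 0)
  ref_i <- which.min(ref_d)
  ref_y <- layout$y[ref_i]
  # measurement target: left_offset_cm toward the subject's left of the
  # reference, at the same height
  meas_d <- d(left_offset_cm, ref_y)
  meas_d[ref_i] <- Inf
  meas_i <- which.min(meas_d)
  if (ref_d[ref_i] > spacing || meas_d[meas_i] > spacing) {
    warning("nearest electrode is farther than one grid spacing from the ",
            "traditional position; using best match", call. = FALSE)
  }
  list(measurement = layout$channel[meas_i], reference = layout$channel[ref_i])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
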