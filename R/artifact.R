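#' Local mean and variance of a signal
#'
#' For each sample, computes the mean and population variance of the signal
#' over a window of `window_n` samples centered on that sample. Windows are
#' truncated at the record edges rather than padded, so the first and last
#' samples use only the data that exist. These local moments stand in for
#' the expectation and variance of the observed signal in the LMMSE artifact
#' estimator.
#'
#' With `mode = "block"` the record is instead cut into disjoint blocks of
#' `window_n` samples and every sample in a block shares that block's mean
#' and variance.
#'
#' @param y Numeric vector of samples (microvolts).
#' @param window_n Odd window length in samples, between 3 and `length(y)`.
#' @param mode `"sliding"` (centered per-sample window) or `"block"`
#'   (disjoint blocks).
#' @return A tibble with columns `local_mean` (uV) and `local_var` (uV^2),
#'   one row per sample, with attribute `window_n`.
#' @export
#' @examples
#' local_moments(c(1, 2, 3, 4, 5), 3)
local_moments <- function(y, window_n, mode = c("sliding", "block")) {
  mode <- match.arg(mode)
  n <- length(y)
  if (window_n %% 2 == 0) {
    stop("window_n must be odd for a centered window", call. = FALSE)
  }
  if (window_n < 3 || window_n > n) {
    stop("window_n must be in [3, length(y)]", call. = FALSE)
  }
  if (anyNA(y)) stop("NA samples in input", call. = FALSE)
  if (mode == "sliding") {
    h <- (window_n - 1L) / 2L
    # windowed sums via cumulative sums; edge windows shrink to the data
    cs <- cumsum(c(0, y))
    cs2 <- cumsum(c(0, y^2))
    idx <- seq_len(n)
    lo <- pmax(idx - h, 1L)
    hi <- pmin(idx + h, n)
    cnt <- hi - lo + 1L
    s1 <- cs[hi + 1L] - cs[lo]
    s2 <- cs2[hi + 1L] - cs2[lo]
    m <- s1 / cnt
    v <- pmax(s2 / cnt - m^2, 0)
  } else {
    block <- (seq_len(n) - 1L) %/% window_n
    m_b <- tapply(y, block, mean)
    v_b <- tapply(y, block, function(x) mean((x - mean(x))^2))
    m <- as.numeric(m_b[as.character(block)])
    v <- as.numeric(v_b[as.character(block)])
  }
  structure(tibble::tibble(local_mean = m, local_var = v),
            window_n = as.integer(window_n),
            class = class(tibble::tibble()))
}

#' Default LMMSE window length
#'
#' The moment-estimation window is one average gastric slow-wave cycle: the
#' sampling rate divided by the mean peak EGG frequency, rounded and forced
#' odd so the window has an exact center sample. At 5 Hz and the normal
#' 3 cpm (0.05 Hz) rhythm this gives 101 samples (about 20 s).
#'
#' @param fs Sampling rate in Hz.
#' @param peak_freq Mean peak EGG frequency in Hz, within the 0.02-0.20 Hz
#'   analysis band.
#' @return Odd integer window length in samples.
#' @export
default_window_n <- function(fs, peak_freq = 0.05) {
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (peak_freq < 0.02 || peak_freq > 0.20) {
    stop("peak_freq outside the 0.02-0.20 Hz analysis band", call. = FALSE)
  }
  n <- round(fs / peak_freq)
  if (n %% 2 == 0) n <- n + 1
  as.integer(n)
}

#' EGG variance floor
#'
#' The variance of the gastric signal itself is not observable, so it is
#' estimated as the mean of the local variance of the observed signal over
#' the whole record. Quiet stretches dominate this average, making it a
#' floor that artifact bursts stand well above.
#'
#' @param moments Tibble from [local_moments()] (or anything with a
#'   `local_var` column).
#' @return Scalar variance floor in uV^2.
#' @export
estimate_sigma_e_sq <- function(moments) {
  v <- moments$local_var
  if (is.null(v) || length(v) == 0L) {
    stop("moments must have a non-empty local_var column", call. = FALSE)
  }
  mean(v)
}

#' LMMSE artifact estimate
#'
#' Computes the artifact estimate
#' \deqn{\hat{x}_t = m_t + \frac{\max\{0, v_t - \sigma_e^2\}}
#'   {\max\{v_t, \sigma_e^2\}} (y_t - m_t)}
#' where \eqn{m_t, v_t} are the local mean and variance of the observation
#' and \eqn{\sigma_e^2} is the EGG variance floor. The shrinkage gain lies
#' in \eqn{[0, 1)}: where the local variance is at or below the floor the
#' estimate is the local mean (pure smoothing), and where an artifact drives
#' the local variance far above the floor the estimate approaches the
#' observation itself. Where both the local variance and the floor are zero
#' the gain is defined as 0.
#'
#' @param y Numeric vector of observed samples (uV).
#' @param moments Tibble from [local_moments()], aligned with `y`.
#' @param sigma_e_sq Non-negative variance floor (uV^2).
#' @return Numeric vector: the estimated artifact series (uV).
#' @export
lmmse_artifact <- function(y, moments, sigma_e_sq) {
  if (sigma_e_sq < 0) stop("sigma_e_sq must be non-negative", call. = FALSE)
  m <- moments$local_mean
  v <- moments$local_var
  if (length(m) != length(y)) {
    stop("moments not aligned with y", call. = FALSE)
  }
  denom <- pmax(v, sigma_e_sq)
  gain <- ifelse(denom > 0, pmax(v - sigma_e_sq, 0) / denom, 0)
  if (sigma_e_sq == 0 && any(v == 0)) {
    warning("degenerate input: zero local variance with zero variance floor; ",
            "gain set to 0 there", call. = FALSE)
  }
  m + gain * (y - m)
}

#' Remove motion artifacts from an EGG signal
#'
#' Runs the full LMMSE artifact-rejection procedure: estimate local mean and
#' variance over one slow-wave cycle, average the local variance into the
#' EGG variance floor \eqn{\sigma_e^2}, form the shrinkage artifact estimate,
#' and subtract it from the observation. The cleaned signal and the artifact
#' estimate always sum back to the input exactly.
#'
#' In artifact-free stretches the local variance sits near (or below) the
#' floor, so the artifact estimate reduces to the local mean and cleaning
#' amounts to removal of baseline drift. Inside a high-amplitude burst the
#' local variance dwarfs the floor, the gain approaches 1, and the burst is
#' subtracted almost entirely.
#'
#' @param data Data frame with the observed signal (e.g. from
#'   [rereference()] or [simulate_egg()]), or a bare numeric vector.
#' @param value Column holding the observed samples (tidyselect; default
#'   `value`, falling back to `observed` if present).
#' @param fs Sampling rate in Hz; taken from the `fs` attribute of `data`
#'   when present.
#' @param peak_freq Mean peak EGG frequency in Hz used to size the window.
#' @param window_n Explicit odd window length in samples; overrides
#'   `peak_freq` sizing.
#' @param mode Moment estimation mode, `"sliding"` or `"block"`; see
#'   [local_moments()].
#' @return An object of class `egg_lmmse`: a list with a per-sample tibble
#'   (`time`, `observed`, `artifact`, `egg`, `gain`) plus `sigma_e_sq`,
#'   `window_n`, `fs` and `mode`. Use [tidy()] for the samples and
#'   [glance()] for the one-row summary.
#' @export
#' @examples
#' sim <- simulate_egg(duration_s = 1200, seed = 1)
#' fit <- remove_artifacts(sim, value = observed)
#' glance(fit)
remove_artifacts <- function(data, value = NULL, fs = NULL, peak_freq = 0.05,
                             window_n = NULL, mode = c("sliding", "block")) {
  mode <- match.arg(mode)
  if (is.numeric(data) && is.null(dim(data))) {
    y <- data
    time <- if (is.null(fs)) seq_along(y) - 1 else (seq_along(y) - 1) / fs
  } else {
    data_tb <- tibble::as_tibble(data)
    fs <- fs %||% attr(data, "fs")
    quo <- rlang::enquo(value)
    col <- if (rlang::quo_is_null(quo)) {
      if ("value" %in% names(data_tb)) "value"
      else if ("observed" %in% names(data_tb)) "observed"
      else stop("no `value` or `observed` column; name one with `value =`",
                call. = FALSE)
    } else {
      rlang::as_name(quo)
    }
    y <- data_tb[[col]]
    if (is.null(y)) stop("column not found: ", col, call. = FALSE)
    time <- data_tb[["time"]] %||% ((seq_along(y) - 1) / (fs %||% 1))
  }
  if (is.null(fs)) stop("sampling rate `fs` is required", call. = FALSE)
  if (anyNA(y)) stop("NA samples in input", call. = FALSE)
  window_n <- window_n %||% default_window_n(fs, peak_freq)
  if (length(y) < window_n) {
    stop("signal shorter than one moment window (", window_n, " samples)",
         call. = FALSE)
  }
  mom <- local_moments(y, window_n, mode = mode)
  sigma_e_sq <- estimate_sigma_e_sq(mom)
  xhat <- lmmse_artifact(y, mom, sigma_e_sq)
  denom <- pmax(mom$local_var, sigma_e_sq)
  gain <- ifelse(denom > 0, pmax(mom$local_var - sigma_e_sq, 0) / denom, 0)
  out <- list(
    data = tibble::tibble(time = time, observed = y, artifact = xhat,
                          egg = y - xhat, gain = gain),
    sigma_e_sq = sigma_e_sq,
    window_n = as.integer(window_n),
    fs = fs,
    mode = mode
  )
  class(out) <- "egg_lmmse"
  out
}

#' @export
print.egg_lmmse <- function(x, ...) {
  cat("<egg_lmmse> LMMSE artifact decomposition\n")
  cat(sprintf("  samples: %d at %g Hz  window_n: %d (%s)\n",
              nrow(x$data), x$fs, x$window_n, x$mode))
  cat(sprintf("  sigma_e^2: %.4g uV^2  artifact burden (gain > 0.5): %.1f%%\n",
              x$sigma_e_sq, 100 * mean(x$data$gain > 0.5)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for LMMSE artifact decompositions
#'
#' `tidy()` returns the per-sample decomposition (`time`, `observed`,
#' `artifact`, `egg`, `gain`); `glance()` returns a one-row summary with the
#' variance floor, window length and the fraction of samples treated as
#' artifact-dominated (gain above 0.5).
#'
#' @param x An `egg_lmmse` object from [remove_artifacts()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.egg_lmmse <- function(x, ...) x$data

#' @rdname tidy.egg_lmmse
#' @export
glance.egg_lmmse <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$data),
    fs = x$fs,
    window_n = x$window_n,
    mode = x$mode,
    sigma_e_sq = x$sigma_e_sq,
    artifact_burden = mean(x$data$gain > 0.5)
  )
}
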