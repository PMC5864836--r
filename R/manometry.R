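#' Manometric motility index
#'
#' A windowed contractility measure from antral manometry: within each
#' analysis window the pressure excess above a 9 mmHg threshold is
#' integrated over time (Riemann sum, each sample representing `1/fs` s,
#' units mmHg*s), and the motility index is the natural logarithm of that
#' area. Windows are framed exactly like [compute_spectrogram()] (default
#' four minutes with 75% overlap), so the index aligns window-for-window
#' with EGG spectral features on an equal-length record.
#'
#' Contraction-free windows have zero area; their index is floored at
#' `log(epsilon)` (0 with the default `epsilon = 1` mmHg*s) and flagged in
#' the `at_floor` column.
#'
#' @param data Data frame with `time` and a pressure column (mmHg), or a
#'   bare numeric vector.
#' @param value Pressure column (tidyselect); defaults to `value`, falling
#'   back to `pressure`.
#' @param fs Sampling rate in Hz; taken from the `fs` attribute when present.
#' @param threshold Threshold pressure in mmHg.
#' @param window_s,overlap_frac Window framing, matching the EGG spectrogram.
#' @param epsilon Area floor in mmHg*s guarding `log(0)`.
#' @return Tibble with columns `time` (window centers, s), `area`
#'   (mmHg*s), `mi` and `at_floor`, with attribute `hop_s`.
#' @export
#' @examples
#' p <- rep(10, 1200)  # constant 10 mmHg for 240 s at 5 Hz
#' motility_index(p, fs = 5)$mi  # log(240)
motility_index <- function(data, value = NULL, fs = NULL, threshold = 9,
                           window_s = 240, overlap_frac = 0.75,
                           epsilon = 1) {
  if (is.numeric(data) && is.null(dim(data))) {
    p <- data
    if (is.null(fs)) stop("fs required for a bare vector", call. = FALSE)
    time <- (seq_along(p) - 1) / fs
  } else {
    data_tb <- tibble::as_tibble(data)
    fs <- fs %||% attr(data, "fs")
    if (is.null(fs)) stop("sampling rate `fs` is required", call. = FALSE)
    quo <- rlang::enquo(value)
    col <- if (rlang::quo_is_null(quo)) {
      cand <- intersect(c("value", "pressure"), names(data_tb))
      if (length(cand) == 0) stop("no pressure column found; use `value =`",
                                  call. = FALSE)
      cand[[1]]
    } else rlang::as_name(quo)
    p <- data_tb[[col]]
    time <- data_tb[["time"]] %||% ((seq_along(p) - 1) / fs)
  }
  W <- round(window_s * fs)
  if (length(p) < W) {
    stop("record shorter than one window (", window_s, " s)", call. = FALSE)
  }
  hop <- max(1L, round(W * (1 - overlap_frac)))
  starts <- seq(1L, length(p) - W + 1L, by = hop)
  excess <- pmax(p - threshold, 0)
  area <- vapply(starts, function(s) {
    seg <- excess[s:(s + W - 1L)]
    if (all(is.na(seg))) return(NA_real_)
    sum(seg, na.rm = TRUE) / fs
  }, numeric(1))
  structure(
    tibble::tibble(
      time = time[starts] + (W - 1) / (2 * fs),
      area = area,
      mi = log(pmax(area, epsilon)),
      at_floor = !is.na(area) & area < epsilon
    ),
    hop_s = window_s * (1 - overlap_frac),
    threshold = threshold,
    class = class(tibble::tibble())
  )
}

#' Correlate EGG band power with the motility index
#'
#' Ordinary least-squares regression of the motility index on the EGG
#' 0.04-0.06 Hz band power across aligned analysis windows, the
#' standard way to validate that the cutaneous slow-wave signal
#' tracks antral contractility. Reports the correlation coefficient, the
#' fitted slope and intercept, the two-sided p-value for a zero slope, and
#' a Bonferroni-adjusted p-value (`min(1, p * n_channels)`) accounting for
#' the number of manometry channels tested per subject.
#'
#' @param data Data frame holding the two aligned per-window series, or a
#'   numeric vector (then `mi` must be a numeric vector too).
#' @param egg_power,mi Columns with the EGG band power (dB) and motility
#'   index (tidyselect), defaulting to `band_power_db` and `mi`.
#' @param n_channels Number of manometry channels for the Bonferroni
#'   correction.
#' @return An object of class `egg_correlation` wrapping the [stats::lm()]
#'   fit; `glance()` returns `r`, `slope`, `intercept`, `p_value`,
#'   `p_adjusted`, `n_windows`, `significant` (at the 0.01 level);
#'   `tidy()` returns the coefficient table.
#' @export
correlate_egg_manometry <- function(data, egg_power = NULL, mi = NULL,
                                    n_channels = 1) {
  if (is.numeric(data) && is.null(dim(data))) {
    x <- data
    y <- mi
    if (!is.numeric(y)) stop("vector input needs numeric `mi`", call. = FALSE)
  } else {
    data_tb <- tibble::as_tibble(data)
    xq <- rlang::enquo(egg_power); yq <- rlang::enquo(mi)
    xcol <- if (rlang::quo_is_null(xq)) "band_power_db" else rlang::as_name(xq)
    ycol <- if (rlang::quo_is_null(yq)) "mi" else rlang::as_name(yq)
    for (cl in c(xcol, ycol)) {
      if (!cl %in% names(data_tb)) stop("column not found: ", cl, call. = FALSE)
    }
    x <- data_tb[[xcol]]
    y <- data_tb[[ycol]]
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3) {
    stop("need at least 3 aligned windows", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in input series; correlation undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- sm$coefficients["x", "Pr(>|t|)"]
  out <- list(
    fit = fit,
    r = stats::cor(x, y),
    slope = unname(stats::coef(fit)["x"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    p_value = p,
    p_adjusted = min(1, p * n_channels),
    n_windows = length(x),
    n_channels = n_channels
  )
  class(out) <- "egg_correlation"
  out
}

#' @export
print.egg_correlation <- function(x, ...) {
  cat("<egg_correlation> EGG band power vs motility index\n")
  cat(sprintf("  r = %.3f, slope = %.4g, n = %d windows\n",
              x$r, x$slope, x$n_windows))
  cat(sprintf("  p = %.3g (Bonferroni x%d: %.3g)\n",
              x$p_value, x$n_channels, x$p_adjusted))
  invisible(x)
}

#' Tidiers for EGG-manometry correlations
#'
#' @param x An `egg_correlation` from [correlate_egg_manometry()].
#' @param ... Unused.
#' @param alpha Significance level applied to the adjusted p-value.
#' @return A tibble.
#' @export
tidy.egg_correlation <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "egg_power"),
    estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"],
    statistic = co[, "t value"],
    p_value = co[, "Pr(>|t|)"]
  )
}

#' @rdname tidy.egg_correlation
#' @export
glance.egg_correlation <- function(x, alpha = 0.01, ...) {
  tibble::tibble(
    r = x$r,
    slope = x$slope,
    intercept = x$intercept,
    p_value = x$p_value,
    p_adjusted = x$p_adjusted,
    n_windows = x$n_windows,
    significant = x$p_adjusted <= alpha
  )
}

#' Paired two-sided comparison
#'
#' Paired, two-sided t-test for identical expected values of two related
#' samples (e.g. per-subject percent normal before and after artifact
#' removal). A constant nonzero shift (zero-variance differences) is
#' degenerate for the t statistic and is reported as `statistic = Inf`,
#' `p_value = 0`; identical samples raise an error.
#'
#' @param before,after Numeric vectors of equal length (n >= 2).
#' @return One-row tibble: `statistic`, `p_value`, `df`, `n`,
#'   `mean_difference`.
#' @export
paired_comparison <- function(before, after) {
  stopifnot(length(before) == length(after))
  if (length(before) < 2) stop("need n >= 2 pairs", call. = FALSE)
  d <- after - before
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      stop("identical paired samples: t-test degenerate", call. = FALSE)
    }
    return(tibble::tibble(statistic = sign(mean(d)) * Inf, p_value = 0,
                          df = length(d) - 1, n = length(d),
                          mean_difference = mean(d)))
  }
  tt <- stats::t.test(after, before, paired = TRUE)
  tibble::tibble(statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 df = unname(tt$parameter),
                 n = length(d),
                 mean_difference = mean(d))
}

#' Unpaired two-sided comparison (equal variances)
#'
#' Pooled-variance two-sample t-test for identical expected values of two
#' independent samples (e.g. post-meal vs fasting EGG power).
#'
#' @param a,b Numeric vectors, each n >= 2.
#' @return One-row tibble: `statistic`, `p_value`, `df`, `n_a`, `n_b`,
#'   `mean_difference`.
#' @export
unpaired_comparison <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2",
                                           call. = FALSE)
  pooled <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (pooled == 0) stop("zero pooled variance: t-test degenerate",
                        call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  tibble::tibble(statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 df = unname(tt$parameter),
                 n_a = length(a), n_b = length(b),
                 mean_difference = mean(a) - mean(b))
}
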