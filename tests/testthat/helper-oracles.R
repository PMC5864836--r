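# Independent brute-force oracles. These deliberately share no code with the
# package: per-sample loops and textbook formulas only.

# centered window, truncated at the edges, population variance
brute_local_moments <- function(y, window_n) {
  h <- (window_n - 1) / 2
  n <- length(y)
  m <- numeric(n)
  v <- numeric(n)
  for (t in seq_len(n)) {
    w <- y[max(1, t - h):min(n, t + h)]
    m[t] <- sum(w) / length(w)
    v[t] <- sum((w - m[t])^2) / length(w)
  }
  list(local_mean = m, local_var = v)
}

# per-sample shrinkage estimator, scalar arithmetic only
brute_lmmse <- function(y, window_n) {
  mom <- brute_local_moments(y, window_n)
  s2 <- mean(mom$local_var)
  xhat <- numeric(length(y))
  for (t in seq_along(y)) {
    num <- max(0, mom$local_var[t] - s2)
    den <- max(mom$local_var[t], s2)
    g <- if (den > 0) num / den else 0
    xhat[t] <- mom$local_mean[t] + g * (y[t] - mom$local_mean[t])
  }
  list(artifact = xhat, egg = y - xhat, sigma_e_sq = s2)
}

# textbook paired t: t = mean(d) / (sd(d) / sqrt(n)), two-sided p from t dist
oracle_paired_t <- function(before, after) {
  d <- after - before
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# pooled-variance two-sample t
oracle_unpaired_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}

# zero-slope test from first principles: slope, its standard error, t, p
oracle_slope_p <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  se <- sqrt(sum(res^2) / (n - 2) / sum((x - mean(x))^2))
  t <- b / se
  list(slope = b, p = 2 * pt(-abs(t), df = n - 2))
}

# one full spectrogram window's periodogram, written independently:
# demean, taper, fft, one-sided fold, normalize by W^2 * mean(w^2)
oracle_window_power <- function(seg, w) {
  W <- length(seg)
  xw <- (seg - mean(seg)) * w
  X <- fft(xw)
  nk <- floor(W / 2) + 1
  sc <- rep(2, nk); sc[1] <- 1
  if (W %% 2 == 0) sc[nk] <- 1
  sc * abs(X[1:nk])^2 / (W^2 * mean(w^2))
}
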