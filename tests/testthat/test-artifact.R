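test_that("local moments match hand computation with truncated edges", {
  mom <- local_moments(c(1, 2, 3, 4, 5), 3)
  expect_equal(mom$local_mean, c(1.5, 2, 3, 4, 4.5))
  # interior windows: population variance of three consecutive integers
  expect_equal(mom$local_var[2:4], rep(2 / 3, 3))
  expect_equal(mom$local_var[c(1, 5)], rep(0.25, 2))
  expect_equal(attr(mom, "window_n"), 3L)
})

test_that("local moments of a constant signal are degenerate", {
  mom <- local_moments(rep(4.2, 50), 11)
  expect_equal(mom$local_mean, rep(4.2, 50))
  expect_equal(mom$local_var, rep(0, 50))
})

test_that("vectorized local moments equal the brute-force loop exactly", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(50:400, 1)
    wn <- sample(seq(3, min(99, n), by = 2), 1)
    y <- rnorm(n, sd = runif(1, 1, 1000))
    mom <- local_moments(y, wn)
    ref <- brute_local_moments(y, wn)
    expect_equal(mom$local_mean, ref$local_mean, tolerance = 1e-12)
    expect_equal(mom$local_var, ref$local_var, tolerance = 1e-12)
  }
})

test_that("local moments validate the window", {
  expect_error(local_moments(rnorm(10), 4), "odd")
  expect_error(local_moments(rnorm(10), 11), "3")
  expect_error(local_moments(c(1, NA, 3, 4, 5), 3), "NA")
})

test_that("block mode shares moments within disjoint blocks", {
  y <- c(1, 2, 3, 10, 20, 30)
  mom <- local_moments(y, 3, mode = "block")
  expect_equal(mom$local_mean, c(2, 2, 2, 20, 20, 20))
  expect_equal(mom$local_var, c(rep(2 / 3, 3), rep(200 / 3, 3)))
})

test_that("default window is one slow-wave cycle, forced odd", {
  expect_identical(default_window_n(5, 0.05), 101L)
  expect_identical(default_window_n(5, 0.1), 51L)
  expect_identical(default_window_n(250, 0.05), 5001L)
  expect_error(default_window_n(5, 0.01), "band")
  expect_error(default_window_n(5, 0.25), "band")
  expect_error(default_window_n(-5, 0.05), "positive")
})

test_that("variance floor is the mean local variance", {
  expect_equal(estimate_sigma_e_sq(tibble::tibble(local_var = c(1, 2, 3))), 2)
  expect_equal(estimate_sigma_e_sq(local_moments(rep(1, 20), 5)), 0)
  set.seed(32)
  y <- rnorm(300)
  expect_equal(estimate_sigma_e_sq(local_moments(y, 21)),
               mean(brute_local_moments(y, 21)$local_var))
  expect_error(estimate_sigma_e_sq(tibble::tibble(local_var = numeric())),
               "empty")
})

test_that("LMMSE gain behaves at its closed-form operating points", {
  # Var(y) == sigma_e^2: estimate collapses to the local mean
  mom <- tibble::tibble(local_mean = 5, local_var = 2)
  expect_equal(lmmse_artifact(12, mom, 2), 5)
  # Var(y) == 2 sigma_e^2 and y - E[y] = 10: gain is exactly 1/2
  mom2 <- tibble::tibble(local_mean = 0, local_var = 4)
  expect_equal(lmmse_artifact(10, mom2, 2), 5)
  # constant signal: 0/0 gain defined as 0, artifact = local mean = y
  y <- rep(3, 30)
  mom3 <- local_moments(y, 5)
  expect_warning(xhat <- lmmse_artifact(y, mom3, 0), "degenerate")
  expect_equal(xhat, y)
})

test_that("shrinkage gain is bounded in [0, 1)", {
  set.seed(33)
  for (i in 1:25) {
    y <- rnorm(500, sd = runif(1, 1, 500)) +
      ifelse(runif(500) < 0.02, rnorm(500, sd = 3000), 0)
    fit <- remove_artifacts(y, fs = 5, window_n = 51)
    expect_true(all(fit$data$gain >= 0))
    expect_true(all(fit$data$gain < 1))
  }
})

test_that("artifact and cleaned signal reconstruct the observation", {
  set.seed(34)
  for (i in 1:10) {
    sim <- simulate_egg(duration_s = 600, seed = i)
    fit <- remove_artifacts(sim, value = observed)
    d <- tidy(fit)
    expect_lt(max(abs(d$artifact + d$egg - d$observed)),
              1e-9 * max(1, max(abs(d$observed))))
  }
})

test_that("full pipeline equals the brute-force per-sample loop", {
  set.seed(35)
  for (i in 1:10) {
    y <- rnorm(800, sd = 50) + ifelse(runif(800) < 0.01, 2000, 0)
    fit <- remove_artifacts(y, fs = 5, window_n = 101)
    ref <- brute_lmmse(y, 101)
    expect_equal(fit$sigma_e_sq, ref$sigma_e_sq, tolerance = 1e-12)
    expect_equal(fit$data$artifact, ref$artifact, tolerance = 1e-12)
    expect_equal(fit$data$egg, ref$egg, tolerance = 1e-12)
  }
})

test_that("cleaning is homogeneous of degree one", {
  set.seed(36)
  y <- rnorm(600, sd = 30) + ifelse(runif(600) < 0.02, 1500, 0)
  f1 <- remove_artifacts(y, fs = 5, window_n = 51)
  f2 <- remove_artifacts(7 * y, fs = 5, window_n = 51)
  expect_equal(f2$data$artifact, 7 * f1$data$artifact, tolerance = 1e-10)
  expect_equal(f2$data$egg, 7 * f1$data$egg, tolerance = 1e-10)
  expect_equal(f2$sigma_e_sq, 49 * f1$sigma_e_sq, tolerance = 1e-10)
})

test_that("below the variance floor the method reduces to local detrending", {
  # heteroscedastic signal: the quiet half sits below the variance floor,
  # where cleaning must equal subtraction of the local mean exactly
  set.seed(39)
  y <- c(rnorm(1000, sd = 5), rnorm(1000, sd = 60))
  fit <- remove_artifacts(y, fs = 5, window_n = 51)
  mom <- local_moments(y, 51)
  low <- mom$local_var <= fit$sigma_e_sq
  expect_gt(mean(low), 0.3)
  expect_identical(fit$data$egg[low], (y - mom$local_mean)[low])
})

test_that("zero input yields zero decomposition", {
  expect_warning(
    fit <- remove_artifacts(rep(0, 200), fs = 5, window_n = 21),
    "degenerate"
  )
  expect_equal(fit$data$artifact, rep(0, 200))
  expect_equal(fit$data$egg, rep(0, 200))
})

test_that("cleaning suppresses bursts relative to plain detrending", {
  sim <- simulate_egg(duration_s = 3600, artifact_count = 8, seed = 37)
  fit <- remove_artifacts(sim, value = observed)
  mom <- local_moments(sim$observed, fit$window_n)
  mask <- sim$artifact_mask
  expect_gt(sum(mask), 0)
  expect_lt(mean(abs(fit$data$egg[mask])),
            mean(abs(sim$observed[mask] - mom$local_mean[mask])))
})

test_that("remove_artifacts validates its input", {
  expect_error(remove_artifacts(rnorm(50), fs = 5, window_n = 101), "shorter")
  expect_error(remove_artifacts(c(rnorm(200), NA), fs = 5, window_n = 21),
               "NA")
  expect_error(remove_artifacts(tibble::tibble(x = rnorm(200)), fs = 5),
               "value")
})

test_that("glance reports the decomposition summary", {
  sim <- simulate_egg(duration_s = 1200, seed = 38)
  fit <- remove_artifacts(sim, value = observed)
  g <- glance(fit)
  expect_equal(g$n, nrow(sim))
  expect_equal(g$window_n, 101L)
  expect_gte(g$sigma_e_sq, 0)
  expect_true(g$artifact_burden >= 0 && g$artifact_burden <= 1)
})
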