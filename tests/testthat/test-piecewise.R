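test_that("the design matrix has the documented structure and term names", {
  # three phases -> 6 columns named after the standard segmented coding
  s3 <- sced_series(1:12, c(1, 2, 1, 2, 4, 5, 6, 7, 3, 2, 1, 0),
                    rep(c("B", "C", "D"), each = 4))
  d3 <- build_design(s3)
  expect_identical(d3$terms, c("Intercept", "Time1", "Phase", "Phase_time2",
                               "Phase2", "Phase2_time3"))
  expect_identical(ncol(d3$X), 6L)
  # two phases of 5/5 starting day 1: indicator and re-zeroed time by hand
  s2 <- sced_series(1:10, c(2, 2, 2, 2, 2, 5, 6, 7, 8, 9),
                    rep(c("A", "B"), each = 5))
  d2 <- build_design(s2)
  expect_identical(unname(d2$X[, "Phase"]), c(rep(0, 5), rep(1, 5)))
  expect_identical(unname(d2$X[, "Phase_time2"]), c(rep(0, 5), 0:4))
  expect_identical(unname(d2$X[, "Time1"]), as.numeric(0:9))
  # a single phase is not segmentable
  expect_sced_error(build_design(sced_series(1:5, 1:5, rep("A", 5))),
                    "one_phase")
  # too few points in a phase
  expect_sced_error(
    build_design(sced_series(1:5, 1:5, c("A", "A", "A", "B", "B"))),
    "phase_too_small")
})

test_that("noiseless piecewise-linear data are recovered exactly", {
  # A: flat at 2 over days 1-5; B: 5 + 1 * (day - 6) over days 6-10.
  # Extrapolated A-line at day 6 is 2, so the level change is 3.
  s <- sced_series(1:10, c(rep(2, 5), 5 + 0:4), rep(c("A", "B"), each = 5))
  fit <- fit_piecewise(s)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[["Intercept"]], 2)
  expect_equal(est[["Time1"]], 0, tolerance = 1e-10)
  expect_equal(est[["Phase"]], 3)
  expect_equal(est[["Phase_time2"]], 1)
  expect_equal(fit$residuals, rep(0, 10), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  expect_identical(fit$df_residual, 10L - 4L)
  # boundary geometry agrees with the indicator coefficient
  seg <- predict_segments(fit)
  expect_equal(seg$boundaries$gap, 3)
  expect_equal(seg$boundaries$extrapolated, 2)
  expect_equal(seg$segments$slope, c(0, 1), tolerance = 1e-10)
})

test_that("a constant series yields zero effects and an undefined R-squared", {
  s <- sced_series(1:10, rep(4, 10), rep(c("A", "B"), each = 5))
  fit <- fit_piecewise(s)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[["Intercept"]], 4)
  expect_equal(unname(est[-1]), rep(0, 3), tolerance = 1e-10)
  expect_true(is.na(fit$r_squared))
  expect_true(is.na(fit$model_p))
})

test_that("one continuous line across both phases gives zero gap and zero trend change", {
  s <- sced_series(1:12, 1 + 0.5 * (0:11), rep(c("A", "B"), each = 6))
  fit <- fit_piecewise(s)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[["Phase"]], 0, tolerance = 1e-10)
  expect_equal(est[["Phase_time2"]], 0, tolerance = 1e-10)
  expect_equal(predict_segments(fit)$boundaries$gap, 0, tolerance = 1e-10)
})

test_that("coefficients agree with a normal-equations oracle on random instances", {
  set.seed(23)
  for (i in 1:50) {
    k <- sample(2:3, 1)
    lens <- sample(4:9, k, replace = TRUE)
    n <- sum(lens)
    s <- sced_series(1:n, rnorm(n, sd = 2), rep(LETTERS[1:k], lens))
    d <- build_design(s)
    fit <- fit_piecewise(s)
    oracle <- bf_ols(d$X, d$y)
    expect_equal(fit$coefficients$estimate, unname(oracle), tolerance = 1e-10)
  }
})

test_that("the joint segmented fit equals per-phase simple regressions", {
  # under the cumulative coding the segmented model is saturated per phase,
  # so each phase's fitted line must match its own simple OLS line
  set.seed(29)
  for (i in 1:20) {
    lens <- sample(5:10, 3, replace = TRUE)
    n <- sum(lens)
    ph <- rep(c("B", "C", "D"), lens)
    s <- sced_series(1:n, rnorm(n, sd = 1.5), ph)
    fit <- fit_piecewise(s)
    seg <- predict_segments(fit)
    for (j in 1:3) {
      lab <- c("B", "C", "D")[j]
      idx <- which(ph == lab)
      sub <- lm(s$value[idx] ~ s$time[idx])
      expect_equal(seg$segments$slope[j], unname(coef(sub)[2]),
                   tolerance = 1e-8)
      start_t <- seg$segments$start_time[j]
      expect_equal(seg$segments$start_value[j],
                   unname(coef(sub)[1] + coef(sub)[2] * start_t),
                   tolerance = 1e-8)
    }
  }
})

test_that("the boundary gap from predicted lines equals the indicator coefficient", {
  set.seed(31)
  for (i in 1:20) {
    lens <- sample(4:8, 3, replace = TRUE)
    n <- sum(lens)
    s <- sced_series(1:n, rnorm(n), rep(c("B", "C", "D"), lens))
    fit <- fit_piecewise(s)
    seg <- predict_segments(fit)
    est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
    expect_equal(seg$boundaries$gap, unname(est[c("Phase", "Phase2")]),
                 tolerance = 1e-10)
  }
})

test_that("estimates recover generating values on average under noise", {
  # level shift 3 and slope change 0.4 at the boundary, sd 0.5 noise
  truth <- c(Intercept = 2, Time1 = 0.05, Phase = 3, Phase_time2 = 0.4)
  n_per <- 30L
  reps <- 500L
  t_all <- seq_len(2L * n_per)
  mu <- truth[["Intercept"]] + truth[["Time1"]] * (t_all - 1) +
    ifelse(t_all > n_per, truth[["Phase"]], 0) +
    ifelse(t_all > n_per, truth[["Phase_time2"]] * (t_all - n_per - 1), 0)
  set.seed(37)
  est <- matrix(NA_real_, reps, 4L)
  for (r in seq_len(reps)) {
    s <- sced_series(t_all, mu + rnorm(length(t_all), sd = 0.5),
                     rep(c("A", "B"), each = n_per))
    est[r, ] <- fit_piecewise(s)$coefficients$estimate
  }
  bias <- colMeans(est) - unname(truth)
  mc_se <- apply(est, 2, sd) / sqrt(reps)
  expect_true(all(abs(bias) <= 2.5 * mc_se))
})

test_that("missing scores are dropped but calendar time is kept", {
  v <- c(2, 2, NA, 2, 2, 5, NA, 7, 8, 9)
  s <- sced_series(1:10, v, rep(c("A", "B"), each = 5))
  d <- build_design(s)
  expect_identical(nrow(d$X), 8L)
  expect_identical(d$time, c(1L, 2L, 4L, 5L, 6L, 8L, 9L, 10L))
  # interaction still re-zeroed at the first observation of phase B (day 6)
  expect_identical(unname(d$X[, "Phase_time2"]), c(0, 0, 0, 0, 0, 2, 3, 4))
})
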