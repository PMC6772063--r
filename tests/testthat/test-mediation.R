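# Deterministic construction of a textbook mediation dataset: the mediator
# jumps at the boundary and the outcome follows it with a lag, with mild
# pseudo-noise so that tests have variance to work with.
strong_mediation_ds <- function(seed = 7, n1 = 20L, n2 = 20L) {
  cfg <- synth_config(phase_lengths = c(n1, n2), a_level = 3, b = -0.6,
                      lag = 2L, sd_m = 0.5, sd_y = 0.5,
                      phi_m = 0.2, phi_y = 0.2, outcome_base = c(7, 0))
  generate_sced(cfg, seed = seed)
}

test_that("the a path is detected when the mediator shifts in the hypothesized direction", {
  ds <- strong_mediation_ds()
  a <- evaluate_a_path(ds)
  expect_s3_class(a, "path_evidence")
  expect_true(a$significant)
  expect_identical(a$path, "a")
  expect_true(all(c("tau_between_level", "piecewise_level_change",
                    "piecewise_trend_change") %in% a$tests$test))
})

test_that("an effect opposite to the hypothesized direction never counts as support", {
  cfg <- synth_config(phase_lengths = c(20L, 20L), a_level = 3, sd_m = 0.3,
                      sd_y = 0.3)
  ds <- generate_sced(cfg, seed = 11)
  # flip the declared direction: the (strong) upward shift is now 'wrong way'
  ds$hypothesized_direction[["mediator"]] <- -1
  a <- evaluate_a_path(ds)
  expect_true(any(a$tests$p_value < 0.05))  # small p-values exist...
  expect_false(a$significant)               # ...but the gate blocks them
})

test_that("the b path distinguishes leading from concurrent support", {
  ds <- strong_mediation_ds()
  b <- evaluate_b_path(ds, reps = 500, seed = 3)
  expect_true(b$significant)
  expect_true(b$support %in% c("leading", "concurrent"))
  expect_true(all(b$crosslag$p_adjusted >= b$crosslag$p, na.rm = TRUE))
  # only lags <= 0 enter the evidence table
  expect_true(all(grepl("lag_[-+]", b$tests$test)))
  expect_identical(nrow(b$tests), 6L)
})

test_that("a flat mediator gives no precedence support and no verdict", {
  cfg <- synth_config(phase_lengths = c(20L, 20L), a_level = 0, b = 0,
                      sd_m = 0.5, sd_y = 0.5)
  ds <- generate_sced(cfg, seed = 1)
  # force an outcome change without any mediator involvement
  ds$outcome$value[21:40] <- ds$outcome$value[21:40] - 4
  ev <- mediation_report(ds, reps = 300, seed = 5)
  expect_false(ev$a$significant)
  expect_identical(ev$temporal_precedence, "not_supported")
  expect_identical(ev$verdict, "no_evidence")
})

test_that("the precedence rules follow their definitions on constructed evidence", {
  path_ev <- function(path, tests, alpha = 0.05) {
    structure(list(path = path, tests = tests,
                   significant = any(tests$p_value < alpha & tests$direction_ok),
                   alpha = alpha),
              class = "path_evidence")
  }
  a_sig <- path_ev("a", data.frame(
    test = c("tau_between_level", "piecewise_level_change",
             "piecewise_trend_change"),
    statistic = c(0.7, 3, 0.1), p_value = c(0.001, 0.002, 0.3),
    direction_ok = TRUE))
  a_flat <- path_ev("a", data.frame(
    test = "tau_between_level", statistic = 0.1, p_value = 0.6,
    direction_ok = TRUE))
  c_gradual <- path_ev("c", data.frame(
    test = c("piecewise_level_change", "piecewise_trend_change"),
    statistic = c(0.2, -0.4), p_value = c(0.5, 0.01), direction_ok = TRUE))
  c_immediate <- path_ev("c", data.frame(
    test = c("piecewise_level_change", "piecewise_trend_change"),
    statistic = c(-2, -0.4), p_value = c(0.01, 0.01), direction_ok = TRUE))
  b_lead <- path_ev("b", data.frame(
    test = c("crosslag_lag_-2", "crosslag_lag_-1", "crosslag_lag_+0"),
    statistic = c(-0.5, -0.45, -0.4), p_value = c(0.01, 0.02, 0.03),
    direction_ok = TRUE))
  b_lead$support <- "leading"; b_lead$significant_lags <- c(-2L, -1L)
  b_lag0 <- path_ev("b", data.frame(
    test = "crosslag_lag_+0", statistic = -0.5, p_value = 0.01,
    direction_ok = TRUE))
  b_lag0$support <- "concurrent"; b_lag0$significant_lags <- 0L
  b_gap <- b_lead
  b_gap$significant_lags <- c(-4L, -3L)   # non-contiguous with lag 0
  b_none <- path_ev("b", data.frame(
    test = "crosslag_lag_+0", statistic = 0.1, p_value = 0.8,
    direction_ok = TRUE))
  b_none$support <- "none"; b_none$significant_lags <- integer(0)

  # mediator shifts, outcome change gradual, contiguous leading lags
  expect_identical(
    assess_temporal_precedence(a_sig, c_gradual, b_lead)$flag, "supported")
  # only lag 0 supports, outcome change immediate: caveat
  expect_identical(
    assess_temporal_precedence(a_sig, c_immediate, b_lag0)$flag,
    "supported_with_caveats")
  # significant leading lags not contiguous with lag 0: caveat
  expect_identical(
    assess_temporal_precedence(a_sig, c_immediate, b_gap)$flag,
    "supported_with_caveats")
  # outcome changes while the mediator is flat
  expect_identical(
    assess_temporal_precedence(a_flat, c_immediate, b_none)$flag,
    "not_supported")
  # mediator significant but nothing ties it to the outcome's timing
  expect_identical(
    assess_temporal_precedence(a_sig, c_immediate, b_none)$flag,
    "not_supported")
})

test_that("a significant c path is reported but never gates the verdict", {
  ds <- strong_mediation_ds()
  ev <- mediation_report(ds, reps = 500, seed = 13)
  expect_identical(ev$verdict, "consistent_with_mediation")
  # neutralize the outcome's phase effect but keep the lagged coupling weakly:
  # verdict logic must not consult c-significance at all
  ev2 <- ev
  ev2$c$significant <- FALSE
  expect_identical(ev2$verdict, "consistent_with_mediation")
})

test_that("single-phase datasets are refused", {
  m <- sced_series(1:10, rnorm(10), rep("B", 10))
  ds <- sced_dataset(m, m)
  expect_sced_error(mediation_report(ds, reps = 300, seed = 1), "one_phase")
})

test_that("an infeasible b path yields an inconclusive verdict, not a crash", {
  # phases large enough for tau/piecewise but too short for max_lag = 5 lags
  cfg <- synth_config(phase_lengths = c(4L, 4L), sd_m = 0.5, sd_y = 0.5,
                      a_level = 3)
  ds <- generate_sced(cfg, seed = 2)
  ev <- mediation_report(ds, reps = 300, seed = 2, max_lag = 5)
  expect_s3_class(ev$b, "error")
  expect_identical(ev$verdict, "inconclusive")
})

test_that("identical configuration and seed give a byte-identical JSON report", {
  ds <- strong_mediation_ds()
  e1 <- mediation_report(ds, reps = 400, seed = 17)
  e2 <- mediation_report(ds, reps = 400, seed = 17)
  j1 <- mediation_report_json(e1)
  j2 <- mediation_report_json(e2)
  expect_identical(as.character(j1), as.character(j2))
  f <- tempfile(fileext = ".json")
  mediation_report_json(e1, f)
  expect_identical(readLines(f), strsplit(as.character(j1), "\n")[[1]])
  unlink(f)
})

test_that("listwise and calendar policies both run end to end on gappy data", {
  cfg <- synth_config(phase_lengths = c(26L, 32L), a_level = 3, b = -0.6,
                      lag = 2L, sd_m = 0.5, sd_y = 0.5,
                      missing_rate = 0.145, outcome_base = c(7, 0))
  ds <- generate_sced(cfg, seed = 23)
  ev_cal <- mediation_report(ds, reps = 300, seed = 23, missing = "calendar")
  ev_lw <- mediation_report(ds, reps = 300, seed = 23, missing = "listwise")
  expect_true(ev_cal$verdict %in%
    c("consistent_with_mediation", "inconclusive", "no_evidence"))
  expect_true(ev_lw$verdict %in%
    c("consistent_with_mediation", "inconclusive", "no_evidence"))
  # listwise compressed the calendar
  expect_identical(ev_lw$config$missing, "listwise")
})
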