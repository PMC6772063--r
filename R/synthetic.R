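# Synthetic SCED mediation datasets with known ground truth.
#
# The generator emulates the kind of data the framework targets: bounded
# daily self-report scores across treatment phases, a phase-linked level
# and/or trend shift in the mediator (the a path), a lagged linear effect of
# the mediator on the outcome (the b path), AR(1) innovations in both
# series, and optional MCAR missingness and discretization to an ordinal
# grid. Defaults mirror a three-phase design with 26/32/14 daily
# observations and ~14.5% missing reports.

#' Configuration for the synthetic SCED generator
#'
#' @param phase_lengths Integer observations per phase (default
#'   `c(26, 32, 14)`), labelled B, C, D, ... in order.
#' @param mediator_base Length-2 numeric `c(level, slope)` of the mediator
#'   before intervention onset.
#' @param a_level Immediate mediator level shift at intervention onset
#'   (first day of the second phase).
#' @param a_trend Mediator slope change at onset (per day).
#' @param b Mediator-to-outcome coefficient; its sign sets the hypothesized
#'   direction of the b path.
#' @param lag Days by which the mediator leads the outcome (>= 0).
#' @param outcome_base Length-2 numeric `c(level, slope)` of the outcome.
#' @param phi_m,phi_y AR(1) coefficients of the innovation processes, in
#'   \[0, 1).
#' @param sd_m,sd_y Innovation standard deviations (>= 0).
#' @param missing_rate MCAR missingness fraction in \[0, 0.5\].
#' @param discretize If `TRUE`, scores are rounded to the even-integer grid
#'   0, 2, 4, 6, 8 after generation (off by default: it breaks
#'   exact-recovery checks).
#' @param withdrawal If `TRUE`, the a-path level and trend effects are
#'   reversed from the first day of the last phase, emulating treatment
#'   withdrawal in a follow-up phase.
#' @param phase_names Optional phase labels.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(phase_lengths = c(26L, 32L, 14L),
                         mediator_base = c(3, 0),
                         a_level = 0, a_trend = 0,
                         b = 0, lag = 0L,
                         outcome_base = c(5, 0),
                         phi_m = 0.3, phi_y = 0.3,
                         sd_m = 1, sd_y = 1,
                         missing_rate = 0,
                         discretize = FALSE,
                         withdrawal = FALSE,
                         phase_names = NULL) {
  phase_lengths <- as.integer(phase_lengths)
  if (length(phase_lengths) < 2L || any(phase_lengths < 3L))
    sced_abort("need >= 2 phases of >= 3 observations each", "bad_config")
  if (abs(phi_m) >= 1 || abs(phi_y) >= 1)
    sced_abort("AR(1) coefficients must satisfy |phi| < 1", "bad_config")
  lag <- as.integer(lag)
  if (lag < 0L || lag >= min(phase_lengths))
    sced_abort("lag must be >= 0 and smaller than the shortest phase",
               "bad_config")
  if (sd_m < 0 || sd_y < 0)
    sced_abort("innovation sds must be non-negative", "bad_config")
  if (missing_rate < 0 || missing_rate > 0.5)
    sced_abort("missing_rate must be in [0, 0.5]", "bad_config")
  if (is.null(phase_names)) phase_names <- LETTERS[1 + seq_along(phase_lengths)]
  if (length(phase_names) != length(phase_lengths))
    sced_abort("phase_names must match phase_lengths", "bad_config")
  structure(list(phase_lengths = phase_lengths,
                 mediator_base = mediator_base,
                 a_level = a_level, a_trend = a_trend, b = b, lag = lag,
                 outcome_base = outcome_base,
                 phi_m = phi_m, phi_y = phi_y, sd_m = sd_m, sd_y = sd_y,
                 missing_rate = missing_rate, discretize = discretize,
                 withdrawal = withdrawal, phase_names = phase_names),
            class = "synth_config")
}

#' @noRd
ar1_noise <- function(n, phi, sd) {
  if (sd == 0) return(rep(0, n))
  e <- stats::rnorm(n, sd = sd)
  if (phi != 0) {
    e[1L] <- e[1L] / sqrt(1 - phi^2)
    for (t in 2:n) e[t] <- phi * e[t - 1L] + e[t]
  }
  e
}

#' Generate a synthetic SCED mediation dataset
#'
#' The mediator follows
#' `M_t = mu_M + slope_M * t + a_level * I(t >= onset) +
#'   a_trend * (t - onset) * I(t >= onset) + AR(1) noise`,
#' where the onset is the first day of the second phase (with `withdrawal`,
#' both a-terms are reversed from the first day of the last phase). The
#' outcome follows `Y_t = mu_Y + slope_Y * t + b * M_(t - lag) + AR(1)
#' noise`; the mediator process is extended `lag` days before day 1 so the
#' lagged term is defined for every t. Missingness and discretization are
#' applied last. The returned dataset carries the noiseless trajectories as
#' ground truth.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer RNG seed; generation is deterministic given the seed.
#' @return A `sced_dataset` with attribute `"ground_truth"`: list with the
#'   config, `onset` day, `m_true` and `y_true` (noiseless trajectories) and
#'   the hypothesized directions implied by the effect signs.
#' @examples
#' cfg <- synth_config(phase_lengths = c(10, 10), a_level = 3, sd_m = 0,
#'                     sd_y = 0)
#' ds <- generate_sced(cfg, seed = 1)
#' @export
generate_sced <- function(cfg, seed) {
  if (!inherits(cfg, "synth_config")) cfg <- do.call(synth_config, cfg)
  if (missing(seed)) sced_abort("seed is required", "bad_config")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  n <- sum(cfg$phase_lengths)
  phase <- rep(cfg$phase_names, cfg$phase_lengths)
  onset <- cfg$phase_lengths[1L] + 1L
  withdraw_at <- if (cfg$withdrawal) {
    n - cfg$phase_lengths[length(cfg$phase_lengths)] + 1L
  } else Inf

  # mediator over extended time 1-lag .. n so M_(t-lag) exists for t = 1
  t_ext <- seq.int(1L - cfg$lag, n)
  a_on <- as.numeric(t_ext >= onset & t_ext < withdraw_at)
  a_off <- as.numeric(t_ext >= withdraw_at)
  m_true_ext <- cfg$mediator_base[1L] + cfg$mediator_base[2L] * t_ext +
    cfg$a_level * a_on + cfg$a_trend * (t_ext - onset) * a_on
  if (is.finite(withdraw_at)) {
    # withdrawal: start from the level reached at the end of the treatment
    # phase, drop the level effect, and reverse the trend effect
    reached <- cfg$a_trend * (withdraw_at - 1L - onset)
    m_true_ext <- m_true_ext +
      (reached - cfg$a_trend * (t_ext - withdraw_at)) * a_off
  }
  m_ext <- m_true_ext + ar1_noise(length(t_ext), cfg$phi_m, cfg$sd_m)
  keep <- t_ext >= 1L
  m <- m_ext[keep]
  m_true <- m_true_ext[keep]

  tt <- seq_len(n)
  m_lagged <- m_ext[match(tt - cfg$lag, t_ext)]
  m_true_lagged <- m_true_ext[match(tt - cfg$lag, t_ext)]
  y_true <- cfg$outcome_base[1L] + cfg$outcome_base[2L] * tt +
    cfg$b * m_true_lagged
  y <- cfg$outcome_base[1L] + cfg$outcome_base[2L] * tt +
    cfg$b * m_lagged + ar1_noise(n, cfg$phi_y, cfg$sd_y)

  bounds <- NULL
  if (cfg$discretize) {
    grid <- c(0, 2, 4, 6, 8)
    snap <- function(v) grid[pmax(1L, pmin(5L, round(v / 2) + 1L))]
    m <- snap(m); y <- snap(y)
    bounds <- c(0, 8)
  }

  dir_m <- if (cfg$a_level != 0 || cfg$a_trend != 0) {
    sign(if (cfg$a_level != 0) cfg$a_level else cfg$a_trend)
  } else 1
  dir_y <- if (cfg$b != 0) sign(cfg$b) * dir_m else -1
  ds <- sced_dataset(
    sced_series(tt, m, phase, bounds),
    sced_series(tt, y, phase, bounds),
    hypothesized_direction = c(mediator = dir_m, outcome = dir_y)
  )
  if (cfg$missing_rate > 0) {
    ds <- inject_missingness(ds, cfg$missing_rate,
                             seed = (as.numeric(seed) + 1) %% 2147483647)
  }
  attr(ds, "ground_truth") <- list(config = cfg, onset = onset,
                                   withdraw_at = withdraw_at,
                                   m_true = m_true, y_true = y_true)
  ds
}

#' Inject MCAR missingness into a dataset
#'
#' Marks `round(rate * n)` time points missing, by default on both
#' variables, never leaving any phase with fewer than 3 complete
#' observations.
#'
#' @param ds A `sced_dataset`.
#' @param rate Fraction of time points to mark missing, in \[0, 0.5\].
#' @param seed Integer RNG seed.
#' @param which `"both"` (the whole day is missing) or `"either"` (each
#'   selected day loses one variable at random).
#' @return The dataset with missing markers added.
#' @export
inject_missingness <- function(ds, rate, seed, which = c("both", "either")) {
  which <- match.arg(which)
  if (rate < 0 || rate > 0.5)
    sced_abort("rate must be in [0, 0.5]", "bad_config")
  if (rate == 0) return(ds)
  n <- nrow(ds$mediator)
  n_miss <- round(rate * n)
  if (n_miss == 0L) return(ds)
  ph <- ds$mediator$phase
  complete <- !is.na(ds$mediator$value) & !is.na(ds$outcome$value)
  labs <- unique(ph)
  # feasibility: every phase must retain >= 3 complete days
  max_per_phase <- vapply(labs, function(l) max(0L, sum(complete & ph == l) - 3L),
                          integer(1))
  if (n_miss > sum(max_per_phase))
    sced_abort("cannot satisfy missing rate while keeping 3 complete points per phase",
               "bad_config")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  # sample days one at a time, respecting the per-phase floor
  budget <- stats::setNames(max_per_phase, labs)
  chosen <- integer(0)
  candidates <- which(complete)
  for (i in seq_len(n_miss)) {
    pool <- candidates[budget[ph[candidates]] > 0L]
    pool <- setdiff(pool, chosen)
    pick <- if (length(pool) == 1L) pool else sample(pool, 1L)
    chosen <- c(chosen, pick)
    budget[ph[pick]] <- budget[ph[pick]] - 1L
  }
  if (which == "both") {
    ds$mediator$value[chosen] <- NA_real_
    ds$outcome$value[chosen] <- NA_real_
  } else {
    side <- sample(c("m", "y"), length(chosen), replace = TRUE)
    ds$mediator$value[chosen[side == "m"]] <- NA_real_
    ds$outcome$value[chosen[side == "y"]] <- NA_real_
  }
  ds
}

#' Operating characteristics over a grid of effect sizes
#'
#' Repeatedly generates datasets for every combination of `a_level` and `b`
#' values, runs the a-path, b-path and joint-verdict analyses on each, and
#' tabulates rejection/detection rates with binomial Monte-Carlo standard
#' errors.
#'
#' @param a_levels,b_values Numeric grids for the mediator level shift and
#'   the mediator-to-outcome coefficient.
#' @param cfg Base [synth_config()] whose other fields define the scenario.
#' @param reps Replicates per cell (>= 100).
#' @param alpha Significance level.
#' @param seed Integer seed; replicate r in cell (i, j) uses a seed derived
#'   deterministically from it.
#' @param surrogate_reps Surrogate pairs per b-path test (kept modest so
#'   grids finish quickly).
#' @param max_lag Maximum lag for the b path.
#' @return Data frame with one row per cell: `a_level`, `b`, `rate_a`,
#'   `rate_b`, `rate_joint`, their MC standard errors, and `reps`.
#' @export
simulate_operating_characteristics <- function(a_levels, b_values, cfg = synth_config(),
                                               reps = 200L, alpha = 0.05,
                                               seed = 1L,
                                               surrogate_reps = 300L,
                                               max_lag = 5L) {
  reps <- as.integer(reps)
  if (reps < 100L) sced_abort("reps must be >= 100", "bad_config")
  grid <- expand.grid(a_level = a_levels, b = b_values,
                      KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg_g <- cfg
    cfg_g$a_level <- grid$a_level[g]
    cfg_g$b <- grid$b[g]
    hits <- matrix(FALSE, nrow = reps, ncol = 3L,
                   dimnames = list(NULL, c("a", "b", "joint")))
    for (r in seq_len(reps)) {
      # derive in double precision: integer arithmetic would overflow
      rep_seed <- (as.numeric(seed) * 10000 + g * 1000 + r) %% 2147483647
      ds <- generate_sced(cfg_g, seed = rep_seed)
      ev <- mediation_report(ds, alpha = alpha, max_lag = max_lag,
                             reps = surrogate_reps, seed = rep_seed)
      hits[r, "a"] <- ev$a$significant
      hits[r, "b"] <- ev$b$significant
      hits[r, "joint"] <- identical(ev$verdict, "consistent_with_mediation")
    }
    rate <- colMeans(hits)
    out[[g]] <- data.frame(a_level = grid$a_level[g], b = grid$b[g],
                           rate_a = rate[["a"]], rate_b = rate[["b"]],
                           rate_joint = rate[["joint"]],
                           se_a = sqrt(rate[["a"]] * (1 - rate[["a"]]) / reps),
                           se_b = sqrt(rate[["b"]] * (1 - rate[["b"]]) / reps),
                           se_joint = sqrt(rate[["joint"]] * (1 - rate[["joint"]]) / reps),
                           reps = reps)
  }
  do.call(rbind, out)
}
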