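# Cross-lagged correlations between mediator and outcome.
#
# Lag convention: a NEGATIVE lag k means the mediator leads — each outcome
# score at day t is paired with the mediator score k days earlier
# (lag -1: outcome today vs mediator yesterday). A positive lag pairs the
# mediator at day t with the outcome |k| days earlier (outcome leads).
# Pairing is by calendar day, so days missing on either side simply drop
# the affected pairs; listwise-compressed datasets pair by compressed index.

#' Lagged mediator/outcome value pairs
#'
#' @param m,y `sced_series` on a shared time index.
#' @param lag Integer lag; negative = mediator leads.
#' @return List with `m`, `y` (paired non-missing values), `n`, and
#'   `time` (the day of the outcome-side member of each pair).
#' @examples
#' m <- sced_series(1:10, 1:10, rep("B", 10))
#' y <- sced_series(1:10, c(0, 0, 1:8), rep("B", 10))
#' lagged_pairs(m, y, -2)$n  # 8 pairs (m1,y3)...(m8,y10)
#' @export
lagged_pairs <- function(m, y, lag) {
  if (!identical(m$time, y$time))
    sced_abort("series must share the same time index", "index_mismatch")
  lag <- as.integer(lag)
  if (abs(lag) >= nrow(m))
    sced_abort("lag magnitude must be smaller than the series length",
               "bad_lag")
  # pair m at day t with y at day t - lag
  y_day <- m$time - lag
  idx <- match(y_day, y$time)
  ok <- !is.na(idx) & !is.na(m$value) & !is.na(y$value[idx])
  list(m = m$value[ok], y = y$value[idx[ok]], n = sum(ok),
       time = y_day[ok])
}

#' Cross-lagged Pearson correlations
#'
#' Computes the Pearson correlation between mediator and outcome at every
#' lag from `-max_lag` to `+max_lag`, using pairwise-complete observations
#' paired by calendar day. Negative lags mean the mediator leads (see
#' [lagged_pairs()]). Lags with fewer than `min_pairs` usable pairs, or with
#' zero variance on either side, get `NA` correlations and are reported as
#' not evaluable rather than failing the whole analysis.
#'
#' @param m,y `sced_series` on a shared time index.
#' @param max_lag Maximum lag in days (default 5).
#' @param min_pairs Minimum usable pairs per lag (default 5).
#' @return An object of class `crosslag_result`: list with `lags`, `r`, `n`,
#'   and empty significance slots to be filled by [surrogate_p_values()].
#' @examples
#' m <- sced_series(1:20, sin(1:20), rep("B", 20))
#' y <- sced_series(1:20, c(0, 0, sin(1:18)), rep("B", 20))
#' cross_lagged_correlations(m, y)$r  # r = 1 at lag -2
#' @export
cross_lagged_correlations <- function(m, y, max_lag = 5L, min_pairs = 5L) {
  max_lag <- as.integer(max_lag)
  n_usable <- sum(!is.na(m$value) & !is.na(y$value))
  if (n_usable < max_lag + 5L)
    sced_abort(sprintf(
      "need at least max_lag + 5 = %d complete observations, have %d",
      max_lag + 5L, n_usable), "too_short")
  lags <- seq.int(-max_lag, max_lag)
  r <- n <- rep(NA_real_, length(lags))
  for (i in seq_along(lags)) {
    pr <- lagged_pairs(m, y, lags[i])
    n[i] <- pr$n
    if (pr$n >= min_pairs &&
        stats::var(pr$m) > 0 && stats::var(pr$y) > 0) {
      r[i] <- stats::cor(pr$m, pr$y)
    }
  }
  structure(list(lags = lags, r = r, n = as.integer(n),
                 p = rep(NA_real_, length(lags)),
                 p_adjusted = rep(NA_real_, length(lags)),
                 method = NA_character_, reps = NA_integer_,
                 seed = NA_integer_,
                 phi = c(m = NA_real_, y = NA_real_)),
            class = "crosslag_result")
}

#' @export
print.crosslag_result <- function(x, ...) {
  cat("<crosslag_result>\n")
  df <- data.frame(lag = x$lags, r = round(x$r, 3), n = x$n,
                   p = signif(x$p, 3), p_adj = signif(x$p_adjusted, 3))
  print(df, row.names = FALSE)
  if (!is.na(x$method))
    cat(sprintf("significance: %s, %d surrogate pairs, seed %d, phi_m=%.2f phi_y=%.2f\n",
                x$method, x$reps, x$seed, x$phi[["m"]], x$phi[["y"]]))
  invisible(x)
}

#' @noRd
lag1_autocorrelation <- function(s) {
  # correlation of scores on consecutive calendar days, both observed
  idx <- match(s$time + 1L, s$time)
  ok <- !is.na(idx) & !is.na(s$value) & !is.na(s$value[idx])
  if (sum(ok) < 3L) return(0)
  x0 <- s$value[ok]; x1 <- s$value[idx[ok]]
  if (stats::var(x0) == 0 || stats::var(x1) == 0) return(0)
  max(-0.95, min(0.95, stats::cor(x0, x1)))
}

#' Monte-Carlo surrogate significance for cross-lagged correlations
#'
#' Observed daily series are autocorrelated, so the classical independence-
#' based p-value for a Pearson correlation is anticonservative. Instead, the
#' null distribution is built by simulation: a lag-1 autocorrelation is
#' estimated for each observed series, and `reps` independent pairs of
#' Gaussian AR(1) surrogate series with matching lengths, autocorrelations
#' and missingness patterns are generated. The per-lag two-sided p-value is
#' the proportion of surrogate pairs whose |r| at that lag reaches the
#' observed |r| (with the +1 adjustment `(b + 1) / (reps + 1)`). Because up
#' to `2 * max_lag + 1` lags are examined, a max-statistic adjusted p-value
#' is also reported: the observed |r| is compared against the null
#' distribution of the maximum |r| over all evaluable lags, controlling the
#' family-wise error across lags.
#'
#' @param m,y The `sced_series` the correlations were computed from.
#' @param result A `crosslag_result` from [cross_lagged_correlations()].
#' @param reps Number of surrogate pairs (>= 100; default 5000).
#' @param seed Integer RNG seed; results are bit-identical for a fixed seed.
#' @return `result` with `p`, `p_adjusted`, `method`, `reps`, `seed`, `phi`
#'   filled in.
#' @export
surrogate_p_values <- function(m, y, result, reps = 5000L, seed) {
  reps <- as.integer(reps)
  if (reps < 100L)
    sced_abort("reps must be at least 100", "bad_config")
  if (missing(seed) || is.null(seed))
    sced_abort("an integer seed is required for reproducibility", "bad_config")
  phi_m <- lag1_autocorrelation(m)
  phi_y <- lag1_autocorrelation(y)

  # simulate on the full calendar grid, then mask to the observed pattern
  days <- seq.int(min(m$time), max(m$time))
  t_len <- length(days)
  pos <- match(m$time, days)
  mask_m <- rep(FALSE, t_len); mask_m[pos[!is.na(m$value)]] <- TRUE
  mask_y <- rep(FALSE, t_len); mask_y[pos[!is.na(y$value)]] <- TRUE

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  M <- ar1_matrix(t_len, reps, phi_m)
  Y <- ar1_matrix(t_len, reps, phi_y)

  eval_lags <- which(!is.na(result$r))
  r_null <- matrix(NA_real_, nrow = reps, ncol = length(result$lags))
  for (i in eval_lags) {
    k <- result$lags[i]
    # pair m at day t with y at day t - k
    t_m <- which(mask_m)
    t_y <- t_m - k
    ok <- t_y >= 1L & t_y <= t_len
    t_m <- t_m[ok]; t_y <- t_y[ok]
    ok <- mask_y[t_y]
    t_m <- t_m[ok]; t_y <- t_y[ok]
    r_null[, i] <- colwise_cor(M[t_m, , drop = FALSE], Y[t_y, , drop = FALSE])
  }
  p <- rep(NA_real_, length(result$lags))
  for (i in eval_lags) {
    p[i] <- (1 + sum(abs(r_null[, i]) >= abs(result$r[i]), na.rm = TRUE)) /
      (reps + 1)
  }
  max_null <- apply(abs(r_null[, eval_lags, drop = FALSE]), 1L, max,
                    na.rm = TRUE)
  p_adj <- rep(NA_real_, length(result$lags))
  for (i in eval_lags) {
    p_adj[i] <- (1 + sum(max_null >= abs(result$r[i]))) / (reps + 1)
  }
  result$p <- p
  result$p_adjusted <- pmax(p_adj, p)
  result$method <- "monte_carlo"
  result$reps <- reps
  result$seed <- as.integer(seed)
  result$phi <- c(m = phi_m, y = phi_y)
  result
}

#' @noRd
ar1_matrix <- function(t_len, reps, phi) {
  # stationary Gaussian AR(1), unit innovation sd, one column per surrogate
  E <- matrix(stats::rnorm(t_len * reps), nrow = t_len)
  if (phi != 0) {
    E[1L, ] <- E[1L, ] / sqrt(1 - phi^2)
    for (t in 2:t_len) E[t, ] <- phi * E[t - 1L, ] + E[t, ]
  }
  E
}

#' @noRd
colwise_cor <- function(A, B) {
  # Pearson correlation of corresponding columns of A and B
  n <- nrow(A)
  A <- sweep(A, 2L, colMeans(A))
  B <- sweep(B, 2L, colMeans(B))
  num <- colSums(A * B)
  den <- sqrt(colSums(A^2) * colSums(B^2))
  ifelse(den > 0, num / den, NA_real_)
}
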