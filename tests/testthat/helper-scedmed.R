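# Independent brute-force oracles and fixture builders.
# Oracles deliberately use plain double loops / normal equations / hand
# shifting so they share no code path with the implementation.

bf_pair_counts_between <- function(a, b) {
  p <- n <- ties <- 0L
  for (x in a) for (y in b) {
    d <- y - x
    if (d > 0) p <- p + 1L else if (d < 0) n <- n + 1L else ties <- ties + 1L
  }
  list(positives = p, negatives = n, ties = ties, s = p - n,
       n_pairs = p + n + ties)
}

bf_pair_counts_trend <- function(x) {
  p <- n <- ties <- 0L
  for (i in seq_along(x)) for (j in seq_along(x)) {
    if (j <= i) next
    d <- x[j] - x[i]
    if (d > 0) p <- p + 1L else if (d < 0) n <- n + 1L else ties <- ties + 1L
  }
  list(positives = p, negatives = n, ties = ties, s = p - n,
       n_pairs = p + n + ties)
}

bf_ols <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# correlation of hand-shifted complete vectors; negative lag = m leads
bf_lag_cor <- function(m, y, lag) {
  n <- length(m)
  if (lag <= 0) {
    k <- -lag
    mm <- m[seq_len(n - k)]
    yy <- y[seq_len(n - k) + k]
  } else {
    mm <- m[seq_len(n - lag) + lag]
    yy <- y[seq_len(n - lag)]
  }
  stats::cor(mm, yy)
}

two_phase_series <- function(v1, v2, labels = c("B", "C")) {
  sced_series(seq_len(length(v1) + length(v2)), c(v1, v2),
              rep(labels, c(length(v1), length(v2))))
}

random_dataset <- function(seed, n1 = 10L, n2 = 12L) {
  set.seed(seed)
  n <- n1 + n2
  sced_dataset(
    sced_series(1:n, rnorm(n), rep(c("B", "C"), c(n1, n2))),
    sced_series(1:n, rnorm(n), rep(c("B", "C"), c(n1, n2)))
  )
}

expect_sced_error <- function(expr, code) {
  expect_error(expr, class = paste0("scedmed_error_", code))
}
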