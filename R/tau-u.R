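# Tau-U nonoverlap statistics for single-case phase comparisons.
#
# All statistics are built from the Kendall-type S numerator: the number of
# positive pairwise differences minus the number of negative ones. Ties
# contribute 0 to S but stay in the pair-count denominator, so
# tau = S / n_pairs is the "percentage of nonoverlapping pairs".

#' Pairwise difference counts between two phases
#'
#' Forms every pair of one score from the earlier phase and one from the
#' later phase (`length(a) * length(b)` pairs) and counts the sign of
#' (later-phase score - earlier-phase score).
#'
#' @param a Numeric scores of the earlier phase (no missing values).
#' @param b Numeric scores of the later phase.
#' @return An object of class `pair_counts`: list with `positives`,
#'   `negatives`, `ties`, `s` (= positives - negatives) and `n_pairs`.
#' @examples
#' pair_counts_between(c(1, 3, 2), c(2, 4))
#' @export
pair_counts_between <- function(a, b) {
  check_phase_scores(a, "earlier")
  check_phase_scores(b, "later")
  d <- sign(rep(b, each = length(a)) - rep.int(a, length(b)))
  new_pair_counts(sum(d > 0), sum(d < 0), sum(d == 0))
}

#' Pairwise difference counts within one phase (trend)
#'
#' Counts the sign of every forward-in-time difference within a phase:
#' for n scores there are n(n-1)/2 pairs, the difference always taken as
#' later score minus earlier score. The resulting tau is the within-phase
#' monotone trend.
#'
#' @param x Numeric scores of one phase in time order, length >= 2, no
#'   missing values.
#' @return A `pair_counts` object.
#' @examples
#' pair_counts_trend(c(3, 1, 2))
#' @export
pair_counts_trend <- function(x) {
  check_phase_scores(x, "trend")
  n <- length(x)
  if (n < 2L)
    sced_abort("within-phase trend needs at least 2 observations",
               "phase_too_small")
  ij <- utils::combn(n, 2L)
  d <- sign(x[ij[2L, ]] - x[ij[1L, ]])
  new_pair_counts(sum(d > 0), sum(d < 0), sum(d == 0))
}

#' @noRd
check_phase_scores <- function(x, what) {
  if (length(x) == 0L)
    sced_abort(sprintf("empty %s phase", what), "empty_phase")
  if (anyNA(x))
    sced_abort("phase scores must not contain missing values; apply a missing policy first",
               "missing_scores")
  invisible(x)
}

#' @noRd
new_pair_counts <- function(p, n, ties) {
  structure(list(positives = p, negatives = n, ties = ties,
                 s = p - n, n_pairs = p + n + ties),
            class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat(sprintf("<pair_counts> P=%d N=%d ties=%d S=%d over %d pairs\n",
              x$positives, x$negatives, x$ties, x$s, x$n_pairs))
  invisible(x)
}

# Inference -------------------------------------------------------------

#' Normal-approximation inference for a Tau-U statistic
#'
#' Uses the Kendall-type null variance of S: for a between-phase comparison
#' of phases with n_a and n_b scores, S = 2U - n_a n_b where U is the
#' Mann-Whitney statistic, so Var(S) = 4 Var(U) =
#' n_a n_b (n_a + n_b + 1) / 3; for a within-phase trend over n scores,
#' Var(S) = n (n - 1) (2n + 5) / 18. A two-sided normal p-value is computed
#' from z = S / sqrt(Var(S)), and the confidence interval is
#' tau +/- z_crit * sqrt(Var(S)) / n_pairs, truncated to [-1, 1]. No tie
#' correction is applied to the variance.
#'
#' @param counts A `pair_counts` object.
#' @param kind `"between_level"`, `"within_trend"` or `"corrected_between"`.
#' @param n_a,n_b Phase sizes; `n_b` is ignored for `"within_trend"`.
#' @param ci_level Two-sided confidence level (default 0.90).
#' @param var_s Optional override of the null variance of S (used by the
#'   baseline-corrected comparison).
#' @return List with `p_value`, `ci` (length-2 numeric), `z`, `var_s`.
#' @export
tau_inference <- function(counts, kind = c("between_level", "within_trend",
                                           "corrected_between"),
                          n_a, n_b = NULL, ci_level = 0.90, var_s = NULL) {
  kind <- match.arg(kind)
  if (is.null(var_s)) {
    var_s <- switch(kind,
      between_level = ,
      corrected_between = n_a * n_b * (n_a + n_b + 1) / 3,
      within_trend = n_a * (n_a - 1) * (2 * n_a + 5) / 18
    )
  }
  tau <- counts$s / counts$n_pairs
  if (var_s <= 0) {   # degenerate single-pair cases
    return(list(p_value = 1, ci = c(tau, tau), z = 0, var_s = var_s))
  }
  z <- counts$s / sqrt(var_s)
  p <- 2 * stats::pnorm(-abs(z))
  zc <- stats::qnorm(1 - (1 - ci_level) / 2)
  half <- zc * sqrt(var_s) / counts$n_pairs
  ci <- c(max(-1, tau - half), min(1, tau + half))
  list(p_value = p, ci = ci, z = z, var_s = var_s)
}

#' @noRd
new_tau_u <- function(kind, counts, n_a, n_b, ci_level, phases_compared,
                      s_override = NULL, var_s = NULL) {
  s <- if (is.null(s_override)) counts$s else s_override
  tau <- s / counts$n_pairs
  eff_counts <- counts
  eff_counts$s <- s
  inf <- tau_inference(eff_counts, kind, n_a, n_b, ci_level, var_s = var_s)
  structure(list(kind = kind, tau = tau, counts = counts, s = s,
                 p_value = inf$p_value, ci = inf$ci, ci_level = ci_level,
                 z = inf$z, phases_compared = phases_compared),
            class = "tau_u")
}

#' @export
print.tau_u <- function(x, ...) {
  cat(sprintf("<tau_u> %s %s: Tau = %.3f, p = %.3g, %d%% CI [%.3f, %.3f]\n",
              x$kind, paste(x$phases_compared, collapse = " vs "),
              x$tau, x$p_value, round(100 * x$ci_level), x$ci[1], x$ci[2]))
  invisible(x)
}

# User-facing statistics ------------------------------------------------

#' Between-phase level change (Tau-U)
#'
#' Measures the change in level between two phases by nonoverlap:
#' tau = S / (n_a n_b) where S counts positive minus negative pairwise
#' differences (later phase minus earlier phase). tau = 1 means every
#' later-phase score exceeds every earlier-phase score.
#'
#' @param a,b Scores of the earlier and later phase.
#' @param ci_level Confidence level for the interval (default 0.90).
#' @param phases Optional labels of the phases compared.
#' @return A `tau_u` object (kind `"between_level"`).
#' @examples
#' tau_between(c(1, 3, 2), c(2, 4))  # tau = 0.5
#' @export
tau_between <- function(a, b, ci_level = 0.90, phases = c("A", "B")) {
  counts <- pair_counts_between(a, b)
  new_tau_u("between_level", counts, length(a), length(b), ci_level, phases)
}

#' Within-phase trend (Tau-U)
#'
#' @param x Scores of one phase in time order.
#' @param ci_level Confidence level (default 0.90).
#' @param phase Optional phase label.
#' @return A `tau_u` object (kind `"within_trend"`).
#' @examples
#' tau_trend(c(1, 2, 3, 4))  # tau = 1
#' @export
tau_trend <- function(x, ci_level = 0.90, phase = "A") {
  counts <- pair_counts_trend(x)
  new_tau_u("within_trend", counts, length(x), NULL, ci_level, phase)
}

#' Baseline-trend-corrected between-phase level change
#'
#' When the earlier phase already shows a trend toward improvement, the
#' between-phase comparison can reflect that pre-existing trend rather than
#' a phase effect. The corrected statistic subtracts the earlier phase's
#' within-phase trend numerator: S_corr = S_between - S_trend(a), with the
#' denominator kept at n_a n_b. The null variance used for inference is the
#' sum of the two components' variances (their covariance, induced by the
#' shared earlier-phase scores, is ignored; see the methods vignette).
#'
#' @inheritParams tau_between
#' @return A `tau_u` object (kind `"corrected_between"`) whose `counts` are
#'   the uncorrected between-phase counts and whose `s` is the corrected
#'   numerator.
#' @examples
#' tau_between_corrected(c(1, 2, 3), c(4, 5, 6))  # (9 - 3) / 9
#' @export
tau_between_corrected <- function(a, b, ci_level = 0.90, phases = c("A", "B")) {
  if (length(a) < 2L)
    sced_abort("baseline correction needs >= 2 earlier-phase scores",
               "phase_too_small")
  between <- pair_counts_between(a, b)
  trend <- pair_counts_trend(a)
  n_a <- length(a); n_b <- length(b)
  var_s <- n_a * n_b * (n_a + n_b + 1) / 3 +
    n_a * (n_a - 1) * (2 * n_a + 5) / 18
  new_tau_u("corrected_between", between, n_a, n_b, ci_level, phases,
            s_override = between$s - trend$s, var_s = var_s)
}
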