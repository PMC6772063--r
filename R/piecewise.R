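# Piecewise (segmented) phase regression.
#
# One joint OLS fit whose coefficients read directly as: level at the first
# observation of the first phase (intercept), trend in the first phase, and,
# for each later phase, the immediate change in level at its first
# observation (relative to the previous segment's extrapolated line) and the
# change in slope at that boundary. The encoding is cumulative: each
# boundary's indicator and re-zeroed time term stay "on" for all subsequent
# phases, so coefficients are changes relative to the previous phase.

#' Build the segmented-regression design matrix for a series
#'
#' For k phases the design has 2k columns: an intercept; global time
#' re-centred at the first observation (`Time1`); and per later phase j a
#' step indicator equal to 1 from the first observation of phase j onward
#' (`Phase`, `Phase2`, ...) and an interaction equal to
#' time - (time of first observation of phase j) from that observation
#' onward, 0 before (`Phase_time2`, `Phase2_time3`, ...). Rows with missing
#' scores are dropped. Under this coding the indicator coefficient is the
#' immediacy estimate: the gap at the boundary between the previous
#' segment's extrapolated line and the new segment's line.
#'
#' @param series A `sced_series` with >= 2 phases and, per phase, >= 3
#'   non-missing observations at >= 2 distinct times.
#' @return An object of class `piecewise_design`: list with `X` (model
#'   matrix), `y`, `time`, `phase`, `terms` (column names), `phase_starts`
#'   (first observed time of each phase).
#' @examples
#' s <- sced_series(1:10, c(2, 2, 2, 2, 2, 5, 6, 7, 8, 9),
#'                  rep(c("A", "B"), each = 5))
#' build_design(s)$terms
#' @export
build_design <- function(series) {
  keep <- !is.na(series$value)
  tm <- series$time[keep]
  y <- series$value[keep]
  ph <- series$phase[keep]
  labs <- rle(ph)$values
  k <- length(labs)
  if (k < 2L)
    sced_abort("piecewise regression needs at least two phases", "one_phase")
  n_ph <- vapply(labs, function(l) sum(ph == l), integer(1))
  t_distinct <- vapply(labs, function(l) length(unique(tm[ph == l])), integer(1))
  if (any(n_ph < 3L) || any(t_distinct < 2L))
    sced_abort(sprintf(
      "phase %s has too few usable observations for piecewise regression",
      paste(labs[n_ph < 3L | t_distinct < 2L], collapse = ", ")),
      "phase_too_small")
  starts <- vapply(labs, function(l) min(tm[ph == l]), numeric(1))
  X <- cbind(Intercept = rep(1, length(y)), Time1 = tm - starts[1])
  term_names <- c("Intercept", "Time1")
  for (j in seq_len(k - 1L)) {
    on <- as.numeric(tm >= starts[j + 1L])
    ind_name <- if (j == 1L) "Phase" else paste0("Phase", j)
    int_name <- if (j == 1L) "Phase_time2" else paste0("Phase", j, "_time", j + 1L)
    X <- cbind(X, on, on * (tm - starts[j + 1L]))
    term_names <- c(term_names, ind_name, int_name)
  }
  colnames(X) <- term_names
  if (qr(X)$rank < ncol(X))
    sced_abort("design matrix is rank deficient (collinear phase terms)",
               "rank_deficient")
  structure(list(X = X, y = y, time = tm, phase = ph, terms = term_names,
                 phase_starts = stats::setNames(starts, labs)),
            class = "piecewise_design")
}

#' Fit the piecewise phase regression
#'
#' Ordinary least squares on the design of [build_design()], with classical
#' (homoskedastic, independence-assuming) standard errors, two-sided
#' t-tests, R-squared and the model F-test. Residual autocorrelation is not
#' corrected for; see the methods vignette for the consequences.
#'
#' @param series A `sced_series`.
#' @return An object of class `piecewise_fit`: list with `coefficients`
#'   (data frame: term, estimate, se, t_value, p_value), `r_squared`,
#'   `model_p`, `fitted`, `residuals`, `df_residual`, `design`, and the
#'   underlying `lm` object as `fit`.
#' @examples
#' s <- sced_series(1:10, c(2, 2, 2, 2, 2, 5, 6, 7, 8, 9),
#'                  rep(c("A", "B"), each = 5))
#' fit_piecewise(s)
#' @export
fit_piecewise <- function(series) {
  design <- build_design(series)
  df <- as.data.frame(design$X[, -1L, drop = FALSE])
  df$.y <- design$y
  fit <- stats::lm(.y ~ ., data = df)
  # noiseless piecewise-linear inputs are a legitimate (tested) use case;
  # keep summary.lm's perfect-fit warning from leaking out of them
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  co <- sm$coefficients
  coefs <- data.frame(
    term = design$terms,
    estimate = unname(co[, 1L]),
    se = unname(co[, 2L]),
    t_value = unname(co[, 3L]),
    p_value = unname(co[, 4L]),
    stringsAsFactors = FALSE
  )
  # model F-test; undefined when the response has zero variance
  if (stats::var(design$y) == 0) {
    r2 <- NA_real_
    model_p <- NA_real_
  } else {
    r2 <- sm$r.squared
    f <- sm$fstatistic
    model_p <- unname(stats::pf(f[1L], f[2L], f[3L], lower.tail = FALSE))
  }
  structure(list(coefficients = coefs, r_squared = r2, model_p = model_p,
                 fitted = unname(stats::fitted(fit)),
                 residuals = unname(stats::residuals(fit)),
                 df_residual = fit$df.residual,
                 design = design, fit = fit),
            class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, digits = 3, ...) {
  cat("<piecewise_fit>\n")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  if (is.na(x$r_squared)) {
    cat("R-squared undefined (response has zero variance)\n")
  } else {
    cat(sprintf("R-squared = %.3f, model p = %.3g (df = %d)\n",
                x$r_squared, x$model_p, x$df_residual))
  }
  invisible(x)
}

#' Per-phase fitted lines and boundary level-change segments
#'
#' Converts the joint fit's coefficients into one (start value, slope) pair
#' per phase, plus, per boundary, the vertical gap at the first observation
#' of the new phase between the previous segment's extrapolated line and the
#' new line. Under the design's coding this gap equals the corresponding
#' indicator coefficient exactly.
#'
#' @param fit A `piecewise_fit`.
#' @return List with `segments` (data frame: phase, start_time, start_value,
#'   slope) and `boundaries` (data frame: phase, time, gap, extrapolated,
#'   observed_line).
#' @export
predict_segments <- function(fit) {
  design <- fit$design
  b <- fit$coefficients$estimate
  starts <- design$phase_starts
  labs <- names(starts)
  k <- length(labs)
  slope <- cumsum(c(b[2L], if (k > 1L) b[seq(4L, 2L * k, by = 2L)]))
  line_at <- function(j, t) {
    # fitted value of segment j's line at time t (extrapolated if needed)
    v <- b[1L] + b[2L] * (t - starts[1L])
    if (j > 1L) for (i in seq_len(j - 1L)) {
      v <- v + b[2L * i + 1L] + b[2L * i + 2L] * (t - starts[i + 1L])
    }
    v
  }
  segments <- data.frame(
    phase = labs,
    start_time = unname(starts),
    start_value = vapply(seq_len(k), function(j) line_at(j, starts[j]), numeric(1)),
    slope = unname(slope),
    stringsAsFactors = FALSE
  )
  boundaries <- data.frame(
    phase = labs[-1L],
    time = unname(starts[-1L]),
    extrapolated = vapply(seq_len(k - 1L),
                          function(j) line_at(j, starts[j + 1L]), numeric(1)),
    observed_line = vapply(seq_len(k - 1L),
                           function(j) line_at(j + 1L, starts[j + 1L]),
                           numeric(1)),
    stringsAsFactors = FALSE
  )
  boundaries$gap <- boundaries$observed_line - boundaries$extrapolated
  list(segments = segments, boundaries = boundaries)
}
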