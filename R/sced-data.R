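#' scedmed: mediation analysis for single-case experimental designs
#'
#' Tools to test hypothesized mediators of intervention outcomes in
#' single-case experimental designs (SCEDs), where one participant is
#' measured repeatedly across treatment phases. The treatment-to-mediator
#' (a) and treatment-to-outcome (c) paths are quantified with Tau-U
#' nonoverlap statistics ([tau_between()], [tau_trend()],
#' [tau_between_corrected()]) and piecewise phase regression
#' ([fit_piecewise()]); the mediator-to-outcome (b) path is proxied by
#' cross-lagged correlations with Monte-Carlo AR(1) surrogate significance
#' ([cross_lagged_correlations()], [surrogate_p_values()]). The evidence is
#' combined under a joint-significance rule with temporal-precedence checks
#' by [mediation_report()]. [generate_sced()] produces synthetic datasets
#' with known ground truth.
#'
#' @keywords internal
"_PACKAGE"

# Conditions ------------------------------------------------------------

#' @noRd
sced_abort <- function(message, code, call = sys.call(-1)) {
  stop(errorCondition(
    message,
    class = c(paste0("scedmed_error_", code), "scedmed_error", "error"),
    call = call
  ))
}

# sced_series -----------------------------------------------------------

#' Construct a single-case experimental design series
#'
#' A `sced_series` holds one participant's repeated scores on one variable:
#' an integer time index (study day, strictly increasing, gaps allowed), a
#' phase label per observation, and optionally the bounds of the measurement
#' scale. Missing scores are stored as `NA`.
#'
#' @param time Integer vector of study days, strictly increasing.
#' @param value Numeric scores, `NA` for missing observations.
#' @param phase Character or factor phase labels; must form contiguous
#'   blocks in time order (e.g. all B days before all C days).
#' @param scale_bounds Optional numeric `c(min, max)` of the measurement
#'   scale; non-missing values outside the bounds are rejected.
#'
#' @return An object of class `sced_series`: a data frame with columns
#'   `time`, `value`, `phase` and attribute `scale_bounds`.
#' @examples
#' s <- sced_series(1:6, c(2, 4, 2, 6, 8, 6), rep(c("B", "C"), each = 3))
#' phase_lengths(s)
#' @export
sced_series <- function(time, value, phase, scale_bounds = NULL) {
  if (length(time) != length(value) || length(time) != length(phase))
    sced_abort("time, value and phase must have equal length", "length_mismatch")
  time <- as.integer(time)
  if (anyNA(time))
    sced_abort("time index must be integer with no missing values", "bad_time")
  if (anyDuplicated(time))
    sced_abort(sprintf("duplicate time values: %s",
                       paste(unique(time[duplicated(time)]), collapse = ", ")),
               "duplicate_time")
  if (is.unsorted(time, strictly = TRUE))
    sced_abort("time index must be strictly increasing", "nonmonotone_time")
  phase <- as.character(phase)
  if (anyNA(phase))
    sced_abort("phase labels must not be missing", "bad_phase")
  # phases must be contiguous blocks in time order
  blocks <- rle(phase)$values
  if (anyDuplicated(blocks)) {
    offender <- blocks[duplicated(blocks)][1L]
    bad_times <- time[phase == offender]
    sced_abort(sprintf(
      "non-contiguous phase '%s' (reappears; time points %s)",
      offender, paste(bad_times, collapse = ", ")), "noncontiguous_phase")
  }
  value <- as.numeric(value)
  if (!is.null(scale_bounds)) {
    scale_bounds <- as.numeric(scale_bounds)
    if (length(scale_bounds) != 2L || anyNA(scale_bounds) ||
        scale_bounds[1] >= scale_bounds[2])
      sced_abort("scale_bounds must be c(min, max) with min < max", "bad_bounds")
    oob <- !is.na(value) & (value < scale_bounds[1] | value > scale_bounds[2])
    if (any(oob))
      sced_abort(sprintf("scores out of declared bounds at time %s",
                         paste(time[oob], collapse = ", ")), "out_of_bounds")
  }
  structure(
    data.frame(time = time, value = value, phase = phase,
               stringsAsFactors = FALSE),
    scale_bounds = scale_bounds,
    class = c("sced_series", "data.frame")
  )
}

#' Phase labels of a series, in time order
#' @param x A `sced_series` or `sced_dataset`.
#' @return Character vector of distinct phase labels.
#' @export
phase_labels <- function(x) {
  if (inherits(x, "sced_dataset")) x <- x$mediator
  rle(as.character(x$phase))$values
}

#' Observations per phase
#' @param x A `sced_series` or `sced_dataset`.
#' @param complete If `TRUE`, count only non-missing scores (for a dataset,
#'   rows complete on both variables).
#' @return Named integer vector, one element per phase in time order.
#' @export
phase_lengths <- function(x, complete = FALSE) {
  if (inherits(x, "sced_dataset")) {
    ok <- if (complete) !is.na(x$mediator$value) & !is.na(x$outcome$value)
          else rep(TRUE, nrow(x$mediator))
    ph <- x$mediator$phase
  } else {
    ok <- if (complete) !is.na(x$value) else rep(TRUE, nrow(x))
    ph <- x$phase
  }
  labs <- rle(as.character(ph))$values
  out <- vapply(labs, function(l) sum(ok & ph == l), integer(1))
  out
}

#' @export
print.sced_series <- function(x, ...) {
  cat(sprintf("<sced_series> %d observations, %d missing\n",
              nrow(x), sum(is.na(x$value))))
  pl <- phase_lengths(x)
  cat("  phases:", paste(sprintf("%s (n=%d)", names(pl), pl), collapse = ", "),
      "\n")
  if (!is.null(attr(x, "scale_bounds")))
    cat("  scale bounds:", paste(attr(x, "scale_bounds"), collapse = "-"), "\n")
  invisible(x)
}

# sced_dataset ----------------------------------------------------------

#' Construct a mediator + outcome SCED dataset
#'
#' Bundles the mediator and outcome series of one participant on a shared
#' time index, with design metadata: the phase order and the hypothesized
#' direction of improvement for each variable.
#'
#' @param mediator,outcome `sced_series` objects sharing an identical time
#'   index and phase labelling.
#' @param phase_order Ordered character vector covering every phase label
#'   exactly once; defaults to the observed time order.
#' @param hypothesized_direction Named numeric vector
#'   `c(mediator = +1 or -1, outcome = +1 or -1)`: `+1` means higher scores
#'   indicate improvement (e.g. coping ability), `-1` means lower scores do
#'   (e.g. anxiety symptoms).
#'
#' @return An object of class `sced_dataset`.
#' @examples
#' m <- sced_series(1:10, c(2,3,2,3,2, 5,6,6,7,8), rep(c("B","C"), each = 5))
#' y <- sced_series(1:10, c(6,5,6,5,6, 5,4,4,3,2), rep(c("B","C"), each = 5))
#' sced_dataset(m, y)
#' @export
sced_dataset <- function(mediator, outcome, phase_order = NULL,
                         hypothesized_direction = c(mediator = 1, outcome = -1)) {
  if (!inherits(mediator, "sced_series") || !inherits(outcome, "sced_series"))
    sced_abort("mediator and outcome must be sced_series objects", "bad_type")
  if (!identical(mediator$time, outcome$time))
    sced_abort("mediator and outcome must share the same time index",
               "index_mismatch")
  if (!identical(mediator$phase, outcome$phase))
    sced_abort("mediator and outcome must share the same phase labels",
               "phase_mismatch")
  observed <- phase_labels(mediator)
  if (is.null(phase_order)) phase_order <- observed
  if (!setequal(phase_order, observed) || anyDuplicated(phase_order))
    sced_abort("phase_order must cover every observed phase exactly once",
               "bad_phase_order")
  hd <- hypothesized_direction
  if (!all(c("mediator", "outcome") %in% names(hd)) ||
      !all(hd[c("mediator", "outcome")] %in% c(-1, 1)))
    sced_abort(
      "hypothesized_direction must be c(mediator = +/-1, outcome = +/-1)",
      "bad_direction")
  structure(
    list(mediator = mediator, outcome = outcome,
         phase_order = as.character(phase_order),
         hypothesized_direction = hd[c("mediator", "outcome")]),
    class = "sced_dataset"
  )
}

#' @export
print.sced_dataset <- function(x, ...) {
  pl <- phase_lengths(x)
  plc <- phase_lengths(x, complete = TRUE)
  cat(sprintf("<sced_dataset> %d days, phases %s\n", nrow(x$mediator),
              paste(sprintf("%s (%d obs, %d complete)", names(pl), pl, plc),
                    collapse = ", ")))
  cat(sprintf("  hypothesized improvement: mediator %s, outcome %s\n",
              ifelse(x$hypothesized_direction[["mediator"]] > 0, "up", "down"),
              ifelse(x$hypothesized_direction[["outcome"]] > 0, "up", "down")))
  invisible(x)
}

#' Check that every phase supports analysis
#'
#' Analyses require at least two phases and at least 3 non-missing
#' observations per phase on each variable.
#' @param ds A `sced_dataset`.
#' @param min_per_phase Minimum complete observations required per phase.
#' @return `ds`, invisibly; errors if infeasible.
#' @export
assert_analyzable <- function(ds, min_per_phase = 3L) {
  labs <- phase_labels(ds)
  if (length(labs) < 2L)
    sced_abort("at least two phases are required for analysis", "one_phase")
  for (v in c("mediator", "outcome")) {
    s <- ds[[v]]
    n_ok <- vapply(labs, function(l) sum(!is.na(s$value[s$phase == l])),
                   integer(1))
    if (any(n_ok < min_per_phase))
      sced_abort(sprintf(
        "phase %s has fewer than %d usable %s observations",
        paste(labs[n_ok < min_per_phase], collapse = ", "),
        min_per_phase, v), "phase_too_small")
  }
  invisible(ds)
}

# CSV I/O ---------------------------------------------------------------

#' Read a SCED dataset from long-format CSV
#'
#' Expects one row per study day with a time column, a phase column, and one
#' column each for the mediator and outcome scores. Empty cells or `NA` are
#' read as missing. Rows are sorted by time before validation.
#'
#' @param path Path to a CSV file.
#' @param column_map Named character vector mapping roles to column names:
#'   `c(time = ..., phase = ..., mediator = ..., outcome = ...)`.
#' @param scale_bounds Optional `c(min, max)` applied to both variables.
#' @param phase_order,hypothesized_direction Passed to [sced_dataset()].
#' @return A validated `sced_dataset`.
#' @seealso [write_sced_csv()] for the inverse.
#' @export
read_sced_csv <- function(path,
                          column_map = c(time = "time", phase = "phase",
                                         mediator = "mediator",
                                         outcome = "outcome"),
                          scale_bounds = NULL, phase_order = NULL,
                          hypothesized_direction = c(mediator = 1,
                                                     outcome = -1)) {
  if (!file.exists(path))
    sced_abort(sprintf("file not found: %s", path), "missing_file")
  need <- c("time", "phase", "mediator", "outcome")
  if (!all(need %in% names(column_map)))
    sced_abort("column_map must name time, phase, mediator and outcome columns",
               "bad_column_map")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  absent <- setdiff(unname(column_map[need]), names(df))
  if (length(absent))
    sced_abort(sprintf("columns not found in %s: %s", path,
                       paste(absent, collapse = ", ")), "missing_column")
  df <- df[order(df[[column_map[["time"]]]]), , drop = FALSE]
  tm <- df[[column_map[["time"]]]]
  if (!is.numeric(tm) || any(!is.na(tm) & tm != round(tm)))
    sced_abort("time column must contain integers", "bad_time")
  ph <- df[[column_map[["phase"]]]]
  mediator <- sced_series(tm, df[[column_map[["mediator"]]]], ph, scale_bounds)
  outcome  <- sced_series(tm, df[[column_map[["outcome"]]]],  ph, scale_bounds)
  sced_dataset(mediator, outcome, phase_order, hypothesized_direction)
}

#' Write a SCED dataset to long-format CSV
#'
#' Missing scores are written as empty cells so that
#' `read_sced_csv(write_sced_csv(ds))` round-trips values, phases and
#' missingness exactly.
#' @param ds A `sced_dataset`.
#' @param path Output file path.
#' @param column_map As in [read_sced_csv()]; controls the column names.
#' @return `path`, invisibly.
#' @export
write_sced_csv <- function(ds, path,
                           column_map = c(time = "time", phase = "phase",
                                          mediator = "mediator",
                                          outcome = "outcome")) {
  df <- data.frame(ds$mediator$time, ds$mediator$phase,
                   ds$mediator$value, ds$outcome$value)
  names(df) <- unname(column_map[c("time", "phase", "mediator", "outcome")])
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# Missing-data policy ---------------------------------------------------

#' Apply a missing-data policy to a dataset
#'
#' Two policies are supported. `"listwise"` drops every time point at which
#' either variable is missing and then re-indexes time consecutively
#' (1, 2, ...), compressing the calendar; this reproduces the common
#' practice of deleting missing daily reports before analysis. `"calendar"`
#' (the default elsewhere in the package) keeps all rows: downstream lag
#' operations pair observations by original calendar day and skip incomplete
#' pairs, so the timing of effects is preserved.
#'
#' Listwise deletion can distort the apparent timing of therapy effects;
#' the calendar policy avoids that at the cost of fewer usable pairs per lag.
#'
#' @param ds A `sced_dataset`.
#' @param policy `"listwise"` or `"calendar"`.
#' @return A `sced_dataset`; for `"calendar"`, `ds` unchanged.
#' @examples
#' m <- sced_series(1:6, c(2, 4, NA, 6, 8, 6), rep(c("B", "C"), each = 3))
#' y <- sced_series(1:6, c(6, 5, 5, 4, 2, 2), rep(c("B", "C"), each = 3))
#' ds <- sced_dataset(m, y)
#' apply_missing_policy(ds, "listwise")$mediator$time  # re-indexed 1..5
#' @export
apply_missing_policy <- function(ds, policy = c("calendar", "listwise")) {
  policy <- match.arg(policy)
  if (policy == "calendar") return(ds)
  keep <- !is.na(ds$mediator$value) & !is.na(ds$outcome$value)
  new_time <- seq_len(sum(keep))
  m <- sced_series(new_time, ds$mediator$value[keep], ds$mediator$phase[keep],
                   attr(ds$mediator, "scale_bounds"))
  y <- sced_series(new_time, ds$outcome$value[keep], ds$outcome$phase[keep],
                   attr(ds$outcome, "scale_bounds"))
  out <- sced_dataset(m, y, ds$phase_order, ds$hypothesized_direction)
  labs <- phase_labels(out)
  n_ok <- phase_lengths(out)
  if (any(n_ok < 3L))
    sced_abort(sprintf(
      "listwise deletion leaves phase %s with fewer than 3 observations",
      paste(names(n_ok)[n_ok < 3L], collapse = ", ")), "phase_too_small")
  out
}

# Plotting --------------------------------------------------------------

#' Plot mediator and outcome series with phase boundaries
#'
#' Writes a two-panel point-and-line display, one panel per variable, with
#' vertical lines at each phase boundary. Missing days are left as gaps
#' (no interpolation across them).
#'
#' @param ds A `sced_dataset`.
#' @param out Path for the image file (`.png` or `.pdf` by extension).
#' @param width,height Device size in inches.
#' @return Invisibly, a list with `path` and `n_boundaries` (the number of
#'   phase-boundary lines drawn per panel).
#' @export
plot_sced_dataset <- function(ds, out, width = 8, height = 6) {
  ext <- tolower(tools::file_ext(out))
  ok <- tryCatch({
    if (ext == "pdf") grDevices::pdf(out, width = width, height = height)
    else grDevices::png(out, width = width * 96, height = height * 96, res = 96)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) sced_abort(sprintf("cannot open graphics file: %s", out), "io")
  on.exit(grDevices::dev.off(), add = TRUE)

  labs <- phase_labels(ds)
  # boundary = first day of each later phase, drawn half a day before it
  starts <- vapply(labs[-1], function(l) {
    min(ds$mediator$time[ds$mediator$phase == l])
  }, numeric(1))
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  # restore par before the device closes, or par() would open a new device
  on.exit(graphics::par(old), add = TRUE, after = FALSE)
  panels <- list(mediator = ds$mediator, outcome = ds$outcome)
  for (nm in names(panels)) {
    s <- panels[[nm]]
    bounds <- attr(s, "scale_bounds")
    ylim <- if (!is.null(bounds)) bounds else range(s$value, na.rm = TRUE)
    graphics::plot(s$time, s$value, type = "n", xlab = "study day",
                   ylab = "score", main = nm, ylim = ylim)
    # draw line segments only between consecutive days both observed
    obs <- !is.na(s$value)
    for (i in seq_len(nrow(s) - 1L)) {
      if (obs[i] && obs[i + 1L] && s$phase[i] == s$phase[i + 1L])
        graphics::segments(s$time[i], s$value[i],
                           s$time[i + 1L], s$value[i + 1L])
    }
    graphics::points(s$time[obs], s$value[obs], pch = 16, cex = 0.7)
    graphics::abline(v = starts - 0.5, lty = 2)
    graphics::mtext(paste(labs, collapse = " | "), side = 3, line = 0,
                    cex = 0.7, adj = 1)
  }
  invisible(list(path = out, n_boundaries = length(starts)))
}
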