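#' Trapezoidal area of a single trajectory segment
#'
#' Area under the linear interpolant of a feature value between two
#' consecutive time points, \eqn{(v_i + v_{i+1})/2 \cdot (t_{i+1} - t_i)}.
#'
#' @param t0,t1 Segment start and end times (months); `t1` must exceed `t0`.
#' @param v0,v1 Feature values at `t0` and `t1`.
#' @return Area in feature-units x months.
#' @export
#' @examples
#' segment_area(0, 2, 1.0, 0.5)  # 1.5
segment_area <- function(t0, t1, v0, v1) {
  if (any(t1 <= t0)) stop("segment end time must exceed start time")
  (v0 + v1) / 2 * (t1 - t0)
}

check_trajectory <- function(times, values) {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) < 2L) stop("a trajectory needs at least 2 time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  invisible(TRUE)
}

#' Unsigned trapezoidal area under a feature trajectory (AUC1)
#'
#' Sums the trapezoid areas of all consecutive time-point pairs, i.e. the
#' exact integral of the piecewise-linear interpolant from baseline to the
#' last time point.
#'
#' @param times Strictly increasing observation times in months, baseline at
#'   the first element.
#' @param values Feature values at `times`.
#' @return AUC1 in feature-units x months.
#' @seealso [auc2()], [beta_value()], [summarize_trajectory()]
#' @export
#' @examples
#' auc1(c(0, 2), c(1.0, 0.5))  # 1.5
auc1 <- function(times, values) {
  check_trajectory(times, values)
  sum(segment_area(times[-length(times)], times[-1L],
                   values[-length(values)], values[-1L]))
}

#' Signed trapezoidal area of a feature trajectory (AUC2)
#'
#' Like [auc1()] but each segment's trapezoid area is added when the feature
#' increases over the segment and subtracted otherwise, so response phases
#' (falling values) pull the total down and progression phases push it up.
#'
#' @inheritParams auc1
#' @param zero_increment How a segment with exactly zero change contributes:
#'   `"subtract"` (default; any non-positive increment subtracts) or
#'   `"drop"` (zero-change segments contribute nothing).
#' @return Signed AUC2 in feature-units x months.
#' @export
#' @examples
#' auc2(c(0, 1, 2), c(1.0, 0.5, 1.0))  # -0.75 + 0.75 = 0
auc2 <- function(times, values, zero_increment = c("subtract", "drop")) {
  check_trajectory(times, values)
  zero_increment <- match.arg(zero_increment)
  dv <- diff(values)
  a <- segment_area(times[-length(times)], times[-1L],
                    values[-length(values)], values[-1L])
  s <- ifelse(dv > 0, 1, -1)
  if (zero_increment == "drop") s[dv == 0] <- 0
  sum(s * a)
}

#' Least-squares slope of a feature trajectory over time (beta value)
#'
#' Ordinary least-squares regression coefficient of the feature values on
#' observation time, summarizing the overall direction of longitudinal
#' change.
#'
#' @inheritParams auc1
#' @return Slope in feature-units per month.
#' @export
#' @examples
#' beta_value(c(0, 1, 2), c(1.0, 0.8, 0.6))  # -0.2
beta_value <- function(times, values) {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(unique(times)) < 2L) stop("at least 2 distinct times required")
  tc <- times - mean(times)
  sum(tc * (values - mean(values))) / sum(tc^2)
}

#' Summarize one feature trajectory into (AUC1, beta, AUC2)
#'
#' Time points with missing values are dropped for this feature (the result
#' carries an `n_dropped` attribute); if fewer than two usable points remain
#' the summaries are `NA` with a warning.
#'
#' @inheritParams auc1
#' @inheritParams auc2
#' @return A named list of class `"summary_triple"` with elements `auc1`,
#'   `beta`, `auc2`, and attribute `n_dropped`.
#' @export
summarize_trajectory <- function(times, values,
                                 zero_increment = c("subtract", "drop")) {
  zero_increment <- match.arg(zero_increment)
  keep <- !is.na(values) & !is.na(times)
  n_dropped <- sum(!keep)
  times <- times[keep]; values <- values[keep]
  if (length(times) < 2L) {
    warning("fewer than 2 usable time points; summaries are NA")
    out <- list(auc1 = NA_real_, beta = NA_real_, auc2 = NA_real_)
  } else {
    out <- list(auc1 = auc1(times, values),
                beta = beta_value(times, values),
                auc2 = auc2(times, values, zero_increment))
  }
  attr(out, "n_dropped") <- n_dropped
  class(out) <- "summary_triple"
  out
}

#' @export
print.summary_triple <- function(x, ...) {
  cat(sprintf("AUC1 = %.4g, beta = %.4g /month, AUC2 = %.4g\n",
              x$auc1, x$beta, x$auc2))
  invisible(x)
}

#' Summarize all patient-by-feature trajectories of a cohort
#'
#' Computes the (AUC1, beta, AUC2) triple for every patient x feature in a
#' long-format trajectory table and returns one wide row per patient.
#' Trajectories may sit on different time grids per patient; no interpolation
#' to a common grid is done.
#'
#' @param trajectories Long-format data frame with columns `patient_id`,
#'   `time_months`, `feature`, `value`.
#' @param normalize If `TRUE` (default) each trajectory is divided by its
#'   baseline (earliest-time) value before summarization, so summaries are on
#'   a relative scale comparable across patients. Trajectories whose baseline
#'   value is 0 or missing yield `NA` summaries with a warning.
#' @param include_baseline If `TRUE` (default) the raw baseline value of each
#'   feature is included as a `<feature>_baseline` column.
#' @inheritParams auc2
#' @return Data frame with `patient_id` and columns
#'   `<feature>_{auc1,beta,auc2}` (plus `<feature>_baseline`).
#' @export
summarize_cohort <- function(trajectories, normalize = TRUE,
                             include_baseline = TRUE,
                             zero_increment = c("subtract", "drop")) {
  zero_increment <- match.arg(zero_increment)
  need <- c("patient_id", "time_months", "feature", "value")
  if (!all(need %in% names(trajectories)))
    stop("trajectories must have columns ", paste(need, collapse = ", "))
  pts <- unique(trajectories$patient_id)
  feats <- unique(trajectories$feature)
  cols <- c(outer(feats, c("auc1", "beta", "auc2"), paste, sep = "_"))
  if (include_baseline) cols <- c(cols, paste0(feats, "_baseline"))
  out <- as.data.frame(matrix(NA_real_, length(pts), length(cols),
                              dimnames = list(NULL, cols)))
  out <- cbind(data.frame(patient_id = pts, stringsAsFactors = FALSE), out)
  for (i in seq_along(pts)) {
    sub <- trajectories[trajectories$patient_id == pts[i], , drop = FALSE]
    for (f in feats) {
      fs <- sub[sub$feature == f, , drop = FALSE]
      fs <- fs[order(fs$time_months), , drop = FALSE]
      if (!nrow(fs)) next
      v <- fs$value; tt <- fs$time_months
      base <- v[1L]
      if (include_baseline) out[i, paste0(f, "_baseline")] <- base
      if (normalize) {
        if (is.na(base) || base == 0) {
          warning(sprintf("patient %s, feature %s: baseline value %s; summaries NA",
                          pts[i], f, ifelse(is.na(base), "missing", "zero")))
          next
        }
        v <- v / base
      }
      tr <- suppressWarnings(summarize_trajectory(tt, v, zero_increment))
      out[i, paste0(f, "_auc1")] <- tr$auc1
      out[i, paste0(f, "_beta")] <- tr$beta
      out[i, paste0(f, "_auc2")] <- tr$auc2
    }
  }
  out
}

#' Spearman correlation between trajectory pattern labels and a summary
#'
#' Rank correlation (average ranks on ties) between ordinal response-pattern
#' labels and a per-patient summary statistic, with a two-sided p-value.
#'
#' @param labels Ordinal pattern labels (integers 1-6).
#' @param summaries Numeric summary statistic, same length.
#' @return List with `rho`, `p`, and `degenerate` (`TRUE` when either input
#'   is constant, in which case `rho` is `NA`).
#' @export
pattern_correlation <- function(labels, summaries) {
  if (length(labels) != length(summaries))
    stop("labels and summaries must have equal length")
  if (length(labels) < 3L) stop("need at least 3 observations")
  ok <- stats::complete.cases(labels, summaries)
  labels <- labels[ok]; summaries <- summaries[ok]
  if (length(unique(labels)) < 2L || length(unique(summaries)) < 2L)
    return(list(rho = NA_real_, p = NA_real_, degenerate = TRUE))
  ct <- suppressWarnings(
    stats::cor.test(as.numeric(labels), summaries, method = "spearman",
                    exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
}
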