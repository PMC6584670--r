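# Six canonical patterns of longitudinal tumor-volume change:
#   1 reduction only (progression driven by nontarget lesions)
#   2 slow progression after rapid response
#   3 rapid progression after rapid response
#   4 slow progression after slight reduction
#   5 rapid progression after slight reduction
#   6 sequential progression

#' Noise-free volume-ratio template for a response pattern
#'
#' Deterministic baseline-normalized volume ratio v(t)/v(0) for one of the
#' six trajectory patterns, evaluated on an arbitrary month grid. Response
#' phases are exponential declines to a pattern-specific nadir reached at
#' 35% of follow-up; progression phases are exponential regrowth at a
#' pattern-specific rate.
#'
#' @param pattern Integer 1-6.
#' @param times Strictly increasing month grid starting at 0.
#' @return Numeric vector of volume ratios, first element 1.
#' @export
pattern_template <- function(pattern, times) {
  if (length(pattern) != 1L || !pattern %in% 1:6)
    stop("pattern must be a single integer in 1..6")
  if (length(times) < 2L || times[1L] != 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing and start at 0")
  t_max <- times[length(times)]
  tn <- 0.35 * t_max
  drop_then_rise <- function(nadir, rise) {
    ifelse(times <= tn,
           exp(log(nadir) / tn * times),
           nadir * exp(rise * (times - tn)))
  }
  switch(pattern,
         0.45 + 0.55 * exp(-0.4 * times),  # 1: decline to plateau
         drop_then_rise(0.30, 0.060),      # 2: deep response, slow regrowth
         drop_then_rise(0.30, 0.188),      # 3: deep response, rapid regrowth
         drop_then_rise(0.85, 0.050),      # 4: slight response, slow regrowth
         drop_then_rise(0.85, 0.153),      # 5: slight response, rapid regrowth
         exp(0.10 * times))                # 6: sequential progression
}

#' Classify a normalized volume trajectory into one of six patterns
#'
#' Decision rules on the nadir depth \eqn{d = 1 - \min v} and the post-nadir
#' slope \eqn{m = (v_{last} - v_{min}) / (t_{last} - t_{min})}:
#' no reduction below baseline gives pattern 6; reduction with no subsequent
#' rise gives pattern 1; otherwise deep (`d >= d_deep`) versus slight
#' reduction crossed with rapid (`m >= m_fast`) versus slow regrowth gives
#' patterns 2-5.
#'
#' @param times Strictly increasing month grid, baseline first.
#' @param values Baseline-normalized volume ratios (first element must be 1).
#' @param d_deep Nadir-depth threshold separating deep from slight response
#'   (default 0.3, i.e. a nadir at or below 70% of baseline is deep).
#' @param m_fast Post-nadir slope threshold separating rapid from slow
#'   progression, in ratio units per month (default 0.1).
#' @return Integer pattern label in 1..6.
#' @export
classify_pattern <- function(times, values, d_deep = 0.3, m_fast = 0.1) {
  check_trajectory(times, values)
  if (abs(values[1L] - 1) > 1e-8)
    stop("values must be baseline-normalized (first value 1)")
  i_min <- which.min(values)
  d <- 1 - values[i_min]
  if (d <= 1e-12) return(6L)
  last <- length(values)
  if (i_min == last) return(1L)
  m <- (values[last] - values[i_min]) / (times[last] - times[i_min])
  if (m <= 0) return(1L)
  deep <- d >= d_deep
  fast <- m >= m_fast
  if (deep && !fast) return(2L)
  if (deep && fast) return(3L)
  if (!deep && !fast) return(4L)
  5L
}

#' Classify all volume trajectories in a long-format table
#'
#' @param trajectories Long-format data frame (`patient_id`, `time_months`,
#'   `feature`, `value`).
#' @param feature Name of the volume feature column value (default
#'   `"volume"`).
#' @param normalize Divide each trajectory by its baseline value first
#'   (default `TRUE`; required when values are raw volumes).
#' @inheritParams classify_pattern
#' @return Data frame with `patient_id` and integer `pattern`.
#' @export
classify_patterns <- function(trajectories, feature = "volume",
                              normalize = TRUE, d_deep = 0.3, m_fast = 0.1) {
  sub <- trajectories[trajectories$feature == feature, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for feature '", feature, "'")
  pts <- unique(sub$patient_id)
  lab <- integer(length(pts))
  for (i in seq_along(pts)) {
    fs <- sub[sub$patient_id == pts[i], , drop = FALSE]
    fs <- fs[order(fs$time_months), , drop = FALSE]
    v <- fs$value
    if (normalize) v <- v / v[1L]
    lab[i] <- classify_pattern(fs$time_months, v, d_deep, m_fast)
  }
  data.frame(patient_id = pts, pattern = lab, stringsAsFactors = FALSE)
}
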