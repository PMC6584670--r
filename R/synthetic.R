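# Synthetic cohorts with known trajectory patterns and proportional-hazards
# outcomes, for end-to-end testing of the longitudinal prognosis pipeline.

# per-feature generative models: each secondary feature tracks the volume
# ratio v(t) through scale * (offset + (1 - offset) * v) with multiplicative
# lognormal noise, so every feature has a known association with pattern.
FEATURE_MODELS <- list(
  density       = list(scale = 40.0, offset = 0.4, cv = 0.08),
  skewness_pos  = list(scale = 1.5,  offset = 0.3, cv = 0.15),
  kurtosis_pos  = list(scale = 5.0,  offset = 0.4, cv = 0.12),
  entropy       = list(scale = 6.0,  offset = 0.8, cv = 0.05),
  entropy_inner = list(scale = 5.5,  offset = 0.8, cv = 0.06)
)

#' Specification of a synthetic longitudinal cohort
#'
#' Bundles and validates all generator settings. Defaults emulate an advanced
#' NSCLC cohort under targeted therapy: serial CT every 2 months, five to
#' eight scans from baseline to progression, six volume-response patterns,
#' 10% multiplicative volume measurement noise, survival driven by the
#' signed trajectory area (AUC2) of volume through a proportional-hazards
#' model, and administrative/dropout censoring uniform on 6-54 months.
#'
#' @param n_patients Number of patients.
#' @param n_timepoints_range Integer (min, max) number of CT time points per
#'   patient (baseline included), each at least 2.
#' @param timepoint_spacing Months between consecutive scans.
#' @param pattern_mix Six nonnegative weights (summing to 1) for the six
#'   trajectory patterns.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise on feature values.
#' @param hazard_coefs Named numeric vector mapping trajectory-summary names
#'   (e.g. `"volume_auc2"`) to log-hazard coefficients.
#' @param baseline_hazard Baseline event rate in events per month.
#' @param censor_range Months (min, max) of the uniform censoring time
#'   (administrative horizon plus dropout).
#' @param baseline_volume_meanlog,baseline_volume_sdlog Lognormal parameters
#'   of the absolute baseline tumor volume in mm^3.
#' @param seed Integer RNG seed; the whole cohort is reproducible from it.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_patients = 200,
                        n_timepoints_range = c(5L, 8L),
                        timepoint_spacing = 2,
                        pattern_mix = rep(1 / 6, 6),
                        noise_cv = 0.10,
                        hazard_coefs = c(volume_auc2 = 0.12),
                        baseline_hazard = 0.02,
                        censor_range = c(6, 54),
                        baseline_volume_meanlog = log(3e4),
                        baseline_volume_sdlog = 0.8,
                        seed = 1L) {
  stopifnot(n_patients >= 0, length(n_timepoints_range) == 2)
  if (n_timepoints_range[1] < 2) stop("minimum number of time points is 2")
  if (n_timepoints_range[2] < n_timepoints_range[1])
    stop("n_timepoints_range must be (min, max) with max >= min")
  if (timepoint_spacing <= 0) stop("timepoint_spacing must be positive")
  if (length(pattern_mix) != 6 || any(pattern_mix < 0))
    stop("pattern_mix must be 6 nonnegative weights")
  if (abs(sum(pattern_mix) - 1) > 1e-9) stop("pattern_mix must sum to 1")
  if (noise_cv < 0) stop("noise_cv must be nonnegative")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (length(censor_range) != 2 || censor_range[1] < 0 ||
      censor_range[2] < censor_range[1])
    stop("censor_range must be (min, max) with 0 <= min <= max")
  structure(list(n_patients = as.integer(n_patients),
                 n_timepoints_range = as.integer(n_timepoints_range),
                 timepoint_spacing = timepoint_spacing,
                 pattern_mix = pattern_mix,
                 noise_cv = noise_cv,
                 hazard_coefs = hazard_coefs,
                 baseline_hazard = baseline_hazard,
                 censor_range = censor_range,
                 baseline_volume_meanlog = baseline_volume_meanlog,
                 baseline_volume_sdlog = baseline_volume_sdlog,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort spec: %d patients, %d-%d scans at ",
                     "%g-month spacing,\n  noise CV %.2f, baseline hazard ",
                     "%.3g/month, censoring U(%g, %g) months, seed %d\n"),
              x$n_patients, x$n_timepoints_range[1], x$n_timepoints_range[2],
              x$timepoint_spacing, x$noise_cv, x$baseline_hazard,
              x$censor_range[1], x$censor_range[2], x$seed))
  invisible(x)
}

lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sg <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sg^2 / 2, sdlog = sg)
}

#' Generate one noisy volume-ratio trajectory
#'
#' Evaluates the deterministic [pattern_template()] on the given month grid
#' and multiplies by lognormal measurement noise with the given coefficient
#' of variation; the result is re-normalized to its (noisy) baseline so the
#' first ratio is exactly 1, as in a measured-ratio pipeline. Uses the
#' current R random stream; call `set.seed()` for reproducibility.
#'
#' @param pattern Integer pattern label 1-6.
#' @param times Strictly increasing month grid starting at 0.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @return Numeric vector of baseline-normalized volume ratios.
#' @export
generate_volume_trajectory <- function(pattern, times, noise_cv = 0.10) {
  v <- pattern_template(pattern, times)
  v <- v * lognormal_noise(length(v), noise_cv)
  v / v[1L]
}

#' Draw one censored survival record from a proportional-hazards model
#'
#' Event time is exponential with rate `baseline_hazard * exp(lp)`; the
#' censoring time is uniform on `censor_range`; the observed time is the
#' minimum of the two with the corresponding event indicator.
#'
#' @param lp Linear predictor (log relative hazard).
#' @param baseline_hazard Events per month, positive.
#' @param censor_range Months (min, max) of uniform censoring; use
#'   `c(h, h)` for purely administrative censoring at horizon `h`.
#' @return List with `time` (months) and `event` (1 = event observed).
#' @export
generate_survival <- function(lp, baseline_hazard, censor_range = c(6, 54)) {
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  t_event <- stats::rexp(1, rate = baseline_hazard * exp(lp))
  t_cens <- stats::runif(1, censor_range[1], censor_range[2])
  if (t_event <= t_cens) list(time = t_event, event = 1L)
  else list(time = t_cens, event = 0L)
}

#' Generate a complete synthetic cohort
#'
#' For each patient: a pattern label is drawn from `pattern_mix`; a scan grid
#' is drawn from `n_timepoints_range`; a noisy volume-ratio trajectory is
#' generated from the pattern template; correlated secondary features
#' (density, skewness and kurtosis of positive attenuation, entropy, core
#' entropy, surface area) are generated as monotone transforms of the volume
#' ratio plus independent noise; the true linear predictor is computed from
#' the generated trajectories' summary statistics via `hazard_coefs`; and a
#' censored survival record is drawn. Fully reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `"synthetic_cohort"`: a list with `trajectories`
#'   (long data frame: `patient_id`, `time_months`, `feature`, `value`; raw
#'   feature scale), `outcomes` (`patient_id`, `time_months`, `event`),
#'   `patients` (per-patient data frame with `pattern`, `baseline_volume`,
#'   `true_lp`), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  traj_list <- vector("list", n)
  patients <- data.frame(patient_id = character(0), pattern = integer(0),
                         baseline_volume = numeric(0), true_lp = numeric(0),
                         stringsAsFactors = FALSE)
  outcomes <- data.frame(patient_id = character(0), time_months = numeric(0),
                         event = integer(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    return(structure(list(
      trajectories = data.frame(patient_id = character(0),
                                time_months = numeric(0),
                                feature = character(0), value = numeric(0),
                                stringsAsFactors = FALSE),
      outcomes = outcomes, patients = patients, spec = spec),
      class = "synthetic_cohort"))
  }
  ids <- sprintf("P%03d", seq_len(n))
  labs <- sample(1:6, n, replace = TRUE, prob = spec$pattern_mix)
  rng <- spec$n_timepoints_range
  for (i in seq_len(n)) {
    k <- sample(seq(rng[1], rng[2]), 1L)
    tt <- seq(0, by = spec$timepoint_spacing, length.out = k)
    ratio <- generate_volume_trajectory(labs[i], tt, spec$noise_cv)
    v0 <- stats::rlnorm(1, spec$baseline_volume_meanlog,
                        spec$baseline_volume_sdlog)
    rows <- data.frame(patient_id = ids[i], time_months = tt,
                       feature = "volume", value = v0 * ratio,
                       stringsAsFactors = FALSE)
    for (f in names(FEATURE_MODELS)) {
      m <- FEATURE_MODELS[[f]]
      val <- m$scale * (m$offset + (1 - m$offset) * ratio) *
        lognormal_noise(k, m$cv)
      rows <- rbind(rows, data.frame(patient_id = ids[i], time_months = tt,
                                     feature = f, value = val,
                                     stringsAsFactors = FALSE))
    }
    # sphere-equivalent surface area tracking volume^(2/3), mild rugosity
    sa <- 1.2 * (36 * pi)^(1 / 3) * (v0 * ratio)^(2 / 3) *
      lognormal_noise(k, 0.08)
    rows <- rbind(rows, data.frame(patient_id = ids[i], time_months = tt,
                                   feature = "surface_area", value = sa,
                                   stringsAsFactors = FALSE))
    traj_list[[i]] <- rows
    # true linear predictor from the realized (normalized) summaries
    lp <- 0
    tr <- summarize_trajectory(tt, ratio)
    summ <- c(volume_auc1 = tr$auc1, volume_beta = tr$beta,
              volume_auc2 = tr$auc2)
    for (f in names(FEATURE_MODELS)) {
      fv <- rows$value[rows$feature == f]
      trf <- summarize_trajectory(tt, fv / fv[1L])
      summ <- c(summ, stats::setNames(
        c(trf$auc1, trf$beta, trf$auc2),
        paste0(f, c("_auc1", "_beta", "_auc2"))))
    }
    for (nm in names(spec$hazard_coefs)) {
      if (!nm %in% names(summ))
        stop("hazard_coefs names a summary not generated: ", nm)
      lp <- lp + spec$hazard_coefs[[nm]] * summ[[nm]]
    }
    sv <- generate_survival(lp, spec$baseline_hazard, spec$censor_range)
    patients <- rbind(patients, data.frame(
      patient_id = ids[i], pattern = labs[i], baseline_volume = v0,
      true_lp = lp, stringsAsFactors = FALSE))
    outcomes <- rbind(outcomes, data.frame(
      patient_id = ids[i], time_months = sv$time, event = sv$event,
      stringsAsFactors = FALSE))
  }
  structure(list(trajectories = do.call(rbind, traj_list),
                 outcomes = outcomes, patients = patients, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d trajectory rows, %d events\n",
              nrow(x$patients), nrow(x$trajectories), sum(x$outcomes$event)))
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `trajectories.csv` (long format) and `outcomes.csv` into `dir`,
#' each preceded by comment lines recording the generator seed, plus
#' `cohort_config.txt` with the full key-value spec.
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- sprintf("# seed: %d", cohort$spec$seed)
  write_csv_hdr <- function(df, path) {
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  write_csv_hdr(cohort$trajectories, file.path(dir, "trajectories.csv"))
  write_csv_hdr(cohort$outcomes, file.path(dir, "outcomes.csv"))
  sp <- cohort$spec
  keyval <- vapply(names(sp), function(k)
    sprintf("%s = %s", k, paste(format(sp[[k]], digits = 15), collapse = ", ")),
    character(1))
  writeLines(keyval, file.path(dir, "cohort_config.txt"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `trajectories.csv` and `outcomes.csv`.
#' @return List with `trajectories` and `outcomes` data frames.
#' @export
read_cohort <- function(dir) {
  tr <- utils::read.csv(file.path(dir, "trajectories.csv"), comment.char = "#",
                        stringsAsFactors = FALSE)
  oc <- utils::read.csv(file.path(dir, "outcomes.csv"), comment.char = "#",
                        stringsAsFactors = FALSE)
  list(trajectories = tr, outcomes = oc)
}
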