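# End-to-end orchestration: ingest or simulate a cohort, summarize
# trajectories, dichotomize markers, screen, select, score, evaluate.

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with its default. The full
#' configuration is serialized into each run directory so runs are
#' self-describing and reproducible.
#'
#' @param mode `"synthetic"` (simulate a cohort), `"feature-table"` (read
#'   long-format trajectory and outcome CSVs) or `"voxel"` (extract features
#'   from NIfTI volumes listed in a manifest).
#' @param cohort A [cohort_spec()] for synthetic mode (its seed is
#'   overridden by `seed`).
#' @param trajectories_path,outcomes_path CSV paths for feature-table mode.
#' @param manifest_path CSV path for voxel mode (columns `patient_id`,
#'   `time_months`, `lesion_id`, `image`, `mask`).
#' @param outdir Output directory of [run_pipeline()].
#' @param seed Integer RNG seed for the run.
#' @param normalize Baseline-normalize trajectories before summarization.
#' @param zero_increment Sign rule for flat segments, see [auc2()].
#' @param marker_summaries Which per-feature columns become candidate
#'   markers (default baseline value and AUC2, as in the prognostic model).
#' @param min_group_frac Group-size floor of [optimal_cutpoint()].
#' @param alpha Univariate selection threshold.
#' @param vif_threshold Collinearity flag threshold.
#' @param horizons Time-dependent ROC horizons in months (default 12 and 36).
#' @param d_deep,m_fast Pattern-classification thresholds, see
#'   [classify_pattern()].
#' @param margin_mm,bin_width Feature-extraction settings (voxel mode).
#' @param write_plots Write Kaplan-Meier and ROC plot files.
#' @return Object of class `"run_config"` (a validated list).
#' @export
run_config <- function(mode = c("synthetic", "feature-table", "voxel"),
                       cohort = cohort_spec(),
                       trajectories_path = NULL, outcomes_path = NULL,
                       manifest_path = NULL,
                       outdir = tempfile("radtraj_run_"),
                       seed = 1L,
                       normalize = TRUE,
                       zero_increment = "subtract",
                       marker_summaries = c("baseline", "auc2"),
                       min_group_frac = 0.1,
                       alpha = 0.05,
                       vif_threshold = 10,
                       horizons = c(12, 36),
                       d_deep = 0.3, m_fast = 0.1,
                       margin_mm = 2, bin_width = 10,
                       write_plots = TRUE) {
  mode <- match.arg(mode)
  if (mode == "feature-table" &&
      (is.null(trajectories_path) || is.null(outcomes_path)))
    stop("feature-table mode needs trajectories_path and outcomes_path")
  if (mode == "voxel" && (is.null(manifest_path) || is.null(outcomes_path)))
    stop("voxel mode needs manifest_path and outcomes_path")
  if (mode == "synthetic") {
    stopifnot(inherits(cohort, "cohort_spec"))
    cohort$seed <- as.integer(seed)
  }
  structure(list(mode = mode, cohort = cohort,
                 trajectories_path = trajectories_path,
                 outcomes_path = outcomes_path,
                 manifest_path = manifest_path,
                 outdir = outdir, seed = as.integer(seed),
                 normalize = normalize, zero_increment = zero_increment,
                 marker_summaries = marker_summaries,
                 min_group_frac = min_group_frac, alpha = alpha,
                 vif_threshold = vif_threshold, horizons = horizons,
                 d_deep = d_deep, m_fast = m_fast,
                 margin_mm = margin_mm, bin_width = bin_width,
                 write_plots = write_plots),
            class = "run_config")
}

#' Validate a long-format cohort before analysis
#'
#' Checks the trajectory and outcome tables for schema problems, duplicate
#' or non-monotone scan times, missing baselines, nonpositive or missing
#' survival times, and patient-id mismatches. Violations are reported, not
#' raised.
#'
#' @param trajectories Long-format trajectory data frame.
#' @param outcomes Outcome data frame (`patient_id`, `time_months`, `event`).
#' @return Data frame with columns `check`, `patient_id`, `detail`; zero
#'   rows when the cohort is well formed.
#' @export
validate_inputs <- function(trajectories, outcomes) {
  bad <- data.frame(check = character(0), patient_id = character(0),
                    detail = character(0), stringsAsFactors = FALSE)
  note <- function(check, pid, detail)
    rbind(bad, data.frame(check = check, patient_id = as.character(pid),
                          detail = detail, stringsAsFactors = FALSE))
  need_t <- c("patient_id", "time_months", "feature", "value")
  miss <- setdiff(need_t, names(trajectories))
  if (length(miss))
    bad <- note("schema", NA, paste("trajectories missing:",
                                    paste(miss, collapse = ", ")))
  need_o <- c("patient_id", "time_months", "event")
  miss <- setdiff(need_o, names(outcomes))
  if (length(miss))
    bad <- note("schema", NA, paste("outcomes missing:",
                                    paste(miss, collapse = ", ")))
  if (nrow(bad)) return(bad)
  for (pid in unique(trajectories$patient_id)) {
    sub <- trajectories[trajectories$patient_id == pid, , drop = FALSE]
    for (f in unique(sub$feature)) {
      tt <- sub$time_months[sub$feature == f]
      if (anyDuplicated(tt))
        bad <- note("duplicate_time", pid, paste("feature", f))
      if (!any(tt == 0))
        bad <- note("missing_baseline", pid, paste("feature", f))
      if (length(tt) < 2L)
        bad <- note("single_timepoint", pid, paste("feature", f))
    }
  }
  if (any(is.na(outcomes$time_months) | outcomes$time_months <= 0))
    for (pid in outcomes$patient_id[is.na(outcomes$time_months) |
                                      outcomes$time_months <= 0])
      bad <- note("nonpositive_survival_time", pid, "")
  if (!all(outcomes$event %in% c(0, 1)))
    bad <- note("event_not_binary", NA, "")
  only_t <- setdiff(unique(trajectories$patient_id), outcomes$patient_id)
  for (pid in only_t) bad <- note("no_outcome", pid, "")
  only_o <- setdiff(outcomes$patient_id, unique(trajectories$patient_id))
  for (pid in only_o) bad <- note("no_trajectory", pid, "")
  bad
}

#' Run the full prognostic analysis on an in-memory cohort
#'
#' Stages: trajectory summarization, pattern classification and
#' pattern-summary correlation, per-marker optimal log-rank cutpoint and
#' dichotomization, univariate Cox screen, VIF collinearity screen,
#' bidirectional stepwise-AIC Cox selection, linear risk score, and
#' time-dependent AUROC at the configured horizons.
#'
#' @param trajectories Long-format trajectory data frame.
#' @param outcomes Outcome data frame (`patient_id`, `time_months`, `event`).
#' @param config A [run_config()] (only its analysis settings are used).
#' @return List with `summaries`, `patterns`, `pattern_correlations`,
#'   `cutpoints`, `dichotomized`, `univariate`, `vif`, `stepwise`,
#'   `final_fit`, `risk_scores`, `td_auroc`, `km`.
#' @export
analyze_cohort <- function(trajectories, outcomes, config = run_config()) {
  summaries <- summarize_cohort(trajectories, normalize = config$normalize,
                                include_baseline = TRUE,
                                zero_increment = config$zero_increment)
  # align outcomes to the summary rows
  m <- match(summaries$patient_id, outcomes$patient_id)
  if (anyNA(m)) stop("outcomes missing for some patients")
  time <- outcomes$time_months[m]
  event <- outcomes$event[m]

  patterns <- classify_patterns(trajectories, feature = "volume",
                                normalize = TRUE,
                                d_deep = config$d_deep, m_fast = config$m_fast)
  pm <- match(summaries$patient_id, patterns$patient_id)
  pc <- lapply(c(auc1 = "volume_auc1", beta = "volume_beta",
                 auc2 = "volume_auc2"), function(cn)
    pattern_correlation(patterns$pattern[pm], summaries[[cn]]))

  feats <- unique(trajectories$feature)
  marker_cols <- as.vector(outer(feats, config$marker_summaries,
                                 function(f, s) paste0(f, "_", s)))
  marker_cols <- intersect(marker_cols, names(summaries))
  cut_tab <- data.frame(marker = character(0), cutoff = numeric(0),
                        chi2 = numeric(0), p = numeric(0),
                        n_low = integer(0), n_high = integer(0),
                        stringsAsFactors = FALSE)
  dicho <- data.frame(patient_id = summaries$patient_id,
                      stringsAsFactors = FALSE)
  for (mc in marker_cols) {
    x <- summaries[[mc]]
    if (anyNA(x)) next
    cp <- tryCatch(optimal_cutpoint(x, time, event,
                                    min_group_frac = config$min_group_frac),
                   error = function(e) NULL)
    if (is.null(cp)) next
    cut_tab <- rbind(cut_tab, data.frame(
      marker = mc, cutoff = cp$cutoff, chi2 = cp$chi2, p = cp$p,
      n_low = cp$n_low, n_high = cp$n_high, stringsAsFactors = FALSE))
    dicho[[mc]] <- as.integer(x > cp$cutoff)
  }
  markers <- dicho[-1L]

  uni <- univariate_screen(markers, time, event, alpha = config$alpha)
  cand <- uni$feature[uni$selected]
  vif <- NULL
  if (length(cand) >= 2L) {
    vif <- vif_screen(markers[cand], threshold = config$vif_threshold)
    drop <- vif$feature[vif$flag | !is.finite(vif$vif)]
    cand <- setdiff(cand, drop)
  }
  sw <- if (length(cand)) stepwise_aic(markers[cand], time, event)
        else list(fit = NULL, selected = character(0), aic = NA_real_,
                  path = data.frame())
  scores <- if (!is.null(sw$fit))
    risk_score(sw$fit, markers) else rep(0, nrow(markers))
  td <- time_dependent_auroc(scores, time, event, config$horizons)
  list(summaries = summaries,
       patterns = patterns,
       pattern_correlations = pc,
       cutpoints = cut_tab,
       dichotomized = dicho,
       univariate = uni,
       vif = vif,
       stepwise = sw,
       final_fit = sw$fit,
       risk_scores = data.frame(patient_id = summaries$patient_id,
                                score = scores, time_months = time,
                                event = event, stringsAsFactors = FALSE),
       td_auroc = td,
       km = km_estimate(time, event))
}

#' Run the pipeline end to end and write a run directory
#'
#' Executes generate/ingest, summarization, cutpoint search, univariate and
#' collinearity screens, stepwise selection, risk scoring and time-dependent
#' ROC, writing every intermediate table as CSV plus a plain-text log and
#' the serialized configuration. Identical configuration and seed give
#' byte-identical numeric tables.
#'
#' @param config A [run_config()].
#' @return The analysis result of [analyze_cohort()], invisibly, with the
#'   run directory attached as attribute `outdir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$outdir, "log.txt")
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  say("radtraj pipeline, mode = %s, seed = %d", config$mode, config$seed)

  if (config$mode == "synthetic") {
    cohort <- generate_cohort(config$cohort)
    trajectories <- cohort$trajectories
    outcomes <- cohort$outcomes
    write_cohort(cohort, config$outdir)
    utils::write.csv(cohort$patients,
                     file.path(config$outdir, "patients_truth.csv"),
                     row.names = FALSE)
    say("generated %d patients (%d events)", nrow(cohort$patients),
        sum(outcomes$event))
  } else if (config$mode == "feature-table") {
    trajectories <- utils::read.csv(config$trajectories_path,
                                    comment.char = "#",
                                    stringsAsFactors = FALSE)
    outcomes <- utils::read.csv(config$outcomes_path, comment.char = "#",
                                stringsAsFactors = FALSE)
    say("read %d trajectory rows, %d outcomes", nrow(trajectories),
        nrow(outcomes))
  } else {
    manifest <- utils::read.csv(config$manifest_path, comment.char = "#",
                                stringsAsFactors = FALSE)
    trajectories <- feature_table_from_manifest(
      manifest, margin_mm = config$margin_mm, bin_width = config$bin_width)
    outcomes <- utils::read.csv(config$outcomes_path, comment.char = "#",
                                stringsAsFactors = FALSE)
    utils::write.csv(trajectories,
                     file.path(config$outdir, "extracted_features.csv"),
                     row.names = FALSE)
    say("extracted features for %d patient-time points",
        nrow(unique(trajectories[c("patient_id", "time_months")])))
  }

  viol <- validate_inputs(trajectories, outcomes)
  utils::write.csv(viol, file.path(config$outdir, "validation.csv"),
                   row.names = FALSE)
  if (nrow(viol)) say("validation: %d violations (see validation.csv)",
                      nrow(viol)) else say("validation: clean")

  res <- analyze_cohort(trajectories, outcomes, config)

  wcsv <- function(x, name)
    utils::write.csv(x, file.path(config$outdir, name), row.names = FALSE)
  wcsv(res$summaries, "summaries.csv")
  wcsv(res$patterns, "patterns.csv")
  pc <- do.call(rbind, lapply(names(res$pattern_correlations), function(nm)
    data.frame(summary = nm, rho = res$pattern_correlations[[nm]]$rho,
               p = res$pattern_correlations[[nm]]$p)))
  wcsv(pc, "pattern_correlations.csv")
  wcsv(res$cutpoints, "cutpoints.csv")
  wcsv(res$dichotomized, "dichotomized.csv")
  wcsv(res$univariate, "univariate.csv")
  if (!is.null(res$vif)) wcsv(res$vif, "vif.csv")
  wcsv(res$stepwise$path, "stepwise_path.csv")
  if (!is.null(res$final_fit)) wcsv(res$final_fit$table, "multivariate.csv")
  wcsv(res$risk_scores, "risk_scores.csv")
  wcsv(as.data.frame(res$td_auroc), "auroc.csv")
  say("cutpoints: %d markers; univariate selected: %d; final model: %d features",
      nrow(res$cutpoints), sum(res$univariate$selected),
      length(res$stepwise$selected))
  for (i in seq_len(nrow(res$td_auroc)))
    say("AUROC at %g months: %.3f", res$td_auroc$horizon[i],
        res$td_auroc$auroc[i])

  cfg <- config
  cfg$cohort <- NULL
  keyval <- vapply(names(cfg), function(k)
    sprintf("%s = %s", k,
            paste(format(cfg[[k]], digits = 15), collapse = ", ")),
    character(1))
  writeLines(keyval, file.path(config$outdir, "config.txt"))
  if (config$mode == "synthetic")
    writeLines(vapply(names(config$cohort), function(k)
      sprintf("cohort.%s = %s", k,
              paste(format(config$cohort[[k]], digits = 15), collapse = ", ")),
      character(1)), file.path(config$outdir, "cohort_spec.txt"))

  if (isTRUE(config$write_plots)) {
    grDevices::pdf(file.path(config$outdir, "km_risk_groups.pdf"), 7, 5)
    sc <- res$risk_scores
    hi <- sc$score > stats::median(sc$score)
    sf <- survival::survfit(survival::Surv(time_months, event) ~ hi, data = sc)
    plot(sf, col = c("steelblue", "firebrick"), xlab = "Months",
         ylab = "Overall survival",
         main = "Kaplan-Meier by risk-score median split")
    graphics::legend("topright", c("low score", "high score"),
                     col = c("steelblue", "firebrick"), lty = 1, bty = "n")
    grDevices::dev.off()
    grDevices::pdf(file.path(config$outdir, "roc_curves.pdf"), 7, 5)
    plot(0:1, 0:1, type = "l", lty = 3, col = "grey", xlab = "1 - specificity",
         ylab = "Sensitivity", main = "Time-dependent ROC")
    cols <- grDevices::hcl.colors(length(config$horizons), "Dark 2")
    for (i in seq_along(config$horizons)) {
      cr <- tryCatch(td_roc_curve(sc$score, sc$time_months, sc$event,
                                  config$horizons[i]), error = function(e) NULL)
      if (!is.null(cr)) graphics::lines(cr$fpr, cr$tpr, col = cols[i], lwd = 2)
    }
    graphics::legend("bottomright", sprintf("%g months", config$horizons),
                     col = cols, lwd = 2, bty = "n")
    grDevices::dev.off()
  }
  writeLines(log_lines, logf)
  attr(res, "outdir") <- config$outdir
  invisible(res)
}

#' Extract an aggregated feature table from a NIfTI manifest
#'
#' Reads each lesion's image and mask, computes the named features, and
#' volume-weight-aggregates lesions within each patient and time point into
#' one long-format feature table.
#'
#' @param manifest Data frame with columns `patient_id`, `time_months`,
#'   `lesion_id`, `image`, `mask` (file paths).
#' @param margin_mm,bin_width Feature-extraction settings.
#' @return Long-format data frame (`patient_id`, `time_months`, `feature`,
#'   `value`).
#' @export
feature_table_from_manifest <- function(manifest, margin_mm = 2,
                                        bin_width = 10) {
  need <- c("patient_id", "time_months", "lesion_id", "image", "mask")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  out <- NULL
  grp <- unique(manifest[c("patient_id", "time_months")])
  for (i in seq_len(nrow(grp))) {
    sub <- manifest[manifest$patient_id == grp$patient_id[i] &
                      manifest$time_months == grp$time_months[i], ,
                    drop = FALSE]
    fl <- lapply(seq_len(nrow(sub)), function(j) {
      roi <- read_lesion_nifti(sub$image[j], sub$mask[j])
      roi_features(roi, margin_mm = margin_mm, bin_width = bin_width)
    })
    agg <- aggregate_lesions(fl)
    out <- rbind(out, data.frame(patient_id = grp$patient_id[i],
                                 time_months = grp$time_months[i],
                                 feature = names(agg), value = unname(agg),
                                 stringsAsFactors = FALSE))
  }
  out
}
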