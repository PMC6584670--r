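# Marker dichotomization at the most significant log-rank cutpoint, Cox
# modelling with stepwise-AIC selection, and censoring-weighted
# time-dependent ROC evaluation of the resulting risk score.

#' Two-group log-rank test
#'
#' Standard log-rank statistic from the observed-minus-expected event counts
#' over the shared risk sets, with a 1-df chi-square p-value. Tied event
#' times are pooled within each risk set. Implemented directly (rather than
#' wrapped) so the cutpoint scan below is self-contained and fast.
#'
#' @param group Logical or 0/1 vector assigning each subject to group 1.
#' @param time Follow-up times in months.
#' @param event Event indicators (1 = event).
#' @return List with `chi2`, `p`, `observed` and `expected` events in group 1.
#' @export
logrank_test <- function(group, time, event) {
  group <- as.logical(group)
  if (length(unique(group)) < 2L) stop("two nonempty groups are required")
  o <- order(time)
  tt <- time[o]; ev <- event[o] == 1; g1 <- group[o]
  n <- length(tt)
  first <- which(!duplicated(tt))            # first index of each unique time
  ut_n <- c(first[-1L], n + 1L) - first       # multiplicity of each time
  at_risk <- n - first + 1L
  g1_tail <- rev(cumsum(rev(g1)))             # of subjects with time >= tt[i]
  n1 <- g1_tail[first]
  grp_idx <- rep(seq_along(first), ut_n)
  d <- as.vector(tapply(ev, grp_idx, sum))
  d1 <- as.vector(tapply(ev & g1, grp_idx, sum))
  keep <- d > 0
  d <- d[keep]; d1 <- d1[keep]; nn <- at_risk[keep]; nn1 <- n1[keep]
  if (!length(d)) return(list(chi2 = 0, p = 1, observed = 0, expected = 0))
  O <- sum(d1)
  E <- sum(d * nn1 / nn)
  vterm <- d * (nn1 / nn) * (1 - nn1 / nn) * (nn - d) / pmax(nn - 1, 1)
  vterm[nn <= 1] <- 0
  V <- sum(vterm)
  if (V <= 0) return(list(chi2 = 0, p = 1, observed = O, expected = E))
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Most significant log-rank cutpoint of a continuous marker
#'
#' Scans every candidate cutoff (midpoints between consecutive sorted
#' distinct marker values) subject to both resulting groups containing at
#' least `min_group_frac` of the subjects, and returns the cutoff with the
#' smallest log-rank p-value (ties broken toward the smaller cutoff). Note
#' that the selected p-value is not corrected for the multiplicity of the
#' scan and is anticonservative; `n_perm` requests a permutation-adjusted
#' p-value for the selected statistic.
#'
#' @param marker Continuous marker values.
#' @param time,event Survival outcome.
#' @param min_group_frac Minimum fraction of subjects in each group
#'   (default 0.1).
#' @param n_perm Number of label permutations for the adjusted p-value
#'   (0 = skip).
#' @return Object of class `"cutpoint_result"`: `cutoff`, `chi2`, `p`,
#'   `n_low`, `n_high`, optionally `p_adjusted`, and the full `scan` table.
#' @export
optimal_cutpoint <- function(marker, time, event, min_group_frac = 0.1,
                             n_perm = 0L) {
  n <- length(marker)
  if (n < 10L) stop("at least 10 subjects are required")
  sv <- sort(unique(marker))
  if (length(sv) < 2L) stop("marker must have at least 2 distinct values")
  cand <- (sv[-length(sv)] + sv[-1L]) / 2
  scan_once <- function(tm, evn) {
    res <- matrix(NA_real_, length(cand), 4L)
    for (i in seq_along(cand)) {
      hi <- marker > cand[i]
      n_hi <- sum(hi)
      if (n_hi < min_group_frac * n || (n - n_hi) < min_group_frac * n) next
      lr <- logrank_test(hi, tm, evn)
      res[i, ] <- c(lr$chi2, lr$p, n - n_hi, n_hi)
    }
    res
  }
  res <- scan_once(time, event)
  ok <- which(!is.na(res[, 2]))
  if (!length(ok)) stop("no cutoff satisfies the group-size constraint")
  best <- ok[which.min(res[ok, 2])]   # which.min takes the first (smallest cutoff)
  out <- list(cutoff = cand[best], chi2 = res[best, 1], p = res[best, 2],
              n_low = as.integer(res[best, 3]),
              n_high = as.integer(res[best, 4]),
              scan = data.frame(cutoff = cand, chi2 = res[, 1], p = res[, 2]))
  if (n_perm > 0L) {
    best_chi2 <- res[best, 1]
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      rb <- scan_once(time[idx], event[idx])
      mx <- suppressWarnings(max(rb[, 1], na.rm = TRUE))
      if (is.finite(mx) && mx >= best_chi2) exceed <- exceed + 1L
    }
    out$p_adjusted <- (exceed + 1) / (n_perm + 1)
  }
  class(out) <- "cutpoint_result"
  out
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("Optimal cutpoint %.4g (n_low %d, n_high %d): chi2 %.3f, p %.4g\n",
              x$cutoff, x$n_low, x$n_high, x$chi2, x$p))
  if (!is.null(x$p_adjusted))
    cat(sprintf("  permutation-adjusted p %.4g\n", x$p_adjusted))
  invisible(x)
}

#' Kaplan-Meier estimate with Greenwood variance
#'
#' Product-limit estimator of the survival function; the median is the first
#' observed time at which the estimated survival drops to 0.5 or below.
#'
#' @param time,event Survival outcome.
#' @return List with `time`, `surv`, `std_err` (Greenwood standard error of
#'   S(t)), `n_risk`, `n_event`, `median` (NA when the curve never reaches
#'   0.5), and the underlying `survival::survfit` object as `fit`.
#' @export
km_estimate <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log")
  med <- fit$time[which(fit$surv <= 0.5)[1L]]
  list(time = fit$time, surv = fit$surv,
       std_err = fit$std.err * fit$surv,   # survfit reports se of log S
       n_risk = fit$n.risk, n_event = fit$n.event,
       median = if (length(med)) med else NA_real_, fit = fit)
}

#' Cox proportional-hazards fit
#'
#' Maximum partial-likelihood fit (Efron handling of tied event times) with
#' Wald confidence intervals and p-values and the model AIC.
#'
#' @param design Data frame of covariates (binary dichotomized markers or
#'   continuous values); constant columns are rejected.
#' @param time,event Survival outcome.
#' @param conf_level Confidence level of the hazard-ratio intervals.
#' @return Object of class `"cox_fit"`: `table` (per-feature coef, HR, CI,
#'   p), `loglik`, `aic`, `n`, `n_events`, `converged`, `separation`
#'   (monotone-likelihood flag), and the `survival::coxph` fit as `model`.
#' @export
cox_fit <- function(design, time, event, conf_level = 0.95) {
  design <- as.data.frame(design)
  if (!ncol(design)) stop("design must have at least one column")
  const <- vapply(design, function(x) length(unique(x)) < 2L, logical(1))
  if (any(const))
    stop("constant columns in design: ", paste(names(design)[const], collapse = ", "))
  if (sum(event) < ncol(design))
    stop("fewer events than covariates")
  dat <- cbind(data.frame(.time = time, .event = event), design)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(design)), collapse = " + ")))
  warn <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  co <- fit$coefficients
  se <- sqrt(diag(fit$var))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(feature = names(design), coef = unname(co),
                    hr = exp(unname(co)),
                    ci_low = exp(unname(co) - z * se),
                    ci_high = exp(unname(co) + z * se),
                    se = unname(se),
                    p = 2 * stats::pnorm(-abs(unname(co) / se)),
                    stringsAsFactors = FALSE)
  separation <- any(grepl("infinite|converge", warn, ignore.case = TRUE)) ||
    any(abs(co) > 15)
  structure(list(table = tab, loglik = fit$loglik[length(fit$loglik)],
                 aic = stats::AIC(fit), n = fit$n, n_events = fit$nevent,
                 converged = is.null(fit$info) || fit$iter < fit$control$iter.max,
                 separation = separation, warnings = warn, model = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox PH fit: n = %d, events = %d, AIC = %.2f\n",
              x$n, x$n_events, x$aic))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print(tab, row.names = FALSE)
  if (x$separation) cat("warning: possible monotone likelihood / separation\n")
  invisible(x)
}

#' Univariate Cox screen
#'
#' Fits one single-covariate Cox model per feature and keeps those with a
#' Wald p-value below `alpha`.
#'
#' @param features Data frame of candidate features (dichotomized markers
#'   and/or clinical covariates).
#' @param time,event Survival outcome.
#' @param alpha Selection threshold on the p-value (default 0.05).
#' @return Data frame with `feature`, `coef`, `hr`, `p`, `selected`;
#'   constant features get `NA` and are never selected.
#' @export
univariate_screen <- function(features, time, event, alpha = 0.05) {
  features <- as.data.frame(features)
  if (!ncol(features))
    return(data.frame(feature = character(0), coef = numeric(0),
                      hr = numeric(0), p = numeric(0), selected = logical(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(feature = names(features), coef = NA_real_,
                    hr = NA_real_, p = NA_real_, selected = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(features)) {
    x <- features[[i]]
    if (length(unique(x)) < 2L) next
    f <- tryCatch(cox_fit(features[i], time, event), error = function(e) NULL)
    if (is.null(f)) next
    out$coef[i] <- f$table$coef[1]
    out$hr[i] <- f$table$hr[1]
    out$p[i] <- f$table$p[1]
    out$selected[i] <- !is.na(out$p[i]) && out$p[i] < alpha
  }
  out
}

#' Variance inflation factors
#'
#' VIF of each feature from an ordinary least-squares regression on all the
#' others; values above `threshold` are flagged as collinear. A perfectly
#' collinear column yields an infinite VIF.
#'
#' @param design Data frame with at least 2 numeric features.
#' @param threshold Collinearity flag threshold (default 10).
#' @return Data frame with `feature`, `vif`, `flag`.
#' @export
vif_screen <- function(design, threshold = 10) {
  design <- as.data.frame(design)
  if (ncol(design) < 2L) stop("at least 2 features are required")
  out <- data.frame(feature = names(design), vif = NA_real_, flag = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_along(design)) {
    y <- design[[j]]
    X <- as.matrix(design[-j])
    fit <- stats::lm.fit(cbind(1, X), y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) next
    r2 <- 1 - rss / tss
    out$vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    out$flag[j] <- out$vif[j] > threshold
  }
  out
}

#' Bidirectional stepwise Cox model selection by AIC
#'
#' Starts from the model containing all candidates; at each step every
#' single-variable removal and addition is evaluated and the move with the
#' lowest AIC is applied, stopping when no move improves the current AIC.
#' Deterministic given the column order of `candidates`.
#'
#' @param candidates Data frame of candidate covariates (typically the
#'   dichotomized markers surviving [univariate_screen()] and [vif_screen()]).
#' @param time,event Survival outcome.
#' @return List with `fit` (a [cox_fit()], or `NULL` for the null model),
#'   `selected` (character vector of retained features), `aic`, and `path`
#'   (data frame logging every step).
#' @export
stepwise_aic <- function(candidates, time, event) {
  candidates <- as.data.frame(candidates)
  all_vars <- names(candidates)
  null_aic <- function() {
    f <- survival::coxph(survival::Surv(time, event) ~ 1)
    -2 * f$loglik[1]
  }
  aic_of <- function(vars) {
    if (!length(vars)) return(null_aic())
    f <- tryCatch(cox_fit(candidates[vars], time, event),
                  error = function(e) NULL)
    if (is.null(f)) Inf else f$aic
  }
  current <- all_vars
  cur_aic <- aic_of(current)
  path <- data.frame(step = 0L, action = "start",
                     variable = NA_character_, aic = cur_aic,
                     stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    step_i <- step_i + 1L
    moves <- data.frame(action = character(0), variable = character(0),
                        aic = numeric(0), stringsAsFactors = FALSE)
    for (v in current)
      moves <- rbind(moves, data.frame(action = "drop", variable = v,
                                       aic = aic_of(setdiff(current, v)),
                                       stringsAsFactors = FALSE))
    for (v in setdiff(all_vars, current))
      moves <- rbind(moves, data.frame(action = "add", variable = v,
                                       aic = aic_of(c(current, v)),
                                       stringsAsFactors = FALSE))
    if (!nrow(moves)) break
    best <- which.min(moves$aic)
    if (!length(best) || moves$aic[best] >= cur_aic - 1e-8) break
    if (moves$action[best] == "drop")
      current <- setdiff(current, moves$variable[best])
    else current <- c(current, moves$variable[best])
    cur_aic <- moves$aic[best]
    path <- rbind(path, data.frame(step = step_i, action = moves$action[best],
                                   variable = moves$variable[best],
                                   aic = cur_aic, stringsAsFactors = FALSE))
  }
  fit <- if (length(current)) cox_fit(candidates[current], time, event) else NULL
  list(fit = fit, selected = current, aic = cur_aic, path = path)
}

#' Linear risk score from a fitted Cox model
#'
#' The linear predictor \eqn{\sum_j \beta_j x_j} (no baseline hazard is
#' needed for ranking patients).
#'
#' @param fit A [cox_fit()].
#' @param features Data frame containing every feature of the fit.
#' @return Numeric score per row of `features`.
#' @export
risk_score <- function(fit, features) {
  stopifnot(inherits(fit, "cox_fit"))
  features <- as.data.frame(features)
  miss <- setdiff(fit$table$feature, names(features))
  if (length(miss)) stop("missing features: ", paste(miss, collapse = ", "))
  as.vector(as.matrix(features[fit$table$feature]) %*% fit$table$coef)
}

# right-continuous KM of the censoring distribution, and its left limit
censoring_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  g_right <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  g_left <- stats::stepfun(fit$time, c(1, fit$surv), right = TRUE)
  list(right = g_right, left = g_left)
}

#' Time-dependent AUROC of a risk score
#'
#' Cumulative-case / dynamic-control area under the time-dependent ROC curve
#' at each horizon, with inverse-probability-of-censoring weights from the
#' Kaplan-Meier estimator of the censoring distribution. Cases at horizon t
#' are subjects with an observed event by t; controls are subjects still
#' under observation beyond t. Tied scores count one half.
#'
#' @param score Risk scores (higher = higher risk).
#' @param time,event Survival outcome.
#' @param horizons Evaluation horizons in months.
#' @return Object of class `"td_roc"`: data frame with `horizon`, `auroc`,
#'   `n_cases`, `n_controls` (`auroc` is `NA` when either group is empty at
#'   the horizon).
#' @export
time_dependent_auroc <- function(score, time, event, horizons) {
  G <- censoring_km(time, event)
  out <- data.frame(horizon = horizons, auroc = NA_real_,
                    n_cases = NA_integer_, n_controls = NA_integer_)
  for (i in seq_along(horizons)) {
    h <- horizons[i]
    case <- time <= h & event == 1
    ctrl <- time > h
    out$n_cases[i] <- sum(case)
    out$n_controls[i] <- sum(ctrl)
    if (!any(case) || !any(ctrl)) next
    w <- 1 / G$left(time[case])
    if (any(!is.finite(w))) {
      ok <- is.finite(w)
      case_scores <- score[case][ok]; w <- w[ok]
      if (!length(w)) next
    } else case_scores <- score[case]
    sc <- sort(score[ctrl])
    less <- findInterval(case_scores, sc, left.open = TRUE)
    leq <- findInterval(case_scores, sc)
    conc <- less + 0.5 * (leq - less)
    out$auroc[i] <- sum(w * conc) / (sum(w) * length(sc))
  }
  class(out) <- c("td_roc", "data.frame")
  out
}

#' Time-dependent ROC curve at one horizon
#'
#' Sensitivity and 1-specificity over all score thresholds for the
#' cumulative-case / dynamic-control definition with IPCW case weights, for
#' plotting.
#'
#' @inheritParams time_dependent_auroc
#' @param horizon Single evaluation horizon in months.
#' @return Data frame with `threshold`, `fpr`, `tpr`.
#' @export
td_roc_curve <- function(score, time, event, horizon) {
  G <- censoring_km(time, event)
  case <- time <= horizon & event == 1
  ctrl <- time > horizon
  if (!any(case) || !any(ctrl)) stop("no cases or no controls at horizon")
  w <- 1 / G$left(time[case])
  w[!is.finite(w)] <- 0
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  tpr <- vapply(thr, function(cc) sum(w * (score[case] >= cc)) / sum(w), 0)
  fpr <- vapply(thr, function(cc) mean(score[ctrl] >= cc), 0)
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}
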