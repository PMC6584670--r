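test_that("log-rank matches the hand-computed 6-patient risk-set table", {
  # group A: (1, event), (3, event), (5, censored)
  # group B: (2, event), (4, censored), (6, event)
  time <- c(1, 3, 5, 2, 4, 6)
  event <- c(1, 1, 0, 1, 0, 1)
  group <- c(1, 1, 1, 0, 0, 0)
  # risk sets: t=1 n=6 n1=3 d=1; t=2 n=5 n1=2 d=1; t=3 n=4 n1=2 d=1;
  # t=6 n=1 n1=0 d=1 (variance term 0)
  # O = 2, E = 3/6 + 2/5 + 2/4 + 0 = 1.4
  # V = 0.25 + 0.24 + 0.25 + 0 = 0.74
  lr <- logrank_test(group, time, event)
  expect_equal(lr$observed, 2)
  expect_equal(lr$expected, 1.4)
  expect_equal(lr$chi2, 0.36 / 0.74, tolerance = 1e-12)
  expect_equal(lr$p, pchisq(0.36 / 0.74, 1, lower.tail = FALSE))
})

test_that("log-rank equals survdiff on random censored data with ties", {
  set.seed(30)
  for (rep in 1:20) {
    d <- random_survival(40, hr = sample(c(1, 2), 1))
    d$time <- round(d$time, 1) + 0.1          # force ties
    lr <- logrank_test(d$group, d$time, d$event)
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    expect_equal(lr$chi2, unname(sd$chisq), tolerance = 1e-9)
  }
  # no events at all -> zero statistic
  expect_equal(logrank_test(c(0, 0, 1, 1), c(1, 2, 3, 4), rep(0, 4))$chi2, 0)
})

test_that("optimal cutpoint equals exhaustive enumeration", {
  set.seed(31)
  for (rep in 1:10) {
    d <- random_survival(30)
    marker <- rnorm(30) + d$time / 10
    cp <- optimal_cutpoint(marker, d$time, d$event)
    bf <- brute_force_cutpoint(marker, d$time, d$event)
    expect_equal(cp$cutoff, bf$cutoff)
    expect_equal(cp$p, bf$p, tolerance = 1e-9)
    expect_equal(cp$n_low + cp$n_high, 30)
  }
})

test_that("cutpoint search separates a perfectly split marker and rejects degenerate input", {
  set.seed(32)
  time <- c(rexp(15, 0.5), rexp(15, 0.02))     # short vs long survivors
  event <- rep(1, 30)
  marker <- c(rnorm(15, 10), rnorm(15, 0))     # high marker = short survival
  cp <- optimal_cutpoint(marker, time, event)
  expect_gt(cp$cutoff, max(marker[16:30]) - 1e-9)
  expect_lt(cp$cutoff, min(marker[1:15]) + 1e-9)
  expect_error(optimal_cutpoint(rep(1, 30), time, event), "distinct")
  expect_error(optimal_cutpoint(marker[1:5], time[1:5], event[1:5]),
               "at least 10")
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  # (1,e) (2,c) (3,e) (4,c) (5,e): S = 0.8, 0.8, 8/15, 8/15, 0
  km <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
  expect_equal(km$surv[km$time == 1], 0.8)
  expect_equal(km$surv[km$time == 3], 0.8 * 2 / 3)
  expect_equal(km$surv[km$time == 5], 0)
  # Greenwood se at t=3
  s3 <- 0.8 * 2 / 3
  expect_equal(km$std_err[km$time == 3],
               s3 * sqrt(1 / (5 * 4) + 1 / (3 * 2)), tolerance = 1e-12)
  expect_equal(km$median, 5)                  # first time S <= 0.5

  no_ev <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(no_ev$surv == 1))
  expect_true(is.na(no_ev$median))

  all_ev <- km_estimate(1:4, rep(1, 4))
  expect_equal(all_ev$surv, 1 - (1:4) / 4)    # ECDF complement
})

test_that("Cox fit maximizes the partial likelihood and reports HR = exp(coef)", {
  x <- c(0, 0, 1, 1, 0, 1)
  time <- c(5, 8, 2, 3, 9, 1)
  event <- rep(1, 6)
  f <- cox_fit(data.frame(x = x), time, event)
  b <- f$table$coef[1]
  ll_hat <- cox_partial_loglik(b, x, time, event)
  for (db in c(-0.2, -0.05, 0.05, 0.2))
    expect_lte(cox_partial_loglik(b + db, x, time, event), ll_hat + 1e-8)
  expect_equal(f$loglik, ll_hat, tolerance = 1e-6)
  expect_equal(f$aic, -2 * ll_hat + 2, tolerance = 1e-6)
  expect_equal(f$table$hr, exp(f$table$coef), tolerance = 1e-12)
  expect_true(f$table$ci_low < f$table$hr & f$table$hr < f$table$ci_high)
})

test_that("Cox fit recovers a null effect and rejects bad designs", {
  set.seed(33)
  d <- random_survival(300, hr = 1)
  f <- cox_fit(data.frame(g = d$group), d$time, d$event)
  expect_true(f$table$ci_low[1] < 1 && 1 < f$table$ci_high[1])
  expect_error(cox_fit(data.frame(g = rep(1, 10)), rexp(10), rep(1, 10)),
               "constant")
  expect_error(cox_fit(data.frame(a = rnorm(5), b = rnorm(5), c = rnorm(5)),
                       rexp(5), c(1, 1, 0, 0, 0)), "fewer events")
})

test_that("univariate screen keeps true predictors and drops noise", {
  set.seed(34)
  d <- random_survival(150, hr = 3)
  feats <- data.frame(true = d$group, noise1 = rnorm(150),
                      noise2 = rnorm(150))
  sc <- univariate_screen(feats, d$time, d$event)
  expect_true(sc$selected[sc$feature == "true"])
  expect_equal(sc$hr, exp(sc$coef))
  empty <- univariate_screen(data.frame()[seq_len(10), , drop = FALSE],
                             rexp(10), rep(1, 10))
  expect_equal(nrow(empty), 0)
})

test_that("VIF matches the least-squares oracle and flags collinearity", {
  set.seed(35)
  x1 <- rnorm(50); x2 <- rnorm(50); x3 <- 0.8 * x1 + 0.6 * rnorm(50)
  v <- vif_screen(data.frame(x1, x2, x3))
  for (j in 1:3) {
    r2 <- summary(lm(
      as.matrix(data.frame(x1, x2, x3))[, j] ~
        as.matrix(data.frame(x1, x2, x3))[, -j]))$r.squared
    expect_equal(v$vif[j], 1 / (1 - r2), tolerance = 1e-8)
  }
  ortho <- vif_screen(data.frame(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1)))
  expect_equal(ortho$vif, c(1, 1))
  dup <- vif_screen(data.frame(a = x1, b = x1))
  expect_true(all(!is.finite(dup$vif) | dup$vif > 1e10))
  expect_true(all(dup$flag))
})

test_that("stepwise AIC keeps a strong predictor, descends monotonically, and nears best subset", {
  set.seed(36)
  kept <- 0L
  for (rep in 1:10) {
    d <- random_survival(120, hr = 4)
    cand <- data.frame(true = d$group, n1 = rnorm(120), n2 = rnorm(120),
                       n3 = rnorm(120))
    sw <- stepwise_aic(cand, d$time, d$event)
    if ("true" %in% sw$selected) kept <- kept + 1L
    expect_true(all(diff(sw$path$aic) < 0))   # AIC strictly improves
  }
  expect_gte(kept, 9L)

  # exhaustive best-subset oracle on 6 candidates
  set.seed(37)
  d <- random_survival(80, hr = 2.5)
  cand <- data.frame(true = d$group, a = rnorm(80), b = rnorm(80),
                     c = rnorm(80), e = rnorm(80), f = rnorm(80))
  sw <- stepwise_aic(cand, d$time, d$event)
  vars <- names(cand)
  best_aic <- Inf
  for (mask in 0:(2^6 - 1)) {
    vv <- vars[bitwAnd(mask, 2^(0:5)) > 0]
    aic <- if (!length(vv)) {
      f0 <- survival::coxph(survival::Surv(d$time, d$event) ~ 1)
      -2 * f0$loglik[1]
    } else cox_fit(cand[vv], d$time, d$event)$aic
    best_aic <- min(best_aic, aic)
  }
  expect_lte(sw$aic, best_aic + 2)

  nullm <- stepwise_aic(cand[0], d$time, d$event)
  expect_null(nullm$fit)
  expect_equal(nullm$selected, character(0))
})

test_that("risk scores are linear and invariant in ranking to monotone maps", {
  set.seed(38)
  d <- random_survival(60, hr = 3)
  f <- cox_fit(data.frame(g = d$group, z = rnorm(60)), d$time, d$event)
  zero <- risk_score(f, data.frame(g = rep(0, 3), z = rep(0, 3)))
  expect_equal(zero, rep(0, 3))
  nd <- data.frame(g = c(1, 0), z = c(0.5, -2))
  expect_equal(risk_score(f, nd),
               as.vector(as.matrix(nd) %*% f$table$coef))
  expect_error(risk_score(f, data.frame(g = 1)), "missing")

  sc <- risk_score(f, data.frame(g = d$group, z = rnorm(60)))
  a1 <- time_dependent_auroc(sc, d$time, d$event, 10)$auroc
  a2 <- time_dependent_auroc(exp(sc / 2), d$time, d$event, 10)$auroc
  expect_equal(a1, a2)
})

test_that("time-dependent AUROC matches pairwise enumeration and its extremes", {
  set.seed(39)
  n <- 150
  time <- rexp(n, 0.05)
  event <- rep(1, n)                           # no censoring
  score <- rnorm(n) - time / 15
  for (h in c(5, 15, 30)) {
    td <- time_dependent_auroc(score, time, event, h)
    case <- time <= h; ctrl <- time > h
    pairs <- outer(score[case], score[ctrl],
                   function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(td$auroc, mean(pairs), tolerance = 1e-12)
  }
  # perfect discrimination: score = reversed survival-time rank
  perf <- time_dependent_auroc(-rank(time), time, event, c(5, 15))
  expect_equal(perf$auroc, c(1, 1))
  # undefined when there are no controls beyond the horizon
  und <- time_dependent_auroc(score, time, event, max(time) + 1)
  expect_true(is.na(und$auroc))
  cur <- td_roc_curve(score, time, event, 15)
  expect_equal(cur$tpr[1], 0)
  expect_equal(max(cur$tpr), 1)
  expect_true(all(diff(cur$fpr) >= 0))
})

test_that("minimum-p cutpoint selection is anticonservative under the null", {
  # scanning cutoffs and keeping the smallest p inflates the type-I error
  # well beyond the nominal 5%; this is why permutation adjustment exists
  set.seed(40)
  naive_sig <- 0L
  for (rep in 1:200) {
    time <- rexp(40, 0.05)
    event <- as.integer(rexp(40, 0.0125) > time)
    cp <- optimal_cutpoint(rnorm(40), time, event)
    if (cp$p < 0.05) naive_sig <- naive_sig + 1L
  }
  expect_gt(naive_sig / 200, 0.10)

  # the permutation-adjusted p restores approximately nominal behavior
  set.seed(44)
  adj_sig <- 0L
  for (rep in 1:60) {
    time <- rexp(40, 0.05)
    event <- as.integer(rexp(40, 0.0125) > time)
    cp <- optimal_cutpoint(rnorm(40), time, event, n_perm = 99L)
    if (cp$p_adjusted < 0.05) adj_sig <- adj_sig + 1L
  }
  expect_lte(adj_sig / 60, 0.15)
})
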