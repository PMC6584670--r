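# Independent oracles and fixture builders shared across the suite.

# exact integral of the piecewise-linear interpolant via fine-grid
# trapezoidal quadrature (knots included so the quadrature is exact up to
# floating point)
quadrature_auc1 <- function(times, values, n_fine = 2000) {
  g <- sort(unique(c(times, seq(min(times), max(times), length.out = n_fine))))
  v <- approx(times, values, xout = g)$y
  sum((v[-1] + v[-length(v)]) / 2 * diff(g))
}

# signed variant: per observed segment, quadrature of the interpolant with
# the sign of the segment's increment (non-positive increments subtract)
quadrature_auc2 <- function(times, values, n_fine = 500) {
  total <- 0
  for (i in seq_len(length(times) - 1L)) {
    a <- quadrature_auc1(times[i:(i + 1)], values[i:(i + 1)], n_fine)
    s <- if (values[i + 1] - values[i] > 0) 1 else -1
    total <- total + s * a
  }
  total
}

# brute-force most-significant log-rank cutpoint using survival::survdiff
brute_force_cutpoint <- function(marker, time, event, min_group_frac = 0.1) {
  n <- length(marker)
  sv <- sort(unique(marker))
  cand <- (sv[-length(sv)] + sv[-1]) / 2
  best <- NULL
  for (cc in cand) {
    hi <- marker > cc
    if (sum(hi) < min_group_frac * n || sum(!hi) < min_group_frac * n) next
    sd <- survival::survdiff(survival::Surv(time, event) ~ hi)
    p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    if (is.null(best) || p < best$p - 1e-15) best <- list(cutoff = cc, p = p)
  }
  best
}

# random censored survival dataset with a binary group effect
random_survival <- function(n, hr = 1, censor_rate = 0.3) {
  g <- rep(c(0, 1), length.out = n)
  t_event <- rexp(n, rate = 0.05 * hr^g)
  t_cens <- rexp(n, rate = 0.05 * censor_rate / (1 - censor_rate))
  data.frame(group = g, time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

# Cox partial likelihood (log scale, Breslow would differ only under ties;
# the fixtures below are tie-free) for a single covariate
cox_partial_loglik <- function(beta, x, time, event) {
  o <- order(time)
  x <- x[o]; ev <- event[o]
  eta <- beta * x
  ll <- 0
  for (i in seq_along(x)) {
    if (ev[i] != 1) next
    ll <- ll + eta[i] - log(sum(exp(eta[i:length(x)])))
  }
  ll
}
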