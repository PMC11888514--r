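# Closed-form / numerical-integration oracles for the synthetic generator,
# independent of the package's sampling code.

# probability that a single urine sample drawn at daily dose d classifies
# above threshold (OR over the two biomarkers)
p_above_given_dose <- function(d, params, thresholds = cosmos_thresholds()) {
  dr <- params$dose_response
  g <- dr[dr$biomarker == "gvlm", ]
  s <- dr[dr$biomarker == "srem", ]
  zg <- (log2(thresholds$t_gvlm) - (g$intercept + g$slope * d)) / g$sd
  zs <- (log2(thresholds$t_srem) - (s$intercept + s$slope * d)) / s$sd
  out <- 1 - pnorm(zg) * pnorm(zs)
  out[d <= 0] <- 0  # zero intake draws sit below the LOQ, below any threshold
  out
}

# expectation of f(dose) over the background-dose mixture given the background
# class probabilities; the moderate lognormal is capped (not rejected) at
# dose_ref - 1, so the cap point carries the upper tail mass
mixture_expectation <- function(f, params, shift = 0) {
  cap <- params$dose_ref - 1
  mu <- params$background_moderate_meanlog
  sg <- params$background_moderate_sdlog
  mod <- stats::integrate(function(d) f(d + shift) * stats::dlnorm(d, mu, sg),
                          0, cap, rel.tol = 1e-9)$value +
    (1 - stats::plnorm(cap, mu, sg)) * f(cap + shift)
  lo <- params$background_high_range[1]
  hi <- params$background_high_range[2]
  high <- stats::integrate(function(d) f(d + shift) / (hi - lo), lo, hi,
                           rel.tol = 1e-9)$value
  params$p_background_high * high +
    (1 - params$p_background_high - params$p_background_zero) * mod +
    params$p_background_zero * f(shift)
}

# oracle for the fraction of baseline samples above threshold
oracle_baseline_above <- function(params, thresholds = cosmos_thresholds()) {
  mixture_expectation(function(d) p_above_given_dose(d, params, thresholds), params)
}

# oracle for biomarker-measured adherence: share of intervention-arm
# participants with follow-up samples classified above at any follow-up visit;
# visit count is 1 + Binomial(2, 0.35), noise independent across visits
oracle_biomarker_adherence <- function(params, thresholds = cosmos_thresholds()) {
  p_any <- function(d) {
    p1 <- p_above_given_dose(d, params, thresholds)
    k <- 1 + 0:2
    w <- stats::dbinom(0:2, 2, 0.35)
    sum(w * (1 - (1 - p1)^k))
  }
  p_any_v <- Vectorize(p_any)
  adh <- mixture_expectation(p_any_v, params, shift = params$dose_ref)
  non <- mixture_expectation(p_any_v, params, shift = 0)
  params$p_adherent * adh + (1 - params$p_adherent) * non
}

# small cohorts for fast unit tests
small_params <- function(...) {
  cohort_params(n_total = 800, seed = 99, ...)
}

# explicit Cox partial log-likelihood for untied data (Breslow/Efron coincide)
cox_logpl <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  n <- length(time)
  sapply(beta, function(b) {
    eta <- b * x
    ll <- 0
    for (i in seq_len(n)) {
      if (event[i]) {
        risk <- time >= time[i]
        ll <- ll + eta[i] - log(sum(exp(eta[risk])))
      }
    }
    ll
  })
}

# two-stage grid maximization of the partial likelihood
cox_grid_mle <- function(time, event, x, lo = -4, hi = 4) {
  g1 <- seq(lo, hi, by = 1e-3)
  b1 <- g1[which.max(cox_logpl(g1, time, event, x))]
  g2 <- seq(b1 - 2e-3, b1 + 2e-3, by = 1e-6)
  g2[which.max(cox_logpl(g2, time, event, x))]
}
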