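# shared fixtures built once per test run; everything is generated in code

# moderate cohort with 10 planted sites (+/-0.7 log-HR per SD)
fixture_cohort <- simulate_cohort(sim_config(n_sites = 300, seed = 42))

# fully null cohort: no methylation signal, no covariate effects
fixture_null_cohort <- simulate_cohort(
  sim_config(n_sites = 300, n_causal_sites = 0,
             covariate_effects = numeric(0), seed = 77))

# small survival fixture with ties and a mix of events/censorings
make_survival_fixture <- function(n = 40, seed = 7, tie_grid = NULL) {
  set.seed(seed)
  te <- rexp(n, 0.15)
  tc <- rexp(n, 0.2)
  t_obs <- pmin(te, tc, 5)
  if (!is.null(tie_grid)) t_obs <- ceiling(t_obs * tie_grid) / tie_grid
  list(times = t_obs,
       events = as.numeric(te <= pmin(tc, 5)),
       x = cbind(a = rnorm(n), b = rbinom(n, 1, 0.4)),
       w = runif(n, 0.5, 3))
}

# brute-force weighted Mann-Whitney AUC (tie = 1/2)
auc_mann_whitney <- function(pred, outcome, weights = rep(1, length(pred))) {
  pos <- which(outcome == 1); neg <- which(outcome == 0)
  num <- 0
  for (i in pos) for (j in neg) {
    num <- num + weights[i] * weights[j] *
      ((pred[i] > pred[j]) + 0.5 * (pred[i] == pred[j]))
  }
  num / (sum(weights[pos]) * sum(weights[neg]))
}

# brute-force two-group log-rank via per-event-time O-E tables
logrank_oracle <- function(times, events, groups) {
  g <- as.integer(factor(groups)) - 1L
  ev_times <- sort(unique(times[events == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    d <- sum(events == 1 & times == t)
    d1 <- sum(events == 1 & times == t & g == 1)
    n_all <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n_all
    if (n_all > 1) {
      v <- v + d * (n1 / n_all) * (1 - n1 / n_all) * (n_all - d) / (n_all - 1)
    }
  }
  chi2 <- o_minus_e^2 / v
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}
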