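#' Dichotomize predicted risk at a cutoff
#'
#' High-risk iff `predicted_risk > cutoff` (strict: values exactly at the
#' cutoff are the last acceptable "negative" and go to the low group).
#'
#' @param predicted_risk numeric risks.
#' @param cutoff finite cutoff.
#' @return factor with levels `low`, `high`.
#' @export
dichotomize <- function(predicted_risk, cutoff) {
  stopifnot(is.finite(cutoff))
  factor(ifelse(predicted_risk > cutoff, "high", "low"),
         levels = c("low", "high"))
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank statistic comparing observed with expected
#' events under the pooled hazard, chi-squared with 1 df (via
#' [survival::survdiff()]).
#'
#' @param times follow-up times.
#' @param events 0/1 event indicator.
#' @param groups two-level grouping.
#' @return list with `chi2` and `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) != 2) stop("exactly two groups required")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  list(chi2 = unname(sd$chisq),
       p = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Weighted-Cox hazard ratio between two risk strata
#'
#' Single-covariate weighted Cox fit of the high-vs-low group indicator
#' (reusing [weighted_cox_fit()]); the Wald 95% CI is formed on the log
#' scale and exponentiated. If one group has no events the partial
#' likelihood is monotone: the result is flagged `degenerate` and carries
#' the one-sided Wald bound from the stopped fit.
#'
#' @param times follow-up times.
#' @param events 0/1 event indicator.
#' @param group_indicator two-level grouping (reference = first level).
#' @param weights sampling weights `w_samp` (default all 1).
#' @return list with `hr`, `ci95`, `p`, `log_hr`, `se`, `degenerate`.
#' @export
strata_hazard_ratio <- function(times, events, group_indicator,
                                weights = NULL) {
  g <- factor(group_indicator)
  if (nlevels(droplevels(g)) != 2) stop("exactly two groups required")
  x <- cbind(group = as.numeric(g == levels(g)[2]))
  degenerate <- any(tapply(events, g, sum) == 0)
  if (degenerate) {
    warning("no events in one group: monotone likelihood, ",
            "hazard ratio is a one-sided bound")
  }
  fit <- weighted_cox_fit(x, times, events, weights)
  b <- unname(coef(fit)[1]); s <- unname(fit$se[1])
  list(hr = exp(b),
       ci95 = exp(c(b - qnorm(0.975) * s, b + qnorm(0.975) * s)),
       p = unname(fit$p[1]), log_hr = b, se = s,
       degenerate = degenerate || !fit$converged)
}

#' Survival stratification of a risk score
#'
#' Splits samples into low/high risk at `cutoff`, and quantifies separation
#' by per-group Kaplan-Meier curves, the (unweighted) log-rank test, and a
#' weighted-Cox hazard ratio of high vs low.
#'
#' @param times follow-up times.
#' @param events 0/1 event indicator.
#' @param predicted_risk risk score per sample.
#' @param cutoff risk cutoff (e.g. the Youden cutoff).
#' @param weights sampling weights for the Cox hazard ratio (default all 1).
#' @return object of class `strata_result`: list with `groups`, `n_low`,
#'   `n_high`, `km_low`, `km_high`, `logrank_chi2`, `logrank_p`, `hr`,
#'   `hr_ci95`, `hr_p`, `degenerate`.
#' @export
survival_strata <- function(times, events, predicted_risk, cutoff,
                            weights = NULL) {
  g <- dichotomize(predicted_risk, cutoff)
  if (nlevels(droplevels(g)) != 2) {
    stop("cutoff does not split the sample into two groups")
  }
  lr <- logrank_test(times, events, g)
  hr <- strata_hazard_ratio(times, events, g, weights)
  low <- g == "low"
  structure(list(groups = g, n_low = sum(low), n_high = sum(!low),
                 km_low = km_estimator(times[low], events[low]),
                 km_high = km_estimator(times[!low], events[!low]),
                 logrank_chi2 = lr$chi2, logrank_p = lr$p,
                 hr = hr$hr, hr_ci95 = hr$ci95, hr_p = hr$p,
                 degenerate = hr$degenerate),
            class = "strata_result")
}

#' @export
print.strata_result <- function(x, ...) {
  cat(sprintf("Risk strata: n_low = %d, n_high = %d\n", x$n_low, x$n_high))
  cat(sprintf("log-rank chi2 = %.2f, p = %.3g\n", x$logrank_chi2,
              x$logrank_p))
  cat(sprintf("weighted-Cox HR (high vs low) = %.2f (95%% CI %.2f-%.2f), p = %.3g%s\n",
              x$hr, x$hr_ci95[1], x$hr_ci95[2], x$hr_p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Kaplan-Meier curve coordinates for plotting
#' @param x a `strata_result`.
#' @param path output CSV path (`group`, `time`, `survival`).
#' @export
write_km_curves <- function(x, path) {
  df <- rbind(
    data.frame(group = "low", time = c(0, x$km_low$times),
               survival = c(1, x$km_low$survival)),
    data.frame(group = "high", time = c(0, x$km_high$times),
               survival = c(1, x$km_high$survival)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
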