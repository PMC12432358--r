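#' Empirical ROC curve and AUC
#'
#' Step-function ROC over all observed thresholds with the classification
#' rule "positive if predicted > threshold" (thresholds are the distinct
#' predicted values in decreasing order, closed by -Inf so the curve runs
#' from (0,0) to (1,1)). AUC is the trapezoid area, which for unweighted
#' input equals the Mann-Whitney U statistic divided by n1*n2 (ties counted
#' one half). Optional per-sample weights enter the empirical counts on both
#' axes.
#'
#' @param predicted numeric risk scores.
#' @param outcome 0/1 outcome; both classes must be present.
#' @param weights optional non-negative weights.
#' @return object of class `roc_curve`: list with `thresholds`, `fpr`,
#'   `tpr`, `auc`.
#' @export
roc_curve <- function(predicted, outcome, weights = NULL) {
  n <- length(predicted)
  stopifnot(length(outcome) == n, all(outcome %in% c(0, 1)))
  if (length(unique(outcome)) < 2) stop("both outcome classes are required")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(all(weights >= 0), length(weights) == n)
  ord <- order(predicted, decreasing = TRUE)
  p <- predicted[ord]; y <- outcome[ord]; w <- weights[ord]
  cum_tp <- cumsum(w * y)
  cum_fp <- cumsum(w * (1 - y))
  last <- which(!duplicated(p, fromLast = TRUE))  # last index of each value
  tot_p <- sum(w * y); tot_n <- sum(w * (1 - y))
  tpr <- c(0, cum_tp[last] / tot_p)
  fpr <- c(0, cum_fp[last] / tot_n)
  # point k pairs with threshold v_k (rule "pred > t"); the final (1,1)
  # point corresponds to -Inf
  thresholds <- c(p[last], -Inf)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(thresholds = thresholds, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Precision-recall curve
#'
#' Precision and recall over the same decreasing thresholds as
#' [roc_curve()]; precision at the empty-positive end is 1 by convention.
#'
#' @inheritParams roc_curve
#' @return list with `thresholds`, `recall`, `precision`.
#' @export
pr_curve <- function(predicted, outcome, weights = NULL) {
  n <- length(predicted)
  stopifnot(length(outcome) == n, all(outcome %in% c(0, 1)))
  if (length(unique(outcome)) < 2) stop("both outcome classes are required")
  if (is.null(weights)) weights <- rep(1, n)
  ord <- order(predicted, decreasing = TRUE)
  p <- predicted[ord]; y <- outcome[ord]; w <- weights[ord]
  cum_tp <- cumsum(w * y)
  cum_pos <- cumsum(w)
  last <- which(!duplicated(p, fromLast = TRUE))
  recall <- c(0, cum_tp[last] / sum(w * y))
  precision <- c(1, cum_tp[last] / cum_pos[last])
  list(thresholds = c(p[last], -Inf), recall = recall,
       precision = precision)
}

#' Compare two paired AUCs (DeLong's test)
#'
#' Two-sided DeLong test for the difference between correlated AUCs of two
#' risk models evaluated on the same samples (via [pROC::roc.test()]).
#' Identical prediction vectors return p = 1 with zero difference.
#'
#' @param pred_a,pred_b predicted risks from the two models.
#' @param outcome shared 0/1 outcome.
#' @return list with `auc_a`, `auc_b`, `diff`, `p`.
#' @export
compare_auc <- function(pred_a, pred_b, outcome) {
  stopifnot(length(pred_a) == length(pred_b),
            length(pred_a) == length(outcome))
  auc_a <- roc_curve(pred_a, outcome)$auc
  auc_b <- roc_curve(pred_b, outcome)$auc
  if (isTRUE(all.equal(pred_a, pred_b))) {
    return(list(auc_a = auc_a, auc_b = auc_b, diff = 0, p = 1))
  }
  ra <- pROC::roc(outcome, pred_a, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  rb <- pROC::roc(outcome, pred_b, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  list(auc_a = auc_a, auc_b = auc_b, diff = auc_a - auc_b,
       p = unname(tst$p.value))
}

#' Youden-index screening cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 over the observed ROC
#' thresholds (the point with the largest vertical distance from the chance
#' line); ties are broken toward the lower cutoff. A warning is issued when
#' even the best threshold has J <= 0 (anti-predictive scores).
#'
#' @param roc a `roc_curve`.
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden_j`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  j <- roc$tpr - roc$fpr
  best <- max(j)
  # thresholds are decreasing: the last maximizer is the lowest cutoff
  k <- max(which(j == best))
  if (best <= 0) warning("anti-predictive scores: best Youden J <= 0")
  list(cutoff = roc$thresholds[k], sensitivity = roc$tpr[k],
       specificity = 1 - roc$fpr[k], youden_j = best)
}

# round half away from zero (printed confusion counts)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Screening-test report at a given sensitivity/specificity
#'
#' Expands a screening test's sensitivity and specificity into confusion
#' counts and prevalence-based predictive values. Counts are rounded half
#' away from zero; PPV, NPV and accuracy follow Bayes' rule,
#' \deqn{PPV = \frac{se \cdot \pi}{se \cdot \pi + (1-sp)(1-\pi)}, \quad
#'       NPV = \frac{sp (1-\pi)}{sp (1-\pi) + (1-se) \pi},}
#' evaluated at the prevalence rounded to 0.1% — the precision at which a
#' screening report quotes prevalence — so the printed metrics are mutually
#' consistent at one-decimal precision.
#'
#' @param sensitivity,specificity proportions in \[0,1\].
#' @param n_events,n_controls positive class counts.
#' @param cutoff optional risk cutoff the test operates at (recorded only).
#' @return object of class `screening_report`: list with `cutoff`,
#'   `sensitivity`, `specificity`, `tp`, `fn`, `tn`, `fp`, `prevalence`
#'   (exact), `ppv`, `npv`, `accuracy`.
#' @export
screening_metrics <- function(sensitivity, specificity, n_events,
                              n_controls, cutoff = NA_real_) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            n_events > 0, n_controls > 0)
  tp <- as.integer(round_half_up(sensitivity * n_events))
  tn <- as.integer(round_half_up(specificity * n_controls))
  n_events <- as.integer(n_events)
  n_controls <- as.integer(n_controls)
  prev <- n_events / (n_events + n_controls)
  pr <- round(prev, 3)
  ppv <- sensitivity * pr / (sensitivity * pr + (1 - specificity) * (1 - pr))
  npv <- specificity * (1 - pr) /
    (specificity * (1 - pr) + (1 - sensitivity) * pr)
  structure(list(cutoff = cutoff, sensitivity = sensitivity,
                 specificity = specificity,
                 tp = tp, fn = n_events - tp, tn = tn, fp = n_controls - tn,
                 prevalence = prev, ppv = ppv, npv = npv,
                 accuracy = sensitivity * pr + specificity * (1 - pr)),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Screening test report\n")
  if (is.finite(x$cutoff)) cat(sprintf("  cutoff:      %.4g\n", x$cutoff))
  cat(sprintf("  sensitivity: %.1f%%   specificity: %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  cat(sprintf("  TP %d  FN %d  TN %d  FP %d\n", x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("  prevalence:  %.1f%%\n", 100 * x$prevalence))
  cat(sprintf("  PPV %.1f%%  NPV %.1f%%  accuracy %.1f%%\n",
              100 * x$ppv, 100 * x$npv, 100 * x$accuracy))
  invisible(x)
}

# proportion moving up/down and the standard error of their difference
.nri_component <- function(up, down) {
  n <- length(up)
  pu <- mean(up); pd <- mean(down)
  list(est = pu - pd, var = (pu + pd - (pu - pd)^2) / n)
}

#' Net reclassification improvement and integrated discrimination improvement
#'
#' Quantifies the added predictive value of a new risk model over a base
#' model. The categorical NRI uses two risk categories split at
#' `category_cutoff`: NRI = \[P(up|event) - P(down|event)\] +
#' \[P(down|nonevent) - P(up|nonevent)\]. The continuous NRI counts any
#' increase/decrease of predicted risk. IDI is the difference in
#' discrimination slopes, (mean new - mean base | events) - (mean new -
#' mean base | nonevents). Standard errors are the usual asymptotic
#' estimators with Wald 95% CIs and two-sided p-values.
#'
#' @param pred_base,pred_new predicted risks from the base and new models
#'   (aligned samples).
#' @param outcome 0/1 outcome with at least one event and one nonevent.
#' @param category_cutoff risk cutoff defining the two categories for the
#'   categorical NRI.
#' @return object of class `reclassification_report`: for each of
#'   `nri_categorical`, `nri_continuous` and `idi` a list with `estimate`,
#'   `se`, `ci95`, `p` (the NRIs also carry their event / nonevent
#'   components, which sum to the estimate).
#' @export
nri_idi <- function(pred_base, pred_new, outcome, category_cutoff) {
  n <- length(outcome)
  stopifnot(length(pred_base) == n, length(pred_new) == n,
            all(outcome %in% c(0, 1)))
  if (sum(outcome) == 0 || sum(outcome) == n) {
    stop("both events and nonevents are required")
  }
  ev <- outcome == 1

  wrap <- function(est, se) {
    list(estimate = est, se = se,
         ci95 = c(est - qnorm(0.975) * se, est + qnorm(0.975) * se),
         p = 2 * pnorm(-abs(est / se)))
  }
  nri_from <- function(up, down) {
    e <- .nri_component(up[ev], down[ev])
    ne <- .nri_component(down[!ev], up[!ev])
    out <- wrap(e$est + ne$est, sqrt(e$var + ne$var))
    out$event_component <- e$est
    out$nonevent_component <- ne$est
    out
  }

  cat_base <- pred_base > category_cutoff
  cat_new <- pred_new > category_cutoff
  nri_cat <- nri_from(up = !cat_base & cat_new, down = cat_base & !cat_new)
  nri_cont <- nri_from(up = pred_new > pred_base, down = pred_new < pred_base)

  d <- pred_new - pred_base
  idi_est <- mean(d[ev]) - mean(d[!ev])
  idi_se <- sqrt(var(d[ev]) / sum(ev) + var(d[!ev]) / sum(!ev))
  idi <- if (idi_se == 0) {
    list(estimate = idi_est, se = 0, ci95 = c(idi_est, idi_est),
         p = if (idi_est == 0) 1 else 0)
  } else wrap(idi_est, idi_se)
  if (all(d == 0)) {  # identical models: degenerate but well-defined
    nri_cat$p <- nri_cont$p <- 1
  }

  structure(list(nri_categorical = nri_cat, nri_continuous = nri_cont,
                 idi = idi, category_cutoff = category_cutoff),
            class = "reclassification_report")
}

#' @export
print.reclassification_report <- function(x, ...) {
  fmt <- function(lab, m) {
    cat(sprintf("  %-16s %6.3f  (95%% CI %.3f to %.3f, p = %.3g)\n",
                lab, m$estimate, m$ci95[1], m$ci95[2], m$p))
  }
  cat(sprintf("Reclassification report (category cutoff = %.4g)\n",
              x$category_cutoff))
  fmt("categorical NRI", x$nri_categorical)
  fmt("continuous NRI", x$nri_continuous)
  fmt("IDI", x$idi)
  invisible(x)
}
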