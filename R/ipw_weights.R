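#' Inverse-probability-of-sampling weights
#'
#' Each sampled subject is weighted by the ratio of the stratum's size in the
#' full source cohort to its size in the analysis sample: controls get
#' `cohort_controls / sample_controls`, cases `cohort_cases / sample_cases`.
#' When the analysis sample is the whole cohort all weights are 1.
#'
#' @param cohort_counts named list/vector with `controls` and `cases`: stratum
#'   sizes in the whole source cohort.
#' @param sample_counts same structure for the analysis sample; must not
#'   exceed `cohort_counts` componentwise. Defaults to the counts observed in
#'   `phenotypes`.
#' @param phenotypes phenotype table (uses `event` and `sample_id`).
#' @return named numeric vector of sampling weights, one per sample.
#' @export
sampling_weights <- function(cohort_counts, phenotypes,
                             sample_counts = list(
                               controls = sum(phenotypes$event == 0),
                               cases = sum(phenotypes$event == 1))) {
  for (s in c("controls", "cases")) {
    if (sample_counts[[s]] == 0) {
      stop("zero sampled subjects in stratum '", s, "'")
    }
    if (sample_counts[[s]] > cohort_counts[[s]]) {
      stop("sample count exceeds cohort count in stratum '", s, "'")
    }
  }
  n_ctrl <- sum(phenotypes$event == 0)
  n_case <- sum(phenotypes$event == 1)
  if (n_ctrl != sample_counts$controls || n_case != sample_counts$cases) {
    stop("sample_counts do not match the phenotype table")
  }
  w <- ifelse(phenotypes$event == 1,
              cohort_counts$cases / sample_counts$cases,
              cohort_counts$controls / sample_counts$controls)
  setNames(w, phenotypes$sample_id)
}

#' Kaplan-Meier product-limit estimator
#'
#' Thin wrapper over [survival::survfit()] returning the estimate in a plain
#' evaluable form. `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` with (optionally
#' weighted) event counts `d` and at-risk counts `n`; at tied times events
#' precede censorings. Which indicator counts as "the event" is the caller's
#' choice, so the same estimator serves both the event-free survival curve
#' and the censoring distribution used for IPCW.
#'
#' @param times positive follow-up times.
#' @param events 0/1 indicator of the event of interest.
#' @param weights optional positive case weights.
#' @return object of class `km_estimate` with components `times` (distinct
#'   event times), `survival`, `at_risk`, `events`, and `n`.
#' @export
km_estimator <- function(times, events, weights = NULL) {
  n <- length(times)
  if (n == 0) stop("empty input")
  stopifnot(length(events) == n, all(events %in% c(0, 1)), all(times > 0))
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(all(weights > 0), length(weights) == n)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           weights = weights)
  keep <- fit$n.event > 0
  structure(list(times = fit$time[keep], survival = fit$surv[keep],
                 at_risk = fit$n.risk[keep], events = fit$n.event[keep],
                 n = n),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: %d subjects, %d distinct event times\n",
              x$n, length(x$times)))
  if (length(x$times)) {
    cat(sprintf("final S(%.3g) = %.4f\n", max(x$times), min(x$survival)))
  }
  invisible(x)
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param km a `km_estimate`.
#' @param t times at which to evaluate.
#' @param left if `TRUE` return the left limit `S(t-)` (steps strictly before
#'   `t`); default is the right-continuous value `S(t)`.
#' @return survival probabilities at `t`.
#' @export
km_survival <- function(km, t, left = FALSE) {
  vapply(t, function(ti) {
    idx <- if (left) km$times < ti else km$times <= ti
    if (!any(idx)) 1 else km$survival[max(which(idx))]
  }, numeric(1))
}

#' Inverse-probability-of-censoring weights for a fixed-horizon endpoint
#'
#' Censoring is treated as the event of interest and its Kaplan-Meier
#' distribution `G(t)` (probability of remaining uncensored) estimated;
#' administrative end of follow-up at the horizon is not counted as
#' censoring. Each censored subject's contribution is thereby redistributed
#' among the subjects still at risk at the censoring time:
#' subjects observed to have the event at time `T` receive `1/G(T-)`,
#' subjects followed event-free to the horizon receive `1/G(horizon-)`, and
#' subjects censored event-free before the horizon receive weight 0 (they
#' can also be retained with weight `1/G(C-)` via `drop_censored = FALSE`).
#' `G` is clipped below at `floor` to cap the weights.
#'
#' @param times observed follow-up times.
#' @param events 0/1 event indicator.
#' @param horizon end of study (years); must be at least the largest event
#'   time.
#' @param floor lower clip for `G` (default 0.05, capping weights at 20).
#' @param drop_censored give early-censored subjects weight 0 (default) or
#'   their own inverse probability.
#' @return numeric vector of censoring weights.
#' @export
censoring_weights <- function(times, events, horizon, floor = 0.05,
                              drop_censored = TRUE) {
  stopifnot(length(times) == length(events), all(events %in% c(0, 1)))
  if (horizon < max(times[events == 1], -Inf)) {
    stop("horizon must be >= the largest observed event time")
  }
  eps <- sqrt(.Machine$double.eps) * max(times, horizon)
  censored <- as.numeric(events == 0 & times < horizon - eps)
  w <- numeric(length(times))
  if (!any(censored == 1)) {
    return(rep(1, length(times)))
  }
  # tie rule "event precedes censoring": subjects with an event at t leave
  # the censoring risk set just before censorings at t, which makes the
  # inverse-weighted event frequency reproduce the Kaplan-Meier event
  # probability exactly
  t_g <- times - 2 * eps * (events == 1)
  G <- km_estimator(t_g, censored)
  g <- function(t) pmax(km_survival(G, t, left = TRUE), floor)
  raw <- km_survival(G, times, left = TRUE)
  n_clip <- sum(raw[censored == 0 | !drop_censored] < floor)
  if (n_clip > 0) {
    warning(sprintf("censoring survival clipped at %.3g for %d subject(s)",
                    floor, n_clip))
  }
  is_event <- events == 1
  to_horizon <- events == 0 & censored == 0
  w[is_event] <- 1 / g(times[is_event])
  w[to_horizon] <- 1 / g(rep(horizon, sum(to_horizon)))
  w[censored == 1] <- if (drop_censored) 0 else 1 / g(times[censored == 1])
  w
}

#' Combine sampling and censoring weights
#'
#' The final weights for the logistic-regression stage are the elementwise
#' product `w_final = w_samp * w_cens`; the Cox stage consumes `w_samp`
#' alone (censoring is handled by the partial likelihood itself).
#'
#' @param w_samp named vector of sampling weights (all > 0).
#' @param w_cens named vector of censoring weights (same samples, >= 0).
#' @return object of class `weight_set`: data frame with `sample_id`,
#'   `w_samp`, `w_cens`, `w_final`.
#' @export
combine_weights <- function(w_samp, w_cens) {
  if (is.null(names(w_samp)) || is.null(names(w_cens))) {
    if (length(w_samp) != length(w_cens)) stop("weight vectors differ in length")
    ids <- names(w_samp) <- names(w_cens) <-
      if (!is.null(names(w_samp))) names(w_samp) else
        sprintf("S%03d", seq_along(w_samp))
  }
  if (!setequal(names(w_samp), names(w_cens))) {
    stop("sample IDs of w_samp and w_cens do not match")
  }
  w_cens <- w_cens[names(w_samp)]
  stopifnot(all(w_samp > 0), all(w_cens >= 0))
  structure(data.frame(sample_id = names(w_samp), w_samp = unname(w_samp),
                       w_cens = unname(w_cens),
                       w_final = unname(w_samp * w_cens),
                       stringsAsFactors = FALSE),
            class = c("weight_set", "data.frame"))
}

#' @rdname combine_weights
#' @param x a `weight_set`.
#' @param path output CSV path.
#' @export
write_weights <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
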