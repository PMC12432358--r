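# run code with a temporary RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Stratified k-fold assignment
#'
#' Splits samples into `k` folds stratifying jointly on event status and
#' gender: within each event-by-gender cell, shuffled samples are dealt
#' round-robin, so per-cell fold counts differ by at most one. If `k`
#' exceeds the smallest cell, a warning is issued and stratification falls
#' back to event status only. Deterministic given `seed`.
#'
#' @param event_labels 0/1 event indicator.
#' @param gender_labels gender per sample (any two-level coding); `NULL` for
#'   event-only stratification.
#' @param k number of folds (>= 2).
#' @param seed integer seed for the shuffle.
#' @return integer vector of fold IDs in 1..k.
#' @export
stratified_kfold <- function(event_labels, gender_labels = NULL, k = 5,
                             seed = 1) {
  n <- length(event_labels)
  stopifnot(k >= 2, k <= n)
  strata <- if (is.null(gender_labels)) factor(event_labels) else
    interaction(event_labels, gender_labels, drop = TRUE)
  if (min(table(strata)) < k && !is.null(gender_labels)) {
    warning("a gender-by-event cell is smaller than k; ",
            "falling back to event-only stratification")
    strata <- factor(event_labels)
  }
  folds <- integer(n)
  with_seed(seed, {
    for (s in levels(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# weighted logistic fit with a small-ridge IRLS fallback under separation;
# returns a plain coefficient vector (intercept first)
fit_weighted_logistic <- function(X, y, w, ridge = 1e-6) {
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- suppressWarnings(
    glm(.y ~ ., data = df, family = quasibinomial(), weights = w,
        control = glm.control(epsilon = 1e-8, maxit = 100)))
  cf <- coef(fit)
  if (fit$converged && all(is.finite(cf)) && max(abs(cf[-1])) <= 20) {
    return(cf)
  }
  warning("separation in weighted logistic fit; ridge fallback (penalty ",
          ridge, ")")
  Xd <- cbind(`(Intercept)` = 1, as.matrix(X))
  beta <- rep(0, ncol(Xd))
  pen <- diag(c(0, rep(ridge, ncol(Xd) - 1)))
  dev_old <- Inf
  for (it in 1:100) {
    eta <- drop(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    ww <- w * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    beta <- solve(crossprod(Xd, Xd * ww) + pen, crossprod(Xd, ww * z))
    dev <- -2 * sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
    if (abs(dev_old - dev) < 1e-8) break
    dev_old <- dev
  }
  setNames(drop(beta), colnames(Xd))
}

predict_logistic <- function(cf, X) {
  eta <- drop(cbind(1, as.matrix(X)) %*% cf)
  1 / (1 + exp(-eta))
}

#' Cross-validated weighted logistic risk prediction
#'
#' For each fold, a weighted logistic model (IRLS; convergence on a deviance
#' change below 1e-8 within 100 iterations) is fitted on the remaining folds
#' and used to predict the held-out samples' event risk, yielding one pooled
#' out-of-fold predicted risk per sample. Weights are the logistic-stage
#' weights `w_final = w_samp * w_cens`; separation triggers a ridge
#' fallback (penalty 1e-6) with a warning.
#'
#' @param features data frame or matrix of numeric predictors.
#' @param outcome 0/1 outcome.
#' @param weights per-sample weights (default all 1). Samples with zero
#'   weight do not influence training but still receive predictions.
#' @param folds integer fold assignment (e.g. from [stratified_kfold()]).
#' @param sample_ids sample identifiers (default rownames / index).
#' @param model_label label stored with the predictions.
#' @return data frame of class `risk_prediction`: `sample_id`, `fold_id`,
#'   `model_label`, `predicted_risk`.
#' @export
cv_predict <- function(features, outcome, weights = NULL, folds,
                       sample_ids = NULL, model_label = "model") {
  X <- as.data.frame(features)
  n <- nrow(X)
  stopifnot(length(outcome) == n, length(folds) == n,
            all(outcome %in% c(0, 1)))
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(all(weights >= 0), length(weights) == n)
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(rownames(X))) rownames(X) else
      sprintf("S%04d", seq_len(n))
  }
  risk <- rep(NA_real_, n)
  for (f in sort(unique(folds))) {
    test <- folds == f
    train <- !test & weights > 0
    cf <- fit_weighted_logistic(X[train, , drop = FALSE], outcome[train],
                                weights[train])
    risk[test] <- predict_logistic(cf, X[test, , drop = FALSE])
  }
  structure(data.frame(sample_id = sample_ids, fold_id = folds,
                       model_label = model_label, predicted_risk = risk,
                       stringsAsFactors = FALSE),
            class = c("risk_prediction", "data.frame"))
}

#' @rdname cv_predict
#' @param x a `risk_prediction`.
#' @param path output CSV path.
#' @export
write_predictions <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
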