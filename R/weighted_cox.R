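#' Weighted Cox proportional-hazards fit
#'
#' Maximizes the weighted Cox partial likelihood with Breslow handling of
#' tied event times by Newton-Raphson with step halving. With case weights
#' \eqn{w_i} the Breslow log partial likelihood is
#' \deqn{\ell(\beta) = \sum_{i:\delta_i=1} w_i x_i'\beta
#'   - \sum_t W_t \log S_0(t,\beta),}
#' where the outer sum runs over distinct event times, \eqn{W_t} is the
#' summed weight of events at \eqn{t} and
#' \eqn{S_0(t,\beta)=\sum_{j: T_j \ge t} w_j e^{x_j'\beta}}. Standard errors
#' come from the inverse observed information and p-values are Wald.
#'
#' Non-convergence or separation (any |coefficient| > 20) is returned as a
#' flagged (`converged = FALSE`) fit rather than an error, so genome-wide
#' scans can carry failed sites as flagged rows.
#'
#' @param covariates numeric matrix (n x p) of covariates; no constant
#'   columns.
#' @param times positive follow-up times.
#' @param events 0/1 event indicator (at least one event).
#' @param weights positive case weights (default all 1).
#' @param init optional starting coefficients (default 0).
#' @param max_iter,tol Newton iteration cap and convergence tolerance on the
#'   maximum absolute score component.
#' @return object of class `wcox`: list with `coefficients`, `se`, `z`, `p`,
#'   `vcov`, `loglik` (log partial likelihood at the optimum), `iter`,
#'   `converged`, `n`, `n_events`.
#' @seealso [survival::coxph()] for the general-purpose implementation this
#'   agrees with (Breslow ties) to numerical precision.
#' @export
weighted_cox_fit <- function(covariates, times, events, weights = NULL,
                             init = NULL, max_iter = 50, tol = 1e-8) {
  X <- as.matrix(covariates)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(times) == n, length(events) == n,
            all(events %in% c(0, 1)))
  if (sum(events) < 1) stop("at least one event is required")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(all(weights > 0), length(weights) == n)
  csd <- apply(X, 2, sd)
  if (any(csd == 0)) {
    stop("constant covariate column: ",
         paste(colnames(X)[csd == 0], collapse = ", "))
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  # center covariates for numerical stability (coefficients are invariant)
  ctr <- colMeans(X)
  X <- sweep(X, 2, ctr)

  ord <- order(times, decreasing = TRUE)
  X <- X[ord, , drop = FALSE]
  tt <- times[ord]
  dd <- events[ord]
  ww <- weights[ord]

  # risk set of a subject at position i (descending time) is 1..end(i),
  # where end(i) closes the block of times tied with t_i
  rl <- rle(tt)
  block_end <- rep(cumsum(rl$lengths), rl$lengths)
  ev <- which(dd == 1)
  # group events by (tied) event time; blocks are contiguous after sorting
  ev_grp <- split(ev, block_end[ev])
  ev_end <- as.integer(names(ev_grp))
  Wt <- vapply(ev_grp, function(g) sum(ww[g]), numeric(1))
  tmp <- vapply(ev_grp, function(g) colSums(X[g, , drop = FALSE] * ww[g]),
                numeric(p))
  sum_wx_ev <- if (p == 1) matrix(tmp, ncol = 1) else t(tmp)
  sum_wx_tot <- colSums(sum_wx_ev)
  # index pairs for the lower triangle of S2
  lt <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)

  deriv <- function(beta) {
    eta <- drop(X %*% beta)
    r <- ww * exp(eta)
    cs0 <- cumsum(r)
    cs1 <- apply(X * r, 2, cumsum)
    cs2 <- apply(X[, lt[, 1], drop = FALSE] * X[, lt[, 2], drop = FALSE] * r,
                 2, cumsum)
    S0 <- cs0[ev_end]
    S1 <- matrix(cs1[ev_end, ], nrow = length(ev_end))
    ll <- sum(ww[ev] * eta[ev]) - sum(Wt * log(S0))
    Ebar <- S1 / S0
    U <- sum_wx_tot - colSums(Wt * Ebar)
    I <- matrix(0, p, p)
    S2k <- matrix(cs2[ev_end, ], nrow = length(ev_end))
    for (k in seq_along(ev_end)) {
      s2 <- matrix(0, p, p)
      s2[cbind(lt[, 1], lt[, 2])] <- S2k[k, ]
      s2[cbind(lt[, 2], lt[, 1])] <- S2k[k, ]
      I <- I + Wt[k] * (s2 / S0[k] - tcrossprod(Ebar[k, ]))
    }
    list(ll = ll, U = U, I = I)
  }

  beta <- if (is.null(init)) rep(0, p) else as.numeric(init)
  d <- deriv(beta)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    if (max(abs(d$U)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(d$I, d$U), error = function(e) NULL)
    if (is.null(step)) break
    # step halving if the likelihood does not improve
    ok <- FALSE
    for (h in 0:5) {
      cand <- beta + step / 2^h
      dc <- deriv(cand)
      if (is.finite(dc$ll) && dc$ll >= d$ll - 1e-12) {
        beta <- cand; d <- dc; ok <- TRUE; break
      }
    }
    if (!ok) break
    if (max(abs(beta)) > 20) break  # separation / monotone likelihood
  }
  if (max(abs(d$U)) < tol && max(abs(beta)) <= 20) converged <- TRUE

  vc <- tryCatch(solve(d$I), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vc), 0))
  z <- beta / se
  names(beta) <- names(se) <- names(z) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, se = se, z = z,
                 p = 2 * pnorm(-abs(z)), vcov = vc, loglik = d$ll,
                 iter = iter, converged = converged, n = n,
                 n_events = sum(events)),
            class = "wcox")
}

#' @export
coef.wcox <- function(object, ...) object$coefficients

#' @export
vcov.wcox <- function(object, ...) object$vcov

#' @export
print.wcox <- function(x, digits = 4, ...) {
  cat(sprintf("Weighted Cox fit (Breslow ties): n = %d, events = %d%s\n",
              x$n, x$n_events,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  tab <- cbind(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
               se = x$se, z = x$z, p = x$p)
  print(round(tab, digits))
  invisible(x)
}

#' @export
summary.wcox <- function(object, ...) {
  ci <- cbind(lower = exp(object$coefficients - qnorm(0.975) * object$se),
              upper = exp(object$coefficients + qnorm(0.975) * object$se))
  out <- list(fit = object, hr = exp(object$coefficients), hr_ci95 = ci)
  class(out) <- "summary.wcox"
  out
}

#' @export
print.summary.wcox <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("HR (95% CI):\n")
  print(round(cbind(HR = x$hr, x$hr_ci95), digits))
  invisible(x)
}
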