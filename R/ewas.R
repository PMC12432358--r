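#' Covariate model specification for the EWAS scan
#'
#' Numbered covariate sets for the per-site Cox models. Model 1 is the
#' primary discovery model (age, gender, BMI, HbA1c); higher-numbered models
#' add further adjustment covariates (cell-composition estimates, medication
#' flags, the smoking-proxy methylation of cg05575921, lipids, ...), all of
#' which must resolve to phenotype-table columns. The composition is
#' configuration, not hard-coded.
#'
#' @param model_id positive integer label.
#' @param covariates character vector of phenotype column names.
#' @return object of class `covariate_model`.
#' @export
covariate_model <- function(model_id,
                            covariates = c("age", "gender", "bmi", "hba1c")) {
  stopifnot(is.numeric(model_id), model_id >= 1, length(covariates) >= 1)
  structure(list(model_id = as.integer(model_id),
                 covariates = as.character(covariates)),
            class = "covariate_model")
}

# expand phenotype columns into a numeric design matrix (gender -> male
# indicator; everything else must already be numeric)
build_design <- function(phenotypes, covariates) {
  miss <- setdiff(covariates, colnames(phenotypes))
  if (length(miss)) {
    stop("covariate(s) not in phenotype table: ", paste(miss, collapse = ", "))
  }
  cols <- lapply(covariates, function(cv) {
    v <- phenotypes[[cv]]
    if (cv == "gender") v <- as.numeric(v == "male")
    if (!is.numeric(v)) stop("covariate '", cv, "' is not numeric")
    v
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- covariates
  mat
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted p-values `q_(i) = min_(j>=i) (p_(j) m / j)` capped at 1
#' and mapped back to input order (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-site weighted Cox EWAS scan
#'
#' Fits one weighted Cox model per methylation site: the site's M-values,
#' standardized to unit (unweighted) SD so hazard ratios are per 1 SD of
#' methylation, enter alongside the model's adjustment covariates. Group
#' mean betas and delta-beta (events minus controls) are reported on the
#' beta scale; q-values are Benjamini-Hochberg over the scan. Sites whose
#' fit fails (separation/non-convergence) are carried as flagged rows with
#' `fit_ok = FALSE` and excluded from the FDR.
#'
#' @param x a `meth_matrix` (beta or M scale; converted internally).
#' @param phenotypes phenotype table covering the matrix samples.
#' @param model a `covariate_model` (or character vector of covariate names).
#' @param weights per-sample sampling weights `w_samp` (default all 1);
#'   censoring is handled by the Cox likelihood itself.
#' @return data frame of class `ewas_result`: `site_id`, `log_hr_per_sd`,
#'   `hr_per_sd`, `se`, `p`, `q`, `mean_beta_events`, `mean_beta_controls`,
#'   `delta_beta`, `fit_ok`; attribute `model_id`.
#' @export
ewas_scan <- function(x, phenotypes, model = covariate_model(1),
                      weights = NULL) {
  if (is.character(model)) model <- covariate_model(1, model)
  stopifnot(inherits(model, "covariate_model"))
  if (!setequal(colnames(x), phenotypes$sample_id)) {
    stop("matrix samples and phenotype table do not match")
  }
  phenotypes <- phenotypes[match(colnames(x), phenotypes$sample_id), ]
  if (!is.null(weights)) {
    if (!is.null(names(weights))) weights <- weights[colnames(x)]
    stopifnot(length(weights) == ncol(x))
  }
  covs <- build_design(phenotypes, model$covariates)
  beta_mat <- unclass(convert_scale(x, "beta"))
  m_mat <- unclass(convert_scale(x, "m"))
  ev <- phenotypes$event == 1
  tv <- phenotypes$time_years

  # warm start: covariate-only fit
  base_fit <- weighted_cox_fit(covs, tv, phenotypes$event, weights)
  init0 <- c(0, coef(base_fit))

  res <- lapply(seq_len(nrow(x)), function(i) {
    z <- m_mat[i, ]
    s <- sd(z)
    if (s == 0) {
      return(list(coef = NA_real_, se = NA_real_, p = NA_real_, ok = FALSE))
    }
    z <- (z - mean(z)) / s
    fit <- tryCatch(
      weighted_cox_fit(cbind(site = z, covs), tv, phenotypes$event, weights,
                       init = init0),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || !is.finite(fit$se[1])) {
      return(list(coef = NA_real_, se = NA_real_, p = NA_real_, ok = FALSE))
    }
    list(coef = unname(coef(fit)[1]), se = unname(fit$se[1]),
         p = unname(fit$p[1]), ok = TRUE)
  })
  log_hr <- vapply(res, `[[`, numeric(1), "coef")
  se <- vapply(res, `[[`, numeric(1), "se")
  p <- vapply(res, `[[`, numeric(1), "p")
  ok <- vapply(res, `[[`, logical(1), "ok")
  q <- rep(NA_real_, length(p))
  if (any(ok)) q[ok] <- bh_fdr(p[ok])

  out <- data.frame(
    site_id = rownames(x),
    log_hr_per_sd = log_hr,
    hr_per_sd = exp(log_hr),
    se = se, p = p, q = q,
    mean_beta_events = rowMeans(beta_mat[, ev, drop = FALSE]),
    mean_beta_controls = rowMeans(beta_mat[, !ev, drop = FALSE]),
    fit_ok = ok,
    stringsAsFactors = FALSE, row.names = NULL)
  out$delta_beta <- out$mean_beta_events - out$mean_beta_controls
  attr(out, "model_id") <- model$model_id
  class(out) <- c("ewas_result", "data.frame")
  out
}

#' Cross-model robustness screen
#'
#' Keeps sites discovered in the primary model (q below `q_threshold`) that
#' also show p below `p_threshold` in *every* supplied secondary model, and
#' records the per-model p-values as `p_model<k>` columns.
#'
#' @param primary `ewas_result` of the discovery model.
#' @param secondary_scans list of `ewas_result`s for the adjustment models;
#'   each must cover all primary discoveries.
#' @param q_threshold FDR threshold in the primary model (default 0.05).
#' @param p_threshold nominal threshold in the secondary models (default
#'   0.05).
#' @return the surviving subset of `primary` rows, with per-model p columns.
#' @export
robustness_screen <- function(primary, secondary_scans,
                              q_threshold = 0.05, p_threshold = 0.05) {
  hits <- primary[!is.na(primary$q) & primary$q < q_threshold, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  keep <- rep(TRUE, nrow(hits))
  for (sc in secondary_scans) {
    idx <- match(hits$site_id, sc$site_id)
    if (anyNA(idx)) {
      stop("secondary scan (model ", attr(sc, "model_id"),
           ") does not cover site(s): ",
           paste(hits$site_id[is.na(idx)], collapse = ", "))
    }
    pm <- sc$p[idx]
    hits[[paste0("p_model", attr(sc, "model_id"))]] <- pm
    keep <- keep & !is.na(pm) & pm < p_threshold
  }
  hits[keep, , drop = FALSE]
}

#' Effect-size filter on group methylation differences
#'
#' Keeps sites whose absolute beta-scale difference between event and
#' control groups is at least `threshold` (inclusive at the boundary); the
#' default 2% selects sites with differences large enough to be robust and
#' likely to replicate.
#'
#' @param results an `ewas_result` (must carry `delta_beta`).
#' @param threshold minimum |delta_beta| (default 0.02).
#' @return the surviving subset of rows.
#' @export
delta_beta_filter <- function(results, threshold = 0.02) {
  results[abs(results$delta_beta) >= threshold, , drop = FALSE]
}

#' Write EWAS results as tab-separated text
#' @param results an `ewas_result`.
#' @param path output path.
#' @export
write_ewas_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
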