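#' Build a methylation risk score model
#'
#' The MRS of a sample is the sum over selected sites of the site's
#' methylation level times its effect size, the log hazard ratio from the
#' discovery Cox model: \eqn{MRS_i = \sum_s \hat\beta_s z_s(i)}, where
#' \eqn{z_s} is the site's M-value standardized by the per-site mean and SD
#' recorded at build time (so scoring new samples uses the training
#' standardization, and adding a constant to a site's raw values does not
#' change the score).
#'
#' @param selected an `ewas_result` subset of selected sites (uses `site_id`
#'   and `log_hr_per_sd`), or a data frame with those columns.
#' @param x the `meth_matrix` the standardization is taken from (training
#'   data).
#' @return object of class `mrs_model`: data frame with `site_id`, `coef`,
#'   `center`, `scale` (M-value mean/SD per site).
#' @export
build_mrs <- function(selected, x) {
  stopifnot(all(c("site_id", "log_hr_per_sd") %in% colnames(selected)))
  if (anyDuplicated(selected$site_id)) stop("duplicate site IDs in selection")
  if (any(!is.finite(selected$log_hr_per_sd))) {
    stop("non-finite coefficient(s) in selection")
  }
  miss <- setdiff(selected$site_id, rownames(x))
  if (length(miss)) {
    stop("site(s) absent from the matrix: ", paste(miss, collapse = ", "))
  }
  m <- unclass(convert_scale(x, "m"))[selected$site_id, , drop = FALSE]
  structure(data.frame(site_id = selected$site_id,
                       coef = selected$log_hr_per_sd,
                       center = rowMeans(m),
                       scale = apply(m, 1, sd),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("mrs_model", "data.frame"))
}

#' @export
print.mrs_model <- function(x, ...) {
  cat(sprintf("Methylation risk score: %d sites\n", nrow(x)))
  cat(sprintf("coefficient (log-HR/SD) range: [%.3f, %.3f]\n",
              min(x$coef), max(x$coef)))
  invisible(x)
}

#' @export
coef.mrs_model <- function(object, ...) setNames(object$coef, object$site_id)

#' Score samples with an MRS model
#'
#' @param object an `mrs_model`.
#' @param newdata a `meth_matrix` containing every model site.
#' @param ... unused.
#' @return named numeric vector, one MRS value per sample.
#' @export
predict.mrs_model <- function(object, newdata, ...) {
  miss <- setdiff(object$site_id, rownames(newdata))
  if (length(miss)) {
    stop("site(s) absent from the matrix: ", paste(miss, collapse = ", "))
  }
  m <- unclass(convert_scale(newdata, "m"))[object$site_id, , drop = FALSE]
  sc <- ifelse(object$scale > 0, object$scale, 1)
  z <- (m - object$center) / sc
  drop(crossprod(z, object$coef))[colnames(newdata)]
}

#' @rdname predict.mrs_model
#' @param model an `mrs_model`.
#' @param x a `meth_matrix`.
#' @export
mrs_score <- function(model, x) predict(model, x)
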