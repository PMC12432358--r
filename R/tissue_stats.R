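#' Per-site paired t-test with FDR correction
#'
#' Classical paired t statistic per methylation site between two matrices of
#' paired samples (e.g. donor-matched diseased and healthy tissue), with
#' Benjamini-Hochberg q-values across sites. Columns are paired by sample ID.
#' Sites with zero difference variance get t = 0, p = 1 when all differences
#' are zero, and p = 0 when a constant nonzero shift makes the statistic
#' unbounded.
#'
#' @param matrix_a,matrix_b `meth_matrix` objects with identical sites and
#'   paired sample IDs (at least 2 pairs).
#' @return data frame: `site_id`, `mean_diff` (a minus b), `t`, `p`, `q`.
#' @export
paired_ttest_fdr <- function(matrix_a, matrix_b) {
  if (!identical(rownames(matrix_a), rownames(matrix_b))) {
    stop("matrices must cover the same sites in the same order")
  }
  if (!setequal(colnames(matrix_a), colnames(matrix_b))) {
    stop("sample IDs cannot be paired: ",
         paste(union(setdiff(colnames(matrix_a), colnames(matrix_b)),
                     setdiff(colnames(matrix_b), colnames(matrix_a))),
               collapse = ", "))
  }
  b <- unclass(matrix_b)[, colnames(matrix_a), drop = FALSE]
  d <- unclass(matrix_a) - b
  n <- ncol(d)
  if (n < 2) stop("at least 2 pairs are required")
  mu <- rowMeans(d)
  s <- sqrt(rowSums((d - mu)^2) / (n - 1))
  t_stat <- ifelse(s > 0, mu / (s / sqrt(n)),
                   ifelse(mu == 0, 0, sign(mu) * Inf))
  p <- 2 * pt(-abs(t_stat), df = n - 1)
  data.frame(site_id = rownames(matrix_a), mean_diff = mu, t = t_stat,
             p = p, q = bh_fdr(p), stringsAsFactors = FALSE, row.names = NULL)
}

#' Spearman rank correlation between methylation and expression
#'
#' Rank correlation with average ranks for ties and a t-approximation
#' p-value (delegates to [stats::cor.test()] with `method = "spearman"`,
#' `exact = FALSE`).
#'
#' @param methylation,expression numeric vectors of equal length (>= 5),
#'   neither constant.
#' @return list with `rho` and `p`.
#' @export
spearman_assoc <- function(methylation, expression) {
  if (length(methylation) != length(expression) || length(methylation) < 5) {
    stop("vectors must have equal length >= 5")
  }
  if (sd(methylation) == 0 || sd(expression) == 0) {
    stop("correlation undefined for a constant vector")
  }
  ct <- suppressWarnings(cor.test(methylation, expression,
                                  method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
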