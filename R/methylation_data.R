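#' Construct a methylation matrix
#'
#' A `meth_matrix` is a numeric sites x samples matrix of methylation values
#' on either the beta scale (methylated fraction, in \[0,1\]) or the M scale
#' (logit2 of beta, unbounded), with unique probe IDs as row names and unique
#' sample IDs as column names.
#'
#' @param values numeric matrix, sites in rows, samples in columns.
#' @param site_ids character vector of probe IDs (defaults to rownames).
#' @param sample_ids character vector of sample IDs (defaults to colnames).
#' @param scale `"beta"` or `"m"`.
#' @return An object of class `meth_matrix` (a matrix with a `scale`
#'   attribute).
#' @export
meth_matrix <- function(values, site_ids = rownames(values),
                        sample_ids = colnames(values),
                        scale = c("beta", "m")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("methylation values must be numeric")
  }
  if (is.null(site_ids) || is.null(sample_ids)) {
    stop("site_ids and sample_ids are required (or set dimnames)")
  }
  if (length(site_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("ID lengths do not match matrix dimensions")
  }
  if (anyDuplicated(site_ids)) {
    stop("duplicate site IDs: ", paste(unique(site_ids[duplicated(site_ids)]),
                                       collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyNA(values)) {
    stop("missing methylation values are not permitted")
  }
  if (scale == "beta" && (any(values < 0) || any(values > 1))) {
    bad <- which(values < 0 | values > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("beta value out of [0,1] at site '%s', sample '%s'",
                 site_ids[bad[1]], sample_ids[bad[2]]))
  }
  dimnames(values) <- list(site_ids, sample_ids)
  structure(values, scale = scale, class = c("meth_matrix", "matrix", "array"))
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d sites x %d samples (%s scale)\n",
              nrow(x), ncol(x), attr(x, "scale")))
  cat("sites:  ", paste(head(rownames(x), 3), collapse = ", "),
      if (nrow(x) > 3) ", ..." else "", "\n", sep = "")
  cat("samples:", paste(head(colnames(x), 3), collapse = ", "),
      if (ncol(x) > 3) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Methylation scale of a matrix
#' @param x a `meth_matrix`.
#' @return `"beta"` or `"m"`.
#' @export
meth_scale <- function(x) attr(x, "scale")

#' Beta-value / M-value conversions
#'
#' The M-value is the logit2 transform of the methylated fraction,
#' M = log2(beta / (1 - beta)), with inverse beta = 2^M / (2^M + 1).
#' Betas at exactly 0 or 1 are clipped to `eps` / `1 - eps` so the
#' transform stays finite.
#'
#' @param beta,m numeric vectors or matrices.
#' @param eps boundary clip for beta (default 1e-6).
#' @return the transformed values, same shape as the input.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  beta <- pmin(pmax(beta, eps), 1 - eps)
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  # 2^m/(2^m+1) written via plogis-style form for overflow safety
  1 / (1 + 2^(-m))
}

#' Convert a whole matrix between the beta and M scales
#' @param x a `meth_matrix`.
#' @param scale target scale.
#' @return a `meth_matrix` on the requested scale (identity if already there).
#' @export
convert_scale <- function(x, scale = c("beta", "m")) {
  scale <- match.arg(scale)
  from <- meth_scale(x)
  if (from == scale) return(x)
  v <- if (scale == "m") beta_to_m(unclass(x)) else m_to_beta(unclass(x))
  meth_matrix(v, rownames(x), colnames(x), scale = scale)
}

#' M-value from raw channel intensities
#'
#' M = log2((max(meth, 0) + 1) / (max(unmeth, 0) + 1)): negative intensities
#' are clamped to zero and both channels are offset by one count.
#'
#' @param meth_intensity,unmeth_intensity numeric, methylated and
#'   unmethylated channel intensities (recycled to common length).
#' @return M-values.
#' @export
intensity_to_m <- function(meth_intensity, unmeth_intensity) {
  if (any(!is.finite(meth_intensity)) || any(!is.finite(unmeth_intensity))) {
    stop("intensities must be finite")
  }
  log2((pmax(meth_intensity, 0) + 1) / (pmax(unmeth_intensity, 0) + 1))
}

#' Read / write a methylation matrix as delimited text
#'
#' Comma-separated, decimal point, mandatory header: first column `probe_id`,
#' one further column per sample. Values written with full double precision
#' so a round trip preserves IDs, order and values.
#'
#' @param path file path.
#' @param scale scale of the stored values.
#' @return `read_meth_matrix` returns a `meth_matrix`; `write_meth_matrix`
#'   returns `path` invisibly.
#' @export
read_meth_matrix <- function(path, scale = c("beta", "m")) {
  scale <- match.arg(scale)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix file needs a probe_id column plus samples")
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!sapply(df[-1], is.numeric))[1]
    stop(sprintf("non-numeric cells in sample column '%s'",
                 colnames(df)[-1][bad]))
  }
  if (scale == "beta" && (any(vals < 0) || any(vals > 1))) {
    bad <- which(vals < 0 | vals > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("beta value out of [0,1] at row %d ('%s'), column '%s'",
                 bad[1], ids[bad[1]], colnames(vals)[bad[2]]))
  }
  # missing policy: drop any site with a missing value (complete-case fits)
  keep <- complete.cases(vals)
  if (!all(keep)) {
    message(sprintf("dropping %d site(s) with missing values", sum(!keep)))
    vals <- vals[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  meth_matrix(vals, ids, colnames(vals), scale = scale)
}

#' @rdname read_meth_matrix
#' @param x a `meth_matrix`.
#' @export
write_meth_matrix <- function(x, path) {
  df <- data.frame(probe_id = rownames(x), unclass(x),
                   check.names = FALSE, row.names = NULL)
  write.csv(format(df, digits = 17, trim = TRUE), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a phenotype table
#'
#' One row per sample with columns `sample_id`, `event` (0/1), `time_years`
#' (> 0), `age`, `gender` ("male"/"female"), `bmi`, `hba1c`, `smoking_proxy`
#' (beta-value of cg05575921), `med_diabetes`, `med_lipid`,
#' `med_antihypertensive` (0/1), plus any optional numeric covariates
#' (e.g. hdl, ldl, tg, egfr, uacr, cell fractions).
#'
#' @param path file path.
#' @return `read_phenotypes` returns a validated data frame.
#' @export
read_phenotypes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_phenotypes(df)
}

#' @rdname read_phenotypes
#' @param phenotypes a phenotype data frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a phenotype table
#' @param phenotypes a data frame with the fields of [read_phenotypes()].
#' @return the data frame, invisibly checked.
#' @export
validate_phenotypes <- function(phenotypes) {
  need <- c("sample_id", "event", "time_years", "age", "gender", "bmi",
            "hba1c", "smoking_proxy", "med_diabetes", "med_lipid",
            "med_antihypertensive")
  miss <- setdiff(need, colnames(phenotypes))
  if (length(miss)) stop("phenotype table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(phenotypes$sample_id)) stop("duplicate sample_id values")
  if (!all(phenotypes$event %in% c(0, 1))) stop("event must be 0/1")
  if (any(phenotypes$time_years <= 0)) stop("time_years must be > 0")
  if (!all(phenotypes$gender %in% c("male", "female"))) {
    stop("gender must be 'male' or 'female'")
  }
  if (any(phenotypes$smoking_proxy < 0 | phenotypes$smoking_proxy > 1)) {
    stop("smoking_proxy must be a beta-value in [0,1]")
  }
  for (f in c("med_diabetes", "med_lipid", "med_antihypertensive")) {
    if (!all(phenotypes[[f]] %in% c(0, 1))) stop(f, " must be 0/1")
  }
  invisible(phenotypes)
}

#' Probe masks
#'
#' A probe mask is a named set of probe IDs to exclude before analysis
#' (failed-detection probes, rs probes, cross-reactive or polymorphic
#' probes, ...), stored as one ID per line in plain text.
#'
#' @param name mask label used in removal logs.
#' @param probe_ids character vector of probe IDs (non-empty).
#' @return an object of class `probe_mask`.
#' @export
probe_mask <- function(name, probe_ids) {
  probe_ids <- unique(as.character(probe_ids))
  if (!length(probe_ids)) stop("probe mask '", name, "' is empty")
  structure(list(name = as.character(name), probe_ids = probe_ids),
            class = "probe_mask")
}

#' @rdname probe_mask
#' @param path one-probe-ID-per-line text file.
#' @export
read_probe_mask <- function(path, name = basename(path)) {
  ids <- readLines(path)
  ids <- ids[nzchar(trimws(ids))]
  probe_mask(name, trimws(ids))
}

#' Remove masked probes from a methylation matrix
#'
#' Drops the union of all masked probe IDs; original site order is preserved
#' and per-mask removal / unmatched counts are reported via `message()`.
#'
#' @param x a `meth_matrix`.
#' @param masks a `probe_mask` or list of them (empty list = identity).
#' @return the filtered `meth_matrix`.
#' @export
filter_probes <- function(x, masks = list()) {
  if (inherits(masks, "probe_mask")) masks <- list(masks)
  drop_ids <- character(0)
  for (m in masks) {
    stopifnot(inherits(m, "probe_mask"))
    present <- m$probe_ids %in% rownames(x)
    message(sprintf("mask '%s': %d probe(s) removed, %d unmatched",
                    m$name, sum(present), sum(!present)))
    drop_ids <- union(drop_ids, m$probe_ids[present])
  }
  keep <- !(rownames(x) %in% drop_ids)
  if (!any(keep)) stop("all probes removed by masks")
  meth_matrix(unclass(x)[keep, , drop = FALSE], rownames(x)[keep],
              colnames(x), scale = meth_scale(x))
}
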