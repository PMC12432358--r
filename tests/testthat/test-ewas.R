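test_that("BH q-values match the step-up hand computation", {
  expect_equal(bh_fdr(0.03), 0.03)                     # m = 1
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))              # hand step-up
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))       # exchangeable
  p <- c(0.001, 0.9, 0.04, 0.3, 0.011)
  q <- bh_fdr(p)
  expect_true(all(q >= p))                             # never decreases
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_fdr(p[perm]), q[perm])               # order invariant
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("the EWAS scan returns one standardized-site result per site", {
  sim <- fixture_cohort
  x1 <- meth_matrix(unclass(sim$methylation)[1, , drop = FALSE],
                    rownames(sim$methylation)[1],
                    colnames(sim$methylation))
  res1 <- ewas_scan(x1, sim$phenotypes)
  expect_identical(nrow(res1), 1L)
  expect_equal(res1$q, res1$p)  # single test: q = p
  expect_equal(res1$hr_per_sd, exp(res1$log_hr_per_sd))
  expect_equal(res1$delta_beta,
               res1$mean_beta_events - res1$mean_beta_controls)
  ph_bad <- sim$phenotypes
  ph_bad$sample_id[1] <- "nobody"
  expect_error(ewas_scan(x1, ph_bad), "do not match")
})

test_that("scan results are invariant to site order", {
  sim <- fixture_cohort
  sub <- unclass(sim$methylation)[1:30, ]
  x <- meth_matrix(sub, rownames(sub), colnames(sub))
  perm <- sample(30)
  xp <- meth_matrix(sub[perm, ], rownames(sub)[perm], colnames(sub))
  r1 <- ewas_scan(x, sim$phenotypes)
  r2 <- ewas_scan(xp, sim$phenotypes)
  r2 <- r2[match(r1$site_id, r2$site_id), ]
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$q, r2$q, tolerance = 1e-12)
})

test_that("planted sites are discovered and their effects recovered", {
  sim <- fixture_cohort
  scan <- ewas_scan(sim$methylation, sim$phenotypes,
                    covariate_model(1), weights = NULL)
  hits <- scan[!is.na(scan$q) & scan$q < 0.05, ]
  truth <- sim$true_effects
  causal_ids <- truth$site_id[truth$log_hr_per_sd != 0]
  expect_gt(nrow(hits), 0)
  # most discoveries are truly causal
  expect_gt(mean(hits$site_id %in% causal_ids), 0.5)
  # the strongest discovery is causal with a correctly signed estimate
  top <- hits[which.min(hits$p), ]
  expect_true(top$site_id %in% causal_ids)
  expect_equal(sign(top$log_hr_per_sd),
               sign(truth$log_hr_per_sd[truth$site_id == top$site_id]))
})

test_that("null scans control the nominal type-I error", {
  sim <- fixture_null_cohort
  scan <- ewas_scan(sim$methylation, sim$phenotypes)
  frac <- mean(scan$p < 0.05)
  band <- 3 * sqrt(0.05 * 0.95 / nrow(scan))
  expect_lt(abs(frac - 0.05), band)
})

test_that("the robustness screen keeps only sites nominal in every secondary model", {
  mk <- function(ids, p, q = p, model_id = 1) {
    structure(data.frame(site_id = ids, p = p, q = q,
                         stringsAsFactors = FALSE),
              model_id = model_id, class = c("ewas_result", "data.frame"))
  }
  primary <- mk(c("a", "b", "c"), p = c(1e-4, 1e-3, 0.2),
                q = c(0.01, 0.01, 0.6))
  sec2 <- mk(c("a", "b", "c"), p = c(0.04, 0.04, 0.9), model_id = 2)
  sec3 <- mk(c("a", "b", "c"), p = c(0.03, 0.06, 0.9), model_id = 3)
  out <- robustness_screen(primary, list(sec2, sec3))
  expect_identical(out$site_id, "a")  # b fails model 3, c fails primary FDR
  expect_equal(out$p_model2, 0.04)
  expect_equal(out$p_model3, 0.03)
  # constructed fixture: 3 of 10 planted sites fail one secondary model
  ids <- paste0("s", 1:10)
  prim <- mk(ids, p = rep(1e-4, 10), q = rep(0.01, 10))
  sec <- mk(ids, p = c(rep(0.01, 7), rep(0.5, 3)), model_id = 2)
  expect_identical(nrow(robustness_screen(prim, list(sec))), 7L)
  # a missing primary site in a secondary scan is a coverage error
  expect_error(robustness_screen(primary, list(mk("a", 0.01, model_id = 2))),
               "does not cover site")
})

test_that("the delta-beta filter is inclusive at the boundary", {
  res <- data.frame(site_id = paste0("s", 1:12),
                    delta_beta = c(0.020, 0.019, -0.020, -0.019,
                                   0.01, -0.01, 0.03, -0.03, 0.04, -0.04,
                                   0.05, -0.05))
  kept <- delta_beta_filter(res)
  expect_identical(kept$site_id,
                   c("s1", "s3", "s7", "s8", "s9", "s10", "s11", "s12"))
  # hand count on the +/-0.01..0.05 ladder: 8 of 10 reach 0.02, 6 reach 0.03
  ladder <- data.frame(site_id = paste0("L", 1:10),
                       delta_beta = c(0.01, -0.01, 0.02, -0.02, 0.03,
                                      -0.03, 0.04, -0.04, 0.05, -0.05))
  expect_identical(nrow(delta_beta_filter(ladder)), 8L)
  expect_identical(nrow(delta_beta_filter(ladder, 0.03)), 6L)
})

test_that("EWAS results write as a readable TSV", {
  sim <- fixture_cohort
  sub <- meth_matrix(unclass(sim$methylation)[1:5, ],
                     rownames(sim$methylation)[1:5],
                     colnames(sim$methylation))
  res <- ewas_scan(sub, sim$phenotypes)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ewas_results(res, path)
  back <- read.delim(path)
  expect_identical(back$site_id, res$site_id)
  expect_equal(back$log_hr_per_sd, res$log_hr_per_sd, tolerance = 1e-6)
})

test_that("paired t statistics match the closed-form oracle", {
  sim <- fixture_cohort
  a <- meth_matrix(unclass(sim$methylation)[1:20, 1:15],
                   rownames(sim$methylation)[1:20],
                   colnames(sim$methylation)[1:15])
  # identical matrices: all t = 0, p = 1
  same <- paired_ttest_fdr(a, a)
  expect_true(all(same$t == 0))
  expect_true(all(same$p == 1))
  # shifted pair: per-site match with stats::t.test
  set.seed(4)
  bvals <- pmin(pmax(unclass(a) + rnorm(300, 0.01, 0.02), 0.01), 0.99)
  b <- meth_matrix(bvals, rownames(a), colnames(a))
  out <- paired_ttest_fdr(a, b)
  for (i in c(1, 7, 20)) {
    ref <- t.test(unclass(a)[i, ], bvals[i, ], paired = TRUE)
    expect_equal(out$t[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(out$p[i], ref$p.value, tolerance = 1e-10)
  }
  # exactly constant nonzero difference (dyadic values, so the shift is
  # representable): the statistic is unbounded and p = 0
  dy <- matrix(sample(c(0.25, 0.375, 0.5, 0.625), 75, replace = TRUE), 5, 15,
               dimnames = list(paste0("cg", 1:5), colnames(a)))
  dy_shift <- dy; dy_shift[1, ] <- dy_shift[1, ] + 0.0625
  guard <- paired_ttest_fdr(meth_matrix(dy_shift), meth_matrix(dy))
  expect_identical(guard$p[1], 0)
  expect_true(all(guard$t[2:5] == 0))
  # pairing is by sample ID, not column position
  perm <- sample(ncol(a))
  b_perm <- meth_matrix(bvals[, perm], rownames(a), colnames(a)[perm])
  out2 <- paired_ttest_fdr(a, b_perm)
  expect_equal(out2$t, out$t, tolerance = 1e-12)
  expect_error(
    paired_ttest_fdr(a, meth_matrix(bvals, rownames(a),
                                    paste0("other", 1:15))),
    "paired")
})

test_that("paired t-test type-I error is nominal under the null", {
  set.seed(42)
  n_sites <- 400
  a <- matrix(runif(n_sites * 10, 0.3, 0.7), n_sites, 10,
              dimnames = list(paste0("cg", 1:n_sites), paste0("p", 1:10)))
  b <- a + matrix(rnorm(n_sites * 10, 0, 0.02), n_sites, 10)
  out <- paired_ttest_fdr(meth_matrix(a), meth_matrix(pmin(pmax(b, 0), 1)))
  expect_lt(abs(mean(out$p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / n_sites))
})

test_that("Spearman association matches an explicit rank-based oracle", {
  expect_equal(spearman_assoc(1:10, (1:10)^3)$rho, 1)    # monotone
  expect_equal(spearman_assoc(1:10, -(1:10)^3)$rho, -1)  # antitone
  set.seed(6)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20); y[3] <- y[5]  # a tie
  out <- spearman_assoc(x, y)
  rx <- rank(x); ry <- rank(y)
  rho_oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(out$rho, rho_oracle, tolerance = 1e-12)
  expect_error(spearman_assoc(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman_assoc(1:4, 1:4), "length")
})
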