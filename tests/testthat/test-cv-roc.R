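test_that("stratified folds balance every event-by-gender cell", {
  # 102 events among 752: per-fold event counts must be 20 or 21
  ev <- rep(c(1, 0), c(102, 650))
  folds <- stratified_kfold(ev, gender_labels = NULL, k = 5, seed = 42)
  per_fold <- table(folds[ev == 1])
  expect_true(all(per_fold %in% c(20, 21)))
  expect_identical(sort(unique(folds)), 1:5)
  # determinism
  expect_identical(folds, stratified_kfold(ev, NULL, k = 5, seed = 42))
  expect_false(identical(folds, stratified_kfold(ev, NULL, k = 5, seed = 43)))
  # 4-cell design (40, 60, 10, 12): per-cell fold counts differ by <= 1
  ev2 <- rep(c(1, 1, 0, 0), c(40, 60, 10, 12))
  g2 <- rep(c("male", "female", "male", "female"), c(40, 60, 10, 12))
  f2 <- stratified_kfold(ev2, g2, k = 5, seed = 1)
  for (cell in split(f2, interaction(ev2, g2, drop = TRUE))) {
    counts <- tabulate(cell, nbins = 5)
    expect_lte(diff(range(counts)), 1)
  }
  # k larger than the smallest cell: warn and fall back to event-only
  ev3 <- rep(c(1, 0), c(6, 30))
  g3 <- c(rep("male", 3), rep("female", 3), rep("male", 15),
          rep("female", 15))
  expect_warning(f3 <- stratified_kfold(ev3, g3, k = 5, seed = 2),
                 "falling back")
  expect_true(all(tabulate(f3[ev3 == 1], 5) %in% 1:2))
})

test_that("cross-validated predictions cover each sample exactly once", {
  set.seed(10)
  n <- 200
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(X$a))
  folds <- stratified_kfold(y, NULL, k = 5, seed = 3)
  pred <- cv_predict(X, y, folds = folds, model_label = "demo")
  expect_identical(nrow(pred), as.integer(n))
  expect_false(anyNA(pred$predicted_risk))
  expect_true(all(pred$predicted_risk >= 0 & pred$predicted_risk <= 1))
  expect_identical(anyDuplicated(pred$sample_id), 0L)
  expect_identical(unique(pred$model_label), "demo")
})

test_that("unit-weight CV predictions equal an unweighted glm oracle", {
  set.seed(11)
  n <- 150
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(0.8 * X$a - 0.3))
  folds <- rep(1:5, length.out = n)
  pred <- cv_predict(X, y, weights = rep(1, n), folds = folds)
  for (f in 1:5) {
    train <- folds != f
    oracle <- glm(y ~ a + b, data = cbind(X, y = y), subset = train,
                  family = binomial())
    expect_equal(pred$predicted_risk[folds == f],
                 unname(predict(oracle, X[folds == f, ], type = "response")),
                 tolerance = 1e-6)
  }
})

test_that("chance-level features give chance-level cross-validated AUC", {
  set.seed(42)
  n <- 1000
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rbinom(n, 1, 0.15)
  folds <- stratified_kfold(y, NULL, k = 5, seed = 42)
  pred <- cv_predict(X, y, folds = folds)
  expect_lt(abs(roc_curve(pred$predicted_risk, y)$auc - 0.5), 0.05)
})

test_that("ROC AUC equals the Mann-Whitney statistic exactly", {
  # perfect ranking
  expect_equal(roc_curve(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  # 10-point fixture with ties, unweighted
  set.seed(12)
  pred <- sample(seq(0.1, 0.9, 0.1), 10, replace = TRUE)
  y <- rbinom(10, 1, 0.5); y[1] <- 1; y[2] <- 0
  expect_equal(roc_curve(pred, y)$auc, auc_mann_whitney(pred, y))
  # weighted identity on n = 50
  pred50 <- rnorm(50); y50 <- rbinom(50, 1, 0.4); y50[1:2] <- c(0, 1)
  w50 <- runif(50, 0.5, 4)
  expect_equal(roc_curve(pred50, y50, w50)$auc,
               auc_mann_whitney(pred50, y50, w50), tolerance = 1e-12)
  # agreement with the pROC reference implementation
  expect_equal(roc_curve(pred50, y50)$auc,
               as.numeric(pROC::auc(pROC::roc(y50, pred50, levels = c(0, 1),
                                              direction = "<",
                                              quiet = TRUE))),
               tolerance = 1e-12)
  # shuffled labels: near chance
  set.seed(13)
  expect_lt(abs(roc_curve(rnorm(2000), rbinom(2000, 1, 0.5))$auc - 0.5),
            0.05)
  expect_error(roc_curve(1:4, rep(1, 4)), "both outcome classes")
})

test_that("precision-recall points match their definitions", {
  pred <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  y <- c(1, 0, 1, 0, 0)
  pr <- pr_curve(pred, y)
  # descending thresholds add one sample at a time:
  # TP/(TP+FP) = 1/1, 1/2, 2/3, 2/4, 2/5 ; recall = 1/2,1/2,1,1,1
  expect_equal(pr$precision, c(1, 1, 1 / 2, 2 / 3, 2 / 4, 2 / 5))
  expect_equal(pr$recall, c(0, 1 / 2, 1 / 2, 1, 1, 1))
})

test_that("the Youden cutoff equals an exhaustive threshold search", {
  # 8-point fixture
  pred <- c(0.05, 0.2, 0.3, 0.35, 0.5, 0.6, 0.8, 0.9)
  y <- c(0, 0, 1, 0, 1, 0, 1, 1)
  roc <- roc_curve(pred, y)
  yj <- youden_cutoff(roc)
  # brute force over every candidate cutoff with rule "pred > c"
  cand <- c(-Inf, pred)
  j_brute <- vapply(cand, function(cc) {
    mean(pred[y == 1] > cc) + mean(pred[y == 0] <= cc) - 1
  }, numeric(1))
  expect_equal(yj$youden_j, max(j_brute), tolerance = 1e-12)
  best_brute <- min(cand[j_brute == max(j_brute)])
  expect_equal(yj$cutoff, best_brute)
  # perfect separation: J = 1 at the largest negative score
  roc2 <- roc_curve(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  yj2 <- youden_cutoff(roc2)
  expect_equal(yj2$youden_j, 1)
  expect_equal(yj2$cutoff, 3)
  # anti-predictive scores warn
  expect_warning(youden_cutoff(roc_curve(c(3, 2, 1), c(0, 0, 1))), "Youden")
})

test_that("identical models compare with p = 1 and real gaps are detected", {
  set.seed(14)
  y <- rbinom(300, 1, 0.3); y[1:2] <- c(0, 1)
  pred <- plogis(rnorm(300) + y)
  self <- compare_auc(pred, pred, y)
  expect_equal(self$diff, 0)
  expect_equal(self$p, 1)
  # type-I error of the DeLong comparison under equal true AUCs
  set.seed(42)
  rej <- replicate(100, {
    n <- 300
    z <- rnorm(n)
    yy <- rbinom(n, 1, plogis(z)); yy[1:2] <- c(0, 1)
    pa <- z + rnorm(n); pb <- z + rnorm(n)
    compare_auc(pa, pb, yy)$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 100) + 0.01)
  # a real AUC gap of ~0.15 is rejected most of the time at n = 750
  set.seed(42)
  power <- replicate(50, {
    n <- 750
    yy <- rbinom(n, 1, 0.14); yy[1:2] <- c(0, 1)
    strong <- yy * 1.6 + rnorm(n)
    weak <- yy * 0.35 + rnorm(n)
    compare_auc(strong, weak, yy)$p < 0.05
  })
  expect_gt(mean(power), 0.8)
})

test_that("separated training data falls back to a ridge fit with a warning", {
  X <- data.frame(a = c(rep(-1, 20) + rnorm(20, 0, 1e-3),
                        rep(1, 20) + rnorm(20, 0, 1e-3)))
  y <- rep(c(0, 1), each = 20)
  warns <- capture_warnings(pred <- cv_predict(X, y, folds = rep(1:2, 20)))
  expect_match(warns, "ridge fallback", all = TRUE)
  expect_gt(length(warns), 0)
  expect_true(all(is.finite(pred$predicted_risk)))
})
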