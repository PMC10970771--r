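test_that("dementia label follows the MoCA <= 21 band", {
  expect_identical(dementia_label(c(21, 22, 30, 0)), c(1L, 0L, 0L, 1L))
  expect_error(dementia_label(31), "0, 30")
  expect_error(dementia_label(-1), "0, 30")
})

test_that("null logistic model matches the closed-form AIC", {
  y <- rep(c(0, 1), each = 5)
  fit <- fit_logistic(NULL, y)                 # intercept-only
  expect_equal(fit$logL, 10 * log(0.5), tolerance = 1e-8)
  expect_equal(fit$AIC, 2 - 20 * log(0.5), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-8)
})

test_that("logistic IRLS agrees with glm and detects separation", {
  set.seed(2)
  n <- 120
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.5 + X[, 1]))
  fit <- fit_logistic(X, y)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$logL, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(fit$AIC, AIC(ref), tolerance = 1e-8)
  # gradient at the optimum vanishes
  mu <- plogis(drop(cbind(1, X) %*% fit$coefficients))
  expect_lt(max(abs(crossprod(cbind(1, X), y - mu))), 1e-6)
  # tiny ridge reproduces the ML fit
  fit_r <- fit_logistic(X, y, ridge = 1e-10)
  expect_equal(fit_r$coefficients, fit$coefficients, tolerance = 1e-5)
  # separable toy errors without ridge, works with it
  Xs <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  ys <- c(0, 0, 0, 1, 1, 1)
  expect_error(fit_logistic(Xs, ys), "separation")
  expect_s3_class(fit_logistic(Xs, ys, ridge = 1e-3), "model_spec")
  expect_error(fit_logistic(cbind(k = rep(1, 6)), ys), "constant")
})

test_that("AIC reduction is exhaustive and prefers informative predictors", {
  wins <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 200
    X <- data.frame(signal = rnorm(n), noise = rnorm(n))
    y <- rbinom(n, 1, plogis(1.5 * X$signal))
    best <- reduce_by_aic(X, y)
    identical(best$predictors, "signal")
  }, TRUE)
  expect_gte(mean(wins), 0.9)
  # exhaustiveness: winner beats every listed subset
  set.seed(11)
  X <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  y <- rbinom(50, 1, 0.5)
  best <- reduce_by_aic(X, y)
  tab <- attr(best, "aic_table")
  expect_equal(nrow(tab), 7)           # 2^3 - 1 subsets
  expect_true(all(best$AIC <= tab$AIC))
})

test_that("train/test split is stratified, sized and reproducible", {
  y <- rep(c(0, 1), c(60, 30))
  sp <- split_train_test(y, 0.7, seed = 5)
  expect_length(sp$train, 63)
  expect_length(sp$test, 27)
  expect_equal(sum(y[sp$train]), 21)   # 70% of the 30 cases
  expect_identical(sp, split_train_test(y, 0.7, seed = 5))
  expect_false(identical(sp, split_train_test(y, 0.7, seed = 6)))
  expect_error(split_train_test(y, 1, seed = 1), "train_frac")
  expect_error(split_train_test(rep(c(0, 1), c(88, 2)), 0.7, 1), "class")
})

test_that("ROC analysis matches pair counting and the full threshold scan", {
  # perfect separation
  r <- roc_analysis(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$accuracy, 1)
  # all-identical scores
  expect_equal(roc_analysis(rep(2, 8), rep(c(0, 1), 4))$auc, 0.5)
  # tied 6-point toy vs exhaustive pair counting
  s6 <- c(1, 2, 2, 3, 2, 4); l6 <- c(0, 0, 1, 1, 0, 1)
  expect_equal(roc_analysis(s6, l6)$auc, auc_pairs(s6, l6))
  # random instances: AUC oracle and operating-point optimality by full scan
  for (seed in 1:5) {
    set.seed(seed)
    sc <- round(rnorm(30), 1)
    lb <- rbinom(30, 1, 0.4)
    if (length(unique(lb)) < 2) next
    r <- roc_analysis(sc, lb)
    expect_equal(r$auc, auc_pairs(sc, lb))
    js <- vapply(unique(sc), function(th) {
      mean(sc[lb == 1] >= th) + mean(sc[lb == 0] < th)
    }, 1)
    expect_equal(r$sensitivity + r$specificity, max(c(js, 1)))
  }
  expect_error(roc_analysis(1:4, rep(1, 4)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  sc <- rnorm(40)
  lb <- rbinom(40, 1, 0.5)
  expect_equal(auc_mw(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE))))
})

test_that("stratified bootstrap keeps classes and brackets the estimate", {
  set.seed(4)
  sc <- c(rnorm(12), rnorm(8, 1.5))
  lb <- rep(c(0, 1), c(12, 8))
  ci <- bootstrap_ci(auc_mw, sc, lb, B = 500, seed = 3)
  est <- auc_mw(sc, lb)
  expect_lte(ci$lower, est)
  expect_gte(ci$upper, est)
  expect_identical(ci$replicates,
                   bootstrap_ci(auc_mw, sc, lb, B = 500, seed = 3)$replicates)
  # constant metric gives a zero-width interval
  cc <- bootstrap_ci(function(s, l) 0.7, sc, lb, B = 100, seed = 1)
  expect_equal(cc$lower, cc$upper)
})

test_that("model comparison table is deterministic and well-formed", {
  v <- generate_validation(validation_design(n_per_group = 30, seed = 31))
  rt <- sample_ratios(v$wells)
  cohort <- merge(v$cohort, rt[, c("sample_id", "ratio")], by = "sample_id")
  pd <- cohort[cohort$group != "HC", ]
  pd$dementia <- dementia_label(pd$moca_total)
  t1 <- model_comparison_table(pd, seed = 9, B = 200)
  t2 <- model_comparison_table(pd, seed = 9, B = 200)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 7)
  expect_true(all(t1$auc >= t1$auc_lo - 1e-9 & t1$auc <= t1$auc_hi + 1e-9))
  expect_true(all(t1[, -1] >= 0 & t1[, -1] <= 1))
})
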