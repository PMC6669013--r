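test_that("balanced-accuracy posterior has the closed-form mean and sane intervals", {
  b <- balanced_accuracy_posterior(12, 7, 15, 3)
  expect_equal(b$mean, ((13 / 21) + (16 / 20)) / 2)
  expect_lt(b$lower, b$mean)
  expect_gt(b$upper, b$mean)
  # symmetric counts center the posterior at 0.5
  expect_equal(balanced_accuracy_posterior(5, 5, 9, 9)$mean, 0.5)
  # large balanced counts drive the mean to 1
  expect_gt(balanced_accuracy_posterior(1000, 0, 1000, 0)$mean, 0.99)
  expect_error(balanced_accuracy_posterior(0, 0, 5, 5), "class")
  expect_error(balanced_accuracy_posterior(2.5, 1, 1, 1), "integer")
  # posterior mean shrinks the raw balanced accuracy toward 0.5
  raw <- (12 / 19 + 15 / 18) / 2
  expect_lt(b$mean, raw)
  expect_gt(b$mean, 0.5)
})

test_that("trapezoidal AUC equals the rank statistic and is transform-invariant", {
  set.seed(71)
  y <- rep(c(TRUE, FALSE), c(12, 15))
  s <- rnorm(27)
  u <- wilcox.test(s[y], s[!y])$statistic
  expect_equal(auc_trapezoid(s, y), unname(u) / (12 * 15), tolerance = 1e-12)
  expect_equal(auc_trapezoid(rank(s), y), auc_trapezoid(s, y))
  expect_equal(auc_trapezoid(exp(2 * s), y), auc_trapezoid(s, y))
  # perfect and reversed rankings
  expect_equal(auc_trapezoid(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_trapezoid(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE)), 0)
  # ties get half credit
  expect_equal(auc_trapezoid(c(1, 1), c(TRUE, FALSE)), 0.5)
  expect_error(auc_trapezoid(1:3, c(TRUE, TRUE, TRUE)), "classes")
  skip_if_not_installed("pROC")
  pr <- pROC::auc(pROC::roc(response = y, predictor = s, quiet = TRUE,
                            direction = "<"))
  expect_equal(auc_trapezoid(s, y), as.numeric(pr), tolerance = 1e-10)
})

test_that("bootstrap AUC intervals are reproducible, cover the point estimate and tighten with n", {
  set.seed(72)
  make <- function(n) {
    y <- rep(c(TRUE, FALSE), each = n / 2)
    list(y = y, s = rnorm(n) + y * 1.2)
  }
  d40 <- make(40)
  ci1 <- auc_bootstrap(d40$s, d40$y, n_boot = 500, seed = 3)
  ci2 <- auc_bootstrap(d40$s, d40$y, n_boot = 500, seed = 3)
  expect_identical(ci1, ci2)
  expect_lte(ci1$lower, ci1$auc)
  expect_gte(ci1$upper, ci1$auc)
  d200 <- make(200)
  ci3 <- auc_bootstrap(d200$s, d200$y, n_boot = 500, seed = 3)
  expect_lt(ci3$upper - ci3$lower, ci1$upper - ci1$lower)
  expect_error(auc_bootstrap(1:4, c(TRUE, FALSE, FALSE, FALSE)), "2 members")
})

test_that("paired AUC comparison is antisymmetric and detects separation", {
  set.seed(73)
  y <- rep(c(TRUE, FALSE), each = 30)
  s_good <- rnorm(60) + y * 2
  s_null <- rnorm(60)
  same <- auc_compare(s_good, s_good, y)
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)
  ab <- auc_compare(s_good, s_null, y, n_boot = 400, seed = 5)
  ba <- auc_compare(s_null, s_good, y, n_boot = 400, seed = 5)
  expect_equal(ab$D, -ba$D, tolerance = 1e-12)
  expect_lt(ab$p_value, 0.05)
})

test_that("elastic-net selection keeps informative features and duplicates move together", {
  set.seed(74)
  ft <- sample_feature_table(n_per_group = c(30, 30), n_features = 30,
                             n_informative = 1, effect_size = 1.5, seed = 10)
  sel <- feature_select_elastic_net(ft$x, ft$y, seed = 11)
  expect_true(sel$mask[1])
  # an absurd penalty yields an empty mask with a warning
  expect_warning(
    sel0 <- feature_select_elastic_net(ft$x, ft$y, alpha_grid = 1,
                                       lambda_grid = c(1e4, 1e3), seed = 11),
    "empty mask")
  expect_false(any(sel0$mask))
  # duplicated informative features are selected in and out together
  x2 <- cbind(ft$x[, 1], ft$x[, 1] + rnorm(60, 0, 1e-6), ft$x[, -1])
  sel2 <- feature_select_elastic_net(x2, ft$y, alpha_grid = 0.5, seed = 12)
  expect_equal(unname(sel2$mask[1]), unname(sel2$mask[2]))
})

test_that("LOSO nested CV separates separable classes and stays honest under permutation", {
  ft <- sample_feature_table(n_per_group = c(20, 20), n_features = 20,
                             n_informative = 5, effect_size = 2, seed = 20)
  res <- loso_nested_cv(ft$x, ft$y, seed = 1)
  expect_equal(length(res$scores), 40)
  expect_equal(sum(res$confusion), 40)
  expect_gte(res$balanced_accuracy, 0.95)
  expect_lt(res$p_binomial, 0.001)
  # n = 37 gives exactly 37 outer folds
  ft37 <- sample_feature_table(seed = 21)
  res37 <- loso_nested_cv(ft37$x[, 1:10], ft37$y, seed = 2)
  expect_equal(length(res37$scores), 37)
  # permuted labels: accuracy near chance (few seeds; the full null audit
  # lives in the acceptance suite)
  set.seed(22)
  ba <- replicate(3, {
    yp <- sample(ft$y)
    loso_nested_cv(ft$x, yp, seed = 3)$balanced_accuracy
  })
  expect_lt(abs(mean(ba) - 0.5), 0.2)
})

test_that("probabilistic logistic pipeline yields calibrated-scale outputs and bend correlation", {
  ft <- sample_feature_table(n_per_group = c(15, 15), n_features = 10,
                             n_informative = 4, effect_size = 1.5, seed = 30)
  res <- loso_nested_cv(ft$x, ft$y, classifier = make_classifier("logreg"),
                        seed = 4)
  expect_true(all(res$probabilities >= 0 & res$probabilities <= 1))
  r <- probabilistic_output_correlation(res$probabilities, ft$outcome)
  expect_gt(as.numeric(r), 0)   # responders have higher outcome by design
  expect_equal(as.numeric(probabilistic_output_correlation(ft$outcome,
                                                           ft$outcome)), 1)
  # bit-for-bit agreement with the diagnostics implementation
  expect_identical(as.numeric(r),
                   as.numeric(percentage_bend_correlation(res$probabilities,
                                                          ft$outcome)))
})

test_that("the peeking negative control inflates permuted-label accuracy", {
  ft <- sample_feature_table(n_per_group = c(20, 20), n_features = 150,
                             n_informative = 0, effect_size = 0, seed = 40)
  set.seed(41)
  yp <- sample(ft$y)
  honest <- loso_nested_cv(ft$x, yp, screen_k = 5, seed = 5)
  expect_warning(leaky <- loso_cv_peeking(ft$x, yp, screen_k = 5, seed = 5),
                 "leaks")
  expect_gt(leaky$balanced_accuracy, honest$balanced_accuracy)
  expect_gt(leaky$balanced_accuracy, 0.6)   # leakage looks like signal
})
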