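test_that("exact binomial exceedance matches enumeration and base R", {
  expect_equal(binomial_exceedance_test(10, 10), 1 / 1024)
  expect_equal(binomial_exceedance_test(5, 10), 638 / 1024)
  expect_equal(binomial_exceedance_test(0, 10), 1)
  # against the independent distribution-function oracle for all n <= 20
  for (n in c(1, 5, 12, 20)) {
    for (k in 0:n) {
      expect_equal(binomial_exceedance_test(k, n, 0.3),
                   stats::pbinom(k - 1, n, 0.3, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  }
  # complement identity: P(X >= k) + P(X <= k - 1) = 1
  for (n in c(6, 13, 20)) {
    for (k in 1:n) {
      expect_equal(binomial_exceedance_test(k, n, 0.5) +
                     sum(choose(n, 0:(k - 1))) / 2^n, 1, tolerance = 1e-12)
    }
  }
  expect_equal(binomial_exceedance_test(8, 10, alternative = "two.sided"),
               stats::binom.test(8, 10, 0.5)$p.value, tolerance = 1e-12)
  expect_error(binomial_exceedance_test(11, 10), "k")
})

test_that("calibration quintiles recover simulated (anti)calibration", {
  set.seed(51)
  p <- runif(1e4, 0.05, 0.95)
  y <- rbinom(1e4, 1, p)
  cal <- calibration_quintiles(p, y)
  expect_gte(cal$r, 0.99)
  expect_equal(sum(cal$table$count), 1e4)
  anti <- calibration_quintiles(p, rbinom(1e4, 1, 1 - p))
  expect_lte(anti$r, -0.9)
  expect_error(calibration_quintiles(rep(0.5, 100), rbinom(100, 1, 0.5)),
               "degenerate")
})

test_that("mean predictive probability averages the observed-choice probabilities", {
  d <- random_sequence(60, seed = 52, p_missed = 0.1)
  tr <- model_trajectory("DYNA", c(beta = 1e-300, gamma = 1, rho = 0.5), d)
  expect_equal(mean_predictive_probability(tr$p_obs), 0.5)
  # per-subject mode averages subjects, not trials
  p_obs <- c(0.9, 0.9, 0.1)
  subj <- c("a", "a", "b")
  expect_equal(mean_predictive_probability(p_obs, subj, mode = "subject"), 0.5)
  expect_equal(mean_predictive_probability(p_obs), mean(p_obs))
  # a well-fitting model beats chance comfortably
  s <- simulate_model_agent("DYNA", c(beta = 2, gamma = 0.5, rho = 0.5),
                            task_config(), seed = 8)
  tr2 <- model_trajectory("DYNA", c(beta = 2, gamma = 0.5, rho = 0.5), s)
  expect_gt(mean_predictive_probability(tr2$p_obs), 0.6)
})

test_that("percentage-bend correlation matches the textbook formula and its invariances", {
  set.seed(53)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  expect_equal(as.numeric(percentage_bend_correlation(x, y)),
               oracle_pbcor(x, y), tolerance = 1e-12)
  expect_equal(as.numeric(percentage_bend_correlation(x, x)), 1)
  expect_equal(as.numeric(percentage_bend_correlation(x, -x)), -1)
  # affine invariance (positive slope) and sign flip under negation
  r0 <- as.numeric(percentage_bend_correlation(x, y))
  expect_equal(as.numeric(percentage_bend_correlation(3 * x + 7, y / 2 - 1)),
               r0, tolerance = 1e-12)
  expect_equal(as.numeric(percentage_bend_correlation(-x, y)), -r0,
               tolerance = 1e-12)
  expect_error(percentage_bend_correlation(x, rep(1, 30)), "scale")
  expect_error(percentage_bend_correlation(1:3, 1:3), "4")
})

test_that("bisquare IRLS equals OLS on clean data and resists a gross outlier", {
  set.seed(54)
  x <- rnorm(50)
  y <- 1 + 2 * x + rnorm(50, 0, 0.3)
  fit <- robust_regression_bisquare(cbind(x), y)
  ols <- coef(lm(y ~ x))
  expect_equal(unname(fit$coefficients), unname(ols), tolerance = 1e-2)
  # perfectly linear data: weights stay 1 and IRLS equals OLS to tight tol
  yl <- 1 + 2 * x
  fitl <- robust_regression_bisquare(cbind(x), yl)
  expect_equal(unname(fitl$coefficients), c(1, 2), tolerance = 1e-6)
  # one gross outlier: robust slope stays closer to the clean OLS slope
  yc <- y; yc[1] <- 60
  fit_r <- robust_regression_bisquare(cbind(x), yc)
  ols_c <- coef(lm(yc ~ x))
  expect_lt(abs(fit_r$coefficients[2] - ols[2]), abs(ols_c[2] - ols[2]))
  expect_lt(fit_r$weights[1], 0.01)   # the outlier is effectively dropped
  expect_error(robust_regression_bisquare(cbind(x, x), y), "rank")
  # agrees with the independent M-estimation implementation in MASS
  skip_if_not_installed("MASS")
  rlm_fit <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare)
  expect_equal(unname(fit$coefficients), unname(coef(rlm_fit)),
               tolerance = 0.05)
})

test_that("choice accuracy is the HPS fraction over valid trials", {
  d <- data.frame(
    choice = c("a", "b", "missed", "a", "b", "a", "a", "missed", "b", "a"),
    hps_identity = c("a", "a", "a", "b", "b", "a", "a", "b", "a", "a"),
    stringsAsFactors = FALSE)
  # valid trials: 8; HPS choices among them: a,a,.,b(no: chose a hps b)...
  # manual count: trials 1 (a=a), 5 (b=b), 6, 7, 10 -> 5 of 8
  expect_equal(choice_accuracy(d), 5 / 8)
  expect_equal(choice_accuracy(data.frame(choice = "a", hps_identity = "a")), 1)
  expect_equal(choice_accuracy(data.frame(choice = "b", hps_identity = "a")), 0)
  expect_error(choice_accuracy(data.frame(choice = "missed",
                                          hps_identity = "a")), "valid")
})
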