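test_that("parameter transforms round-trip and reject boundary values", {
  for (mn in c("DYNA", "DYNA_STICK", "PH", "HGF", "K1")) {
    sp <- model_spec(mn)
    p <- from_transformed(sp$prior_mean + 0.3, sp)
    expect_equal(from_transformed(to_transformed(p, sp), sp), p,
                 tolerance = 1e-12)
  }
  sp <- model_spec("DYNA")
  expect_equal(to_transformed(c(beta = 1, gamma = 1, rho = 0.5), sp)[["rho"]], 0)
  expect_equal(to_transformed(c(beta = 1, gamma = 1, rho = 0.5), sp)[["beta"]], 0)
  expect_error(to_transformed(c(beta = 1, gamma = 1, rho = 0), sp), "interior")
  # scaled logit honors the upper bound of 3 on kappa
  sph <- model_spec("HGF")
  x <- to_transformed(c(kappa = 1.5, theta = 0.001, beta = 1), sph)
  expect_equal(from_transformed(x, sph)[["kappa"]], 1.5, tolerance = 1e-12)
  expect_error(to_transformed(c(kappa = 3, theta = 0.001, beta = 1), sph),
               "kappa")
})

test_that("the Laplace covariance of a quadratic log-posterior is the exact inverse Hessian", {
  A <- matrix(c(4, 1, 1, 3), 2, 2)
  f <- function(x) 0.5 * sum(x * (A %*% x))
  H <- revlearn:::numerical_hessian(f, c(0.3, -0.2))
  expect_equal(H, A, tolerance = 1e-5)
  expect_equal(revlearn:::hessian_to_cov(H), solve(A), tolerance = 1e-4)
  # indefinite input is repaired to positive-definite
  B <- matrix(c(1, 0, 0, -2), 2, 2)
  ev <- eigen(revlearn:::hessian_to_cov(B))$values
  expect_true(all(ev > 0))
})

test_that("a dominating prior pins the MAP at the prior mean", {
  d <- random_sequence(40, seed = 31)
  pr <- population_prior(c(beta = 0.2, gamma = -0.5, rho = 0.4),
                         c(beta = 1e-8, gamma = 1e-8, rho = 1e-8))
  f <- fit_map("DYNA", d, prior = pr, n_restarts = 1)
  expect_equal(unname(f$theta_map), c(0.2, -0.5, 0.4), tolerance = 1e-3)
})

test_that("MAP fitting recovers generating parameters on a single informative subject", {
  p_true <- c(beta = 0.3, gamma = 0.5, rho = 0.5, stick = 0.3)
  s <- simulate_model_agent("DYNA_STICK", p_true, task_config(), seed = 5)
  pr <- population_prior(
    c(beta = log(0.2), gamma = log(0.5), rho = 0, stick = 0.1),
    c(beta = 0.25, gamma = 0.25, rho = 0.64, stick = 0.09))
  f <- fit_map("DYNA_STICK", s, prior = pr, n_restarts = 3, seed = 1)
  expect_true(f$converged)
  # the fitted sequence NLL cannot exceed the chance benchmark
  expect_lt(f$nll, sum(s$choice != "missed") * log(2))
  expect_true(all(eigen(f$sigma)$values > 0))
})

test_that("EM on identical subjects converges the population mean to the common MAP", {
  d <- random_sequence(60, seed = 32)
  ds <- do.call(rbind, lapply(1:4, function(i)
    transform(d, subject = sprintf("s%02d", i))))
  fit <- run_em("DYNA", ds, max_iter = 8, bic_samples = 0, seed = 1)
  mus <- vapply(fit$subjects, `[[`, numeric(3), "theta_map")
  expect_lt(max(apply(mus, 1, function(z) diff(range(z)))), 1e-4)
  expect_lt(max(abs(fit$prior$mean - rowMeans(mus))), 1e-6)
})

test_that("integrated BIC with one sample reduces to the penalized log likelihood at the draw", {
  d <- random_sequence(50, seed = 33)
  sp <- model_spec("DYNA")
  pr <- population_prior(sp$prior_mean, c(beta = 0.2, gamma = 0.2, rho = 0.2))
  res <- integrated_bic(sp, list(s1 = d), pr, n_samples = 1, seed = 9)
  set.seed(9)
  draw <- pr$mean + stats::rnorm(3) * sqrt(pr$var)
  ll <- -sequence_nll(sp, from_transformed(draw, sp), d)
  expect_equal(res$bic_int, -2 * ll + 6 * log(sum(d$choice != "missed")),
               tolerance = 1e-10)
  expect_equal(res$q, 6L)
})

test_that("the Monte-Carlo error of the marginal likelihood shrinks like 1/sqrt(K)", {
  d <- random_sequence(60, seed = 34)
  sp <- model_spec("DYNA")
  pr <- population_prior(c(beta = log(0.3), gamma = log(0.5), rho = 0),
                         c(beta = 0.3, gamma = 0.3, rho = 0.3))
  est <- function(K, r) integrated_bic(sp, list(s1 = d), pr, n_samples = K,
                                       seed = 1000 + r)$log_ml
  se_small <- sd(vapply(1:20, function(r) est(40, r), numeric(1)))
  se_large <- sd(vapply(1:20, function(r) est(640, r), numeric(1)))
  ratio <- se_small / se_large  # expect ~ 4 for a 16-fold sample increase
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})

test_that("model ranking is deterministic, order-invariant and validates datasets", {
  set.seed(35)
  spec <- cohort_spec(n_responders = 3, n_nonresponders = 3,
                      task = task_config(n_trials = 60))
  coh <- sample_cohort(spec, seed = 4)
  f1 <- run_em("DYNA_STICK", coh$choices, max_iter = 3, bic_samples = 300,
               seed = 1)
  f2 <- run_em("PH", coh$choices, max_iter = 3, bic_samples = 300, seed = 1)
  tab <- compare_models(list(f1, f2))
  expect_s3_class(tab, "model_comparison")
  expect_equal(tab$delta_bic[1], 0)
  expect_equal(tab$bic_int, sort(tab$bic_int))
  tab_rev <- compare_models(list(f2, f1))
  expect_equal(tab, tab_rev)
  # permuting subject order leaves the integrated BIC unchanged
  seqs <- revlearn:::split_choices(coh$choices)
  pr <- f1$prior
  b1 <- integrated_bic("DYNA_STICK", seqs, pr, n_samples = 200, seed = 2)
  b2 <- integrated_bic("DYNA_STICK", rev(seqs), pr, n_samples = 200, seed = 2)
  expect_equal(b1$bic_int, b2$bic_int, tolerance = 1e-10)
  # a fit on different subjects cannot be compared
  coh2 <- sample_cohort(cohort_spec(n_responders = 2, n_nonresponders = 2,
                                    task = task_config(n_trials = 60)),
                        seed = 5)
  f3 <- run_em("PH", coh2$choices, max_iter = 2, bic_samples = 0, seed = 1)
  expect_error(compare_models(list(f1, f3)), "same dataset")
})
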