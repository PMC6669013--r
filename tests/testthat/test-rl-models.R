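test_that("contingency coding matches the task's outcome mapping", {
  expect_equal(encode_contingency(TRUE, TRUE), 1)    # (+ | HPS)
  expect_equal(encode_contingency(FALSE, FALSE), 1)  # (- | LPS)
  expect_equal(encode_contingency(TRUE, FALSE), 0)   # (- | HPS)
  expect_equal(encode_contingency(FALSE, TRUE), 0)   # (+ | LPS)
  expect_error(encode_contingency(NA, TRUE), "missed")
})

test_that("slope modulation is odd, bounded, gamma-flattened and tanh-equivalent", {
  expect_equal(slope_modulation(0, 1), 0)
  expect_equal(slope_modulation(0, 0.01), 0)
  m <- seq(-2, 2, by = 0.05)
  f <- slope_modulation(m, 0.5)
  expect_true(all(abs(f) < 1))
  expect_true(all(sign(f) == sign(m)))
  # |f| strictly decreasing in gamma for fixed m != 0
  gammas <- c(0.1, 0.5, 1, 5)
  fm <- sapply(gammas, function(g) abs(slope_modulation(0.7, g)))
  expect_true(all(diff(fm) < 0))
  # the double sigmoid is tanh at half the argument
  expect_equal(slope_modulation(m, 0.7), tanh(m / (2 * 0.7)),
               tolerance = 1e-12)
  expect_error(slope_modulation(1, 0), "gamma")
})

test_that("single DYNA steps follow the printed recursions", {
  st <- list(v = c(a = 0, b = 0), alpha = 0.5, pemag = 0)
  # first trial: delta is the raw outcome, pemag' = rho * |delta|
  r1 <- dyna_step(st, "a", 10, list(rho = 0.3, gamma = 1))
  expect_equal(r1$latents$delta, 10)
  expect_equal(r1$latents$pemag, 3)
  expect_equal(r1$latents$m, 2)   # slope saturates when starting from 0
  # rho = 1 degenerates the convex combination to |delta|
  r2 <- dyna_step(st, "b", -10, list(rho = 1 - 1e-12, gamma = 1))
  expect_equal(r2$latents$pemag, 10, tolerance = 1e-9)
  expect_error(dyna_step(st, "a", 10, list(rho = 1, gamma = 1)), "rho")
})

test_that("DYNA trajectories equal the straight-line oracle and composed R steps", {
  d <- random_sequence(25, seed = 11, p_missed = 0.1)
  p <- c(beta = 0.4, gamma = 0.7, rho = 0.35, stick = 0.3)
  tr <- model_trajectory("DYNA_STICK", p, d)
  or <- oracle_dyna(d$choice, d$outcome, p[["beta"]], p[["gamma"]],
                    p[["rho"]], p[["stick"]])
  expect_equal(tr$p_a, or$p_a, tolerance = 1e-10)
  expect_equal(tr$alpha, or$alpha, tolerance = 1e-10)
  expect_equal(tr$pemag, or$pemag, tolerance = 1e-10)
  expect_equal(tr$wrpe, or$wrpe, tolerance = 1e-10)
  expect_equal(attr(tr, "nll"), or$nll, tolerance = 1e-10)
  # composing the exported single-trial step function reproduces the filter
  st <- list(v = c(a = 0, b = 0), alpha = 0.5, pemag = 0)
  pars <- list(rho = p[["rho"]], gamma = p[["gamma"]])
  for (t in seq_len(nrow(d))) {
    if (d$choice[t] == "missed") next
    res <- dyna_step(st, d$choice[t], d$outcome[t], pars)
    expect_equal(res$latents$alpha, tr$alpha[t], tolerance = 1e-12)
    st <- res$state
  }
})

test_that("Pearce-Hall uses the previous unsigned PE as learning rate", {
  st <- list(v = c(a = 0.5, b = 0.5), alpha = 0.6)
  # salience 0 freezes the values at their 0.5 initialization
  r <- pearce_hall_step(st, "a", 1, list(S = 0))
  expect_equal(r$state$v[["a"]], 0.5)
  # zero previous PE means no value change this trial
  st0 <- list(v = c(a = 0.5, b = 0.5), alpha = 0)
  r0 <- pearce_hall_step(st0, "a", 1, list(S = 2))
  expect_equal(r0$state$v[["a"]], 0.5)
  d <- random_sequence(20, seed = 12)
  p <- c(alpha1 = 0.4, S = 0.8, beta = 3)
  tr <- model_trajectory("PH", p, d)
  or <- oracle_ph(d$choice, d$outcome, p[["S"]], p[["alpha1"]], p[["beta"]])
  expect_equal(tr$p_a, or$p_a, tolerance = 1e-10)
  expect_equal(attr(tr, "nll"), or$nll, tolerance = 1e-10)
})

test_that("HGF updates are precision-weighted and match the oracle unrolling", {
  # near-perfectly predicted input leaves the level-2 mean in place
  st <- list(mu2 = 30, sa2 = 0.5, mu3 = 1, sa3 = 1)
  r <- hgf_step(st, 1, list(kappa = 1, omega = -4, theta = 0.002))
  expect_lt(abs(r$state$mu2 - 30), 1e-8)
  # constant input drives the predicted probability monotonically to 1
  st <- list(mu2 = 0, sa2 = 1, mu3 = 1, sa3 = 1)
  preds <- numeric(100)
  for (t in 1:100) {
    preds[t] <- plogis(st$mu2)
    st <- hgf_step(st, 1, list(kappa = 1.4, omega = -4, theta = 0.003))$state
  }
  expect_true(all(diff(preds) > 0))
  expect_gt(preds[100], 0.9)
  d <- random_sequence(20, seed = 13)
  p <- c(kappa = 1, theta = 0.0025, beta = 4)
  tr <- model_trajectory("HGF", p, d)
  or <- oracle_hgf(d$choice, oracle_u(d$choice, d$outcome, d$hps_identity),
                   d$hps_identity, p[["kappa"]], -4, p[["theta"]], p[["beta"]])
  expect_equal(tr$p_a, or$p_a, tolerance = 1e-10)
  expect_equal(tr$mu2, or$mu2, tolerance = 1e-10)
  expect_equal(tr$mu3, or$mu3, tolerance = 1e-10)
  expect_equal(attr(tr, "nll"), or$nll, tolerance = 1e-10)
})

test_that("K1 gain adaptation matches the oracle and is inert at zero PE or zero mu", {
  st <- list(v = 1, h = 0.1, b = log(0.1))
  r <- k1_step(st, 1, list(mu = 1))  # delta = 0 exactly
  expect_identical(r$state, st)
  # mu = 0: the log-gain never moves, so the learning rate is constant
  d <- random_sequence(30, seed = 14)
  tr0 <- model_trajectory("K1", c(mu = 1e-300, h1 = 0.1, beta = 3), d)
  gains <- tr0$gain[!is.na(tr0$gain)]
  expect_true(all(abs(gains - gains[1]) < 1e-12))
  p <- c(mu = 2, h1 = 0.05, beta = 3)
  tr <- model_trajectory("K1", p, d)
  or <- oracle_k1(d$choice, oracle_u(d$choice, d$outcome, d$hps_identity),
                  d$hps_identity, p[["mu"]], p[["h1"]], p[["beta"]])
  expect_equal(tr$p_a, or$p_a, tolerance = 1e-10)
  expect_equal(tr$gain, or$gain, tolerance = 1e-10)
  expect_equal(attr(tr, "nll"), or$nll, tolerance = 1e-10)
})

test_that("the sigmoid choice rule is symmetric, saturating and stable", {
  expect_equal(choice_probability(1, 1, 5), 0.5)
  expect_equal(choice_probability(3, -2, 0), 0.5)
  expect_equal(choice_probability(2, 1, 1e6), 1)
  expect_equal(choice_probability(1, 2, 1e6), 0)
  expect_gt(choice_probability(0, 0, 1, stick = 2, prev_choice = "a"), 0.5)
  expect_lt(choice_probability(0, 0, 1, stick = 2, prev_choice = "b"), 0.5)
  expect_error(choice_probability(0, 0, -1), "beta")
})

test_that("sequence NLL is the summed cross-entropy with missed trials carried", {
  d <- random_sequence(40, seed = 15, p_missed = 0.2)
  n_valid <- sum(d$choice != "missed")
  # beta = 0 forces p = 0.5 on every valid trial
  expect_equal(sequence_nll("DYNA", c(beta = 1e-300, gamma = 1, rho = 0.5), d),
               n_valid * log(2), tolerance = 1e-8)
  # additivity: dropping the last valid trial removes exactly its -log p
  p <- c(beta = 0.3, gamma = 0.5, rho = 0.5)
  tr <- model_trajectory("DYNA", p, d)
  lastv <- max(which(d$choice != "missed"))
  expect_equal(sequence_nll("DYNA", p, d[-(lastv:nrow(d)), ]),
               attr(tr, "nll") + sum(log(tr$p_obs[lastv:nrow(d)]),
                                     na.rm = TRUE),
               tolerance = 1e-10)
  expect_error(sequence_nll("DYNA", p,
                            transform(d, choice = "missed")), "missed")
})

test_that("DYNA learning rate and pemag stay in their bounds on random sequences", {
  set.seed(99)
  for (i in 1:300) {
    d <- random_sequence(30, seed = 1e5 + i, p_missed = 0.05)
    p <- c(beta = exp(rnorm(1)), gamma = exp(rnorm(1)),
           rho = plogis(rnorm(1)), stick = rnorm(1))
    tr <- model_trajectory("DYNA_STICK", p, d)
    a <- tr$alpha[!is.na(tr$alpha)]
    pm <- tr$pemag[!is.na(tr$pemag)]
    m <- tr$m[!is.na(tr$m)]
    expect_true(all(a >= 0 & a <= 1))
    expect_true(all(pm >= 0))
    expect_true(all(pm <= max(abs(tr$delta), na.rm = TRUE) + 1e-12))
    expect_true(all(m >= -2 & m <= 2))
    expect_true(all(tr$p_a >= 0 & tr$p_a <= 1))
  }
})

test_that("forward simulation is self-consistent: truth beats perturbed parameters", {
  set.seed(21)
  spec <- model_spec("DYNA_STICK")
  wins <- 0
  n_rep <- 30
  for (i in seq_len(n_rep)) {
    p_true <- c(beta = 0.3, gamma = 0.5, rho = 0.5, stick = 0.2)
    s <- simulate_model_agent("DYNA_STICK", p_true, task_config(),
                              seed = 400 + i)
    x <- to_transformed(p_true, spec)
    x_pert <- x + sample(c(-1, 1), length(x), replace = TRUE)
    p_pert <- from_transformed(x_pert, spec)
    wins <- wins + (sequence_nll(spec, p_true, s) <
                      sequence_nll(spec, p_pert, s))
  }
  expect_gt(wins / n_rep, 0.8)
})
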