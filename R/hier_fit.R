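#' Population-level prior over transformed parameters
#'
#' The empirical-Bayes population distribution: an independent Gaussian per
#' parameter in transformed space, summarized by its mean and variance.
#'
#' @param mean Named numeric vector of means (transformed space).
#' @param var Named numeric vector of positive variances.
#' @return An object of class `population_prior`.
#' @export
population_prior <- function(mean, var) {
  stopifnot(length(mean) == length(var),
            identical(names(mean), names(var)))
  if (any(!is.finite(var)) || any(var <= 0))
    stop("prior variances must be positive and finite")
  structure(list(mean = mean, var = var), class = "population_prior")
}

#' @rdname population_prior
#' @param spec A [model_spec()]; returns its default prior.
#' @export
default_prior <- function(spec) {
  spec <- resolve_model(spec)
  population_prior(spec$prior_mean, spec$prior_var)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# split a tidy multi-subject choice table into per-subject sequences
split_choices <- function(data) {
  if (is.data.frame(data)) {
    if (!"subject" %in% names(data))
      stop("a tidy choice table needs a `subject` column")
    ids <- unique(data$subject)
    out <- lapply(ids, function(s) data[data$subject == s, , drop = FALSE])
    names(out) <- as.character(ids)
    out
  } else if (is.list(data)) {
    if (is.null(names(data)))
      names(data) <- sprintf("s%02d", seq_along(data))
    data
  } else stop("dataset must be a data frame or a list of sequences")
}

# central-difference Hessian of fn at x
numerical_hessian <- function(fn, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- fn(x)
  for (i in seq_len(d)) {
    for (j in i:d) {
      ei <- ej <- numeric(d); ei[i] <- h; ej[j] <- h
      if (i == j) {
        H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h^2
      } else {
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) -
             fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h^2)
      }
    }
  }
  H
}

# invert a Hessian into a covariance, repairing to positive-definite by
# flooring eigenvalues
hessian_to_cov <- function(H, floor = 1e-6) {
  H <- (H + t(H)) / 2
  ei <- eigen(H, symmetric = TRUE)
  vals <- pmax(ei$values, floor)
  ei$vectors %*% diag(1 / vals, nrow = length(vals)) %*% t(ei$vectors)
}

#' Maximum a posteriori fit of one subject
#'
#' Maximizes `log p(C | theta) + log N(theta; xi)` in transformed parameter
#' space by quasi-Newton (BFGS) search with multiple restarts jittered
#' around the prior mean, and computes the Laplace posterior: a Gaussian at
#' the optimum whose covariance is the inverse of the numerical Hessian of
#' the negative log joint (central differences, positive-definite repaired
#' by eigenvalue flooring).
#'
#' @param model Model name or [model_spec()].
#' @param data One subject's trial sequence.
#' @param prior A [population_prior()]; defaults to the model's.
#' @param n_restarts Number of optimization starts (first is the prior
#'   mean, or `init` when given).
#' @param init Optional warm-start vector in transformed space.
#' @param seed Optional seed for the restart jitter.
#' @return An object of class `subject_posterior`: `theta_map` (transformed),
#'   `params` (native), `sigma` (Laplace covariance), `log_joint`, `nll`,
#'   `n_valid`, `converged`.
#' @export
fit_map <- function(model, data, prior = NULL, n_restarts = 5, init = NULL,
                    seed = NULL) {
  spec <- resolve_model(model)
  if (is.null(prior)) prior <- default_prior(spec)
  stopifnot(inherits(prior, "population_prior"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  prep <- prepare_sequence(data)
  m <- prior$mean[spec$par_names]
  v <- prior$var[spec$par_names]
  nll_fn <- make_nll_fn(spec, prep)
  to_native <- make_native_fn(spec)
  nlp <- function(x) {
    val <- nll_fn(to_native(x)) + 0.5 * sum((x - m)^2 / v)
    if (!is.finite(val)) 1e12 else val
  }
  jitter_sd <- pmin(sqrt(v), 2)
  # first two starts are deterministic (warm start and prior mean);
  # further restarts jitter around the prior mean
  starts <- list(if (is.null(init)) m else init)
  if (!is.null(init) && n_restarts > 1) starts <- c(starts, list(m))
  while (length(starts) < n_restarts)
    starts[[length(starts) + 1]] <- m + stats::rnorm(length(m)) * jitter_sd
  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, nlp, method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (opt$convergence == 0) any_conv <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop(sprintf("all %d restarts failed for model %s", n_restarts,
                 spec$name))
  xhat <- best$par
  names(xhat) <- spec$par_names
  H <- numerical_hessian(nlp, xhat)
  nll_hat <- .nll_prepared(spec, from_transformed(xhat, spec), prep)
  h_lik <- H - diag(1 / v, nrow = length(v))
  post <- laplace_posterior(xhat, nll_hat, h_lik, m, v)
  structure(c(post,
              list(params = from_transformed(xhat, spec),
                   n_valid = prep$n_valid, converged = any_conv,
                   model = spec$name)),
            class = "subject_posterior")
}

# Assemble the Laplace posterior of one subject under a given prior from
# cached pieces: the MAP location, its data likelihood and the likelihood
# part of the Hessian (which does not depend on the prior). The penalized
# Hessian provably dominates the prior precision, so its eigenvalues are
# floored there: flat likelihood directions inherit the prior variance
# instead of an arbitrary (and numerically unstable) ceiling.
laplace_posterior <- function(theta, nll, h_lik, m, v) {
  d <- length(theta)
  H <- h_lik + diag(1 / v, nrow = d)
  sigma <- hessian_to_cov(H, floor = max(1e-6, min(1 / v)))
  log_joint <- -nll - 0.5 * sum((theta - m)^2 / v) -
    0.5 * sum(log(2 * pi * v))
  log_ml <- log_joint + d / 2 * log(2 * pi) +
    0.5 * determinant(sigma)$modulus[1]
  list(theta_map = theta, sigma = sigma, h_lik = h_lik,
       log_joint = log_joint, log_ml_laplace = log_ml, nll = nll)
}

#' Hierarchical empirical-Bayes fit by expectation-maximization
#'
#' Type-II maximum likelihood over a cohort: alternates an E-step (per
#' subject, a MAP fit with Laplace posterior given the current population
#' prior) with an M-step that re-estimates the prior's first and second
#' moments from the subject posteriors (`mean_j = avg(mu_ij)`,
#' `var_j = avg(mu_ij^2 + Sigma_ijj) - mean_j^2`), until the largest
#' hyperparameter change falls below `tol` or `max_iter` is reached. The
#' Laplace approximation of the marginal likelihood is tracked per
#' iteration; negative M-step variances are floored with a warning. After
#' convergence the model's integrated BIC is computed at the final prior.
#'
#' @param model Model name or [model_spec()].
#' @param dataset Tidy choice table (with a `subject` column) or list of
#'   per-subject sequences; at least 2 subjects.
#' @param init_prior Starting [population_prior()] (default: the model's).
#' @param max_iter,tol EM stopping rule.
#' @param n_restarts Restarts for first-iteration MAP fits (later
#'   iterations warm-start from the previous MAP plus one fresh start).
#' @param bic_samples Monte-Carlo sample count for [integrated_bic()]
#'   (set to 0 to skip).
#' @param seed Seed controlling restart jitter and BIC sampling.
#' @return An object of class `fit_result`: subject posteriors, final
#'   prior, per-iteration hyperparameter/objective trajectory, `bic_int`.
#' @export
run_em <- function(model, dataset, init_prior = NULL, max_iter = 100,
                   tol = 1e-3, n_restarts = 3, bic_samples = 1000,
                   seed = NULL) {
  spec <- resolve_model(model)
  seqs <- split_choices(dataset)
  if (length(seqs) < 2) stop("EM needs at least 2 subjects")
  if (!is.null(seed)) set.seed(as.integer(seed))
  prior <- if (is.null(init_prior)) default_prior(spec) else init_prior
  d <- length(spec$par_names)
  fits <- vector("list", length(seqs))
  traj <- list()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m <- prior$mean[spec$par_names]
    v <- prior$var[spec$par_names]
    fits <- lapply(seq_along(seqs), function(i) {
      cand <- fit_map(spec, seqs[[i]], prior,
                      n_restarts = if (it == 1) n_restarts else 2,
                      init = if (it == 1) NULL else fits[[i]]$theta_map)
      if (it == 1) return(cand)
      # keep the previous iteration's optimum if it still yields the
      # higher Laplace marginal under the new prior (guards against
      # spurious basin switches destabilizing the EM objective)
      prev <- fits[[i]]
      kept <- laplace_posterior(prev$theta_map, prev$nll, prev$h_lik, m, v)
      if (kept$log_ml_laplace > cand$log_ml_laplace) {
        cand[names(kept)] <- kept
        cand$params <- from_transformed(kept$theta_map, spec)
      }
      cand
    })
    mu <- vapply(fits, function(f) f$theta_map, numeric(d))
    sg <- vapply(fits, function(f) diag(f$sigma), numeric(d))
    if (d == 1) { mu <- matrix(mu, 1); sg <- matrix(sg, 1) }
    new_mean <- rowMeans(mu)
    new_var <- rowMeans(mu^2 + sg) - new_mean^2
    if (any(new_var <= 0)) {
      warning("M-step produced a non-positive variance; floored at 1e-6")
      new_var <- pmax(new_var, 1e-6)
    }
    names(new_mean) <- names(new_var) <- spec$par_names
    # Laplace approximation of the summed log marginal likelihood
    objective <- sum(vapply(fits, `[[`, numeric(1), "log_ml_laplace"))
    traj[[it]] <- c(iter = it, objective = objective,
                    stats::setNames(prior$mean, paste0("mean_", spec$par_names)),
                    stats::setNames(prior$var, paste0("var_", spec$par_names)))
    delta <- max(abs(c(new_mean - prior$mean[spec$par_names],
                       new_var - prior$var[spec$par_names])))
    prior <- population_prior(new_mean, new_var)
    if (delta < tol) { converged <- TRUE; break }
  }
  trajectory <- as.data.frame(do.call(rbind, traj))
  names(fits) <- names(seqs)
  n_total <- sum(vapply(fits, `[[`, numeric(1), "n_valid"))
  bic <- if (bic_samples > 0)
    integrated_bic(spec, seqs, prior, n_samples = bic_samples)
  else NULL
  structure(list(model = spec$name, subjects = fits, prior = prior,
                 trajectory = trajectory, converged = converged,
                 n_iter = nrow(trajectory), n_subjects = length(seqs),
                 subject_ids = names(seqs), n_total_choices = n_total,
                 bic_int = if (is.null(bic)) NA_real_ else bic$bic_int,
                 bic = bic),
            class = "fit_result")
}

#' Integrated BIC of a model on a cohort
#'
#' Approximates each subject's marginal likelihood by Monte-Carlo
#' integration over the population prior: `n_samples` parameter vectors are
#' drawn from the Gaussian prior, the sequence likelihood is evaluated at
#' each, and the average is taken in log space (log-sum-exp). The group
#' score is `-2 * sum_i log p_hat_i + q * log(N)` where `N` is the total
#' number of valid choices and `q = 2 * (number of free parameters)` counts
#' the fitted hyperparameters (a mean and a variance per parameter). Lower
#' is better.
#'
#' @param model Model name or [model_spec()].
#' @param dataset Choice table or list of sequences.
#' @param prior [population_prior()] whose moments define the sampling
#'   density (typically the EM-estimated prior).
#' @param n_samples Number of Monte-Carlo draws (default 1000).
#' @param seed Optional seed.
#' @return List with `bic_int`, per-subject `log_ml`, `q`, `n_total`,
#'   `n_samples`.
#' @export
integrated_bic <- function(model, dataset, prior, n_samples = 1000,
                           seed = NULL) {
  spec <- resolve_model(model)
  stopifnot(inherits(prior, "population_prior"))
  seqs <- split_choices(dataset)
  if (!is.null(seed)) set.seed(as.integer(seed))
  d <- length(spec$par_names)
  m <- prior$mean[spec$par_names]
  sd_ <- sqrt(prior$var[spec$par_names])
  draws <- matrix(stats::rnorm(n_samples * d), n_samples, d)
  draws <- sweep(sweep(draws, 2, sd_, `*`), 2, m, `+`)
  colnames(draws) <- spec$par_names
  to_native <- make_native_fn(spec)
  natives <- lapply(seq_len(n_samples), function(k) to_native(draws[k, ]))
  log_ml <- vapply(seqs, function(sq) {
    nll_fn <- make_nll_fn(spec, prepare_sequence(sq))
    ll <- -vapply(natives, nll_fn, numeric(1))
    ll[!is.finite(ll)] <- -Inf   # overflowed draws contribute zero likelihood
    lm <- logsumexp(ll) - log(n_samples)
    if (!is.finite(lm))
      stop("all Monte-Carlo samples underflowed; the prior is degenerate")
    lm
  }, numeric(1))
  n_total <- sum(vapply(seqs, function(sq) prepare_sequence(sq)$n_valid,
                        numeric(1)))
  q <- 2L * d
  list(bic_int = -2 * sum(log_ml) + q * log(n_total),
       log_ml = log_ml, q = q, n_total = n_total, n_samples = n_samples)
}

#' Rank fitted models by integrated BIC
#'
#' @param fits List of [run_em()] results fitted to the same dataset.
#' @return A data frame of class `model_comparison`, ascending in
#'   `bic_int`, with deltas to the best model. Ties are broken
#'   alphabetically by model name.
#' @export
compare_models <- function(fits) {
  if (length(fits) < 1) stop("no fits supplied")
  stopifnot(all(vapply(fits, inherits, logical(1), "fit_result")))
  ids <- lapply(fits, `[[`, "subject_ids")
  if (length(unique(vapply(ids, paste, character(1), collapse = "|"))) != 1)
    stop("fits were not computed on the same dataset (subject ids differ)")
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    bic_int = vapply(fits, `[[`, numeric(1), "bic_int"),
    n_iter = vapply(fits, `[[`, numeric(1), "n_iter"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$bic_int, tab$model), , drop = FALSE]
  tab$delta_bic <- tab$bic_int - tab$bic_int[1]
  rownames(tab) <- NULL
  class(tab) <- c("model_comparison", "data.frame")
  tab
}
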