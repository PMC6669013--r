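#' Specification of a synthetic two-group cohort
#'
#' Describes the ground-truth population from which synthetic subjects are
#' drawn: group sizes (defaults mirror a 19-responder / 18-nonresponder
#' cohort), per-group Gaussian means and SDs of the generating model's
#' parameters in transformed space, and the task configuration. The
#' default group effect places the responders' mean logit-rho 0.8
#' population SDs below the nonresponders' (responders smooth more over
#' previous unsigned prediction errors) and their stickiness one SD
#' higher; effect magnitudes are harness choices for recovery studies, not
#' estimates of any real effect.
#'
#' @param n_responders,n_nonresponders Group sizes (>= 2).
#' @param model Generating model name (default `"DYNA_STICK"`).
#' @param mean_nonresponder,mean_responder Named transformed-space means.
#' @param sd Named transformed-space population SDs (> 0).
#' @param task A [task_config()].
#' @param outcome_noise_sd SD of the noise on the simulated continuous
#'   outcome (percent symptom change).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_responders = 19, n_nonresponders = 18,
                        model = "DYNA_STICK",
                        mean_nonresponder = NULL, mean_responder = NULL,
                        sd = NULL, task = task_config(),
                        outcome_noise_sd = 15) {
  stopifnot(n_responders >= 2, n_nonresponders >= 2)
  spec <- resolve_model(model)
  if (is.null(sd)) {
    sd <- c(beta = 0.5, gamma = 0.5, rho = 0.8, stick = 0.3,
            alpha1 = 0.5, S = 0.5, kappa = 0.5, theta = 0.5, mu = 0.5,
            h1 = 0.5)[spec$par_names]
  }
  if (any(is.na(sd)) || any(sd <= 0)) stop("population SDs must be positive")
  if (is.null(mean_nonresponder)) {
    base <- c(beta = log(0.2), gamma = log(0.5), rho = 0, stick = 0.1,
              alpha1 = 0, S = log(0.3), kappa = stats::qlogis(2.2 / 3),
              theta = 0, mu = log(1), h1 = log(0.3))
    mean_nonresponder <- base[spec$par_names]
  }
  if (is.null(mean_responder)) {
    mean_responder <- mean_nonresponder
    if ("rho" %in% spec$par_names)
      mean_responder["rho"] <- mean_responder["rho"] - 0.8 * sd[["rho"]]
    if ("stick" %in% spec$par_names)
      mean_responder["stick"] <- mean_responder["stick"] + sd[["stick"]]
  }
  structure(list(n_responders = n_responders,
                 n_nonresponders = n_nonresponders, model = spec$name,
                 mean_responder = mean_responder[spec$par_names],
                 mean_nonresponder = mean_nonresponder[spec$par_names],
                 sd = sd[spec$par_names], task = task,
                 outcome_noise_sd = outcome_noise_sd),
            class = "cohort_spec")
}

#' Sample a synthetic cohort with known ground truth
#'
#' For each subject, transformed parameters are drawn from the group
#' Gaussian, mapped to native space (the transforms enforce all native
#' bounds by construction), and a model-based agent plays the reversal
#' task via [simulate_model_agent()]. A continuous outcome resembling
#' percent symptom improvement is generated as a noisy decreasing function
#' of the subject's logit-rho (when present; otherwise of the first
#' parameter), clipped to `[-100, 100]`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the full cohort is reproducible from it.
#' @return List with `choices` (tidy multi-subject trial table) and
#'   `truth` (one row per subject: group, native and transformed
#'   parameters, continuous outcome).
#' @export
sample_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  mspec <- model_spec(spec$model)
  d <- length(mspec$par_names)
  n <- spec$n_responders + spec$n_nonresponders
  group <- rep(c("responder", "nonresponder"),
               c(spec$n_responders, spec$n_nonresponders))
  ids <- sprintf("s%02d", seq_len(n))
  key <- if ("rho" %in% mspec$par_names) "rho" else mspec$par_names[1]
  choices <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    m <- if (group[i] == "responder") spec$mean_responder
    else spec$mean_nonresponder
    theta <- m + stats::rnorm(d) * spec$sd
    names(theta) <- mspec$par_names
    native <- from_transformed(theta, mspec)
    sq <- simulate_model_agent(mspec, native, spec$task, subject = ids[i])
    outcome_cont <- 30 - 25 * (theta[[key]] - mean(c(spec$mean_responder[[key]],
                                                     spec$mean_nonresponder[[key]]))) +
      stats::rnorm(1, 0, spec$outcome_noise_sd)
    outcome_cont <- max(-100, min(100, outcome_cont))
    choices[[i]] <- sq
    row <- data.frame(subject = ids[i], group = group[i],
                      stringsAsFactors = FALSE)
    for (pn in mspec$par_names) row[[paste0("t_", pn)]] <- theta[[pn]]
    for (pn in mspec$par_names) row[[pn]] <- native[[pn]]
    row$outcome <- outcome_cont
    truth[[i]] <- row
  }
  list(choices = do.call(rbind, choices), truth = do.call(rbind, truth),
       model = spec$model, spec = spec)
}

#' Sample a synthetic feature table for classifier evaluation
#'
#' Multivariate Gaussian features for two groups; the first
#' `n_informative` features are shifted by `effect_size` (in SD units) in
#' the second group and may be equicorrelated (`correlation`); the rest
#' are independent noise. A continuous outcome is generated as the
#' informative-feature score plus Gaussian noise, rescaled to a
#' percent-change-like range and clipped to `[-100, 100]`.
#'
#' @param n_per_group Length-2 group sizes (default `c(19, 18)`).
#' @param n_features Total feature count.
#' @param n_informative Number of informative features
#'   (<= `n_features`).
#' @param effect_size Between-group mean shift of informative features.
#' @param correlation Equicorrelation among informative features.
#' @param outcome_noise_sd Noise SD on the continuous outcome scale.
#' @param seed Seed.
#' @return List with `x` (matrix), `y` (factor nonresponder/responder),
#'   `outcome` (continuous), `informative` (index vector).
#' @export
sample_feature_table <- function(n_per_group = c(19, 18), n_features = 50,
                                 n_informative = 5, effect_size = 1,
                                 correlation = 0, outcome_noise_sd = 20,
                                 seed = NULL) {
  if (n_informative > n_features)
    stop("`n_informative` must not exceed `n_features`")
  if (n_informative > 1 &&
      (correlation >= 1 || correlation <= -1 / (n_informative - 1)))
    stop("`correlation` does not give a positive-definite block")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- sum(n_per_group)
  x <- matrix(stats::rnorm(n * n_features), n, n_features)
  if (n_informative > 1 && correlation != 0) {
    S <- matrix(correlation, n_informative, n_informative)
    diag(S) <- 1
    x[, seq_len(n_informative)] <-
      x[, seq_len(n_informative), drop = FALSE] %*% chol(S)
  }
  y <- rep(c("nonresponder", "responder"), n_per_group)
  shift <- (y == "responder") * effect_size
  x[, seq_len(n_informative)] <- x[, seq_len(n_informative), drop = FALSE] +
    shift
  colnames(x) <- sprintf("f%03d", seq_len(n_features))
  score <- if (n_informative > 0)
    rowMeans(x[, seq_len(n_informative), drop = FALSE]) else numeric(n)
  outcome <- 25 * score + stats::rnorm(n, 0, outcome_noise_sd)
  outcome <- pmax(-100, pmin(100, outcome))
  list(x = x, y = factor(y, levels = c("nonresponder", "responder")),
       outcome = outcome, informative = seq_len(n_informative))
}

#' Replicated parameter- and model-recovery experiment
#'
#' For each replicate: a cohort is sampled from `spec`, each candidate
#' model is fitted hierarchically by [run_em()], and the integrated BIC
#' plus (for the generating model) the correlations between true and
#' MAP-estimated transformed parameters are recorded. Fitting failures are
#' aggregated into the report rather than aborting the experiment.
#'
#' @param models Character vector of candidate model names; must include
#'   the generating model.
#' @param spec A [cohort_spec()].
#' @param n_replicates Number of replicate cohorts.
#' @param seed Base seed (replicate r uses `seed + r`).
#' @param em_args List of extra arguments for [run_em()] (e.g.
#'   `max_iter`).
#' @return Data frame with one row per replicate x model: `bic_int`,
#'   `converged`, `error`, and `recov_<param>` correlation columns for the
#'   generating model.
#' @export
recovery_experiment <- function(models, spec = cohort_spec(),
                                n_replicates = 10, seed = 1,
                                em_args = list()) {
  stopifnot(spec$model %in% models)
  gen_pars <- model_spec(spec$model)$par_names
  rows <- list()
  for (r in seq_len(n_replicates)) {
    coh <- sample_cohort(spec, seed = seed + r)
    for (mn in models) {
      fit <- tryCatch(
        do.call(run_em, c(list(model = mn, dataset = coh$choices,
                               seed = seed + r), em_args)),
        error = function(e) e)
      row <- data.frame(replicate = r, model = mn, bic_int = NA_real_,
                        converged = NA, error = NA_character_,
                        stringsAsFactors = FALSE)
      for (pn in gen_pars) row[[paste0("recov_", pn)]] <- NA_real_
      if (inherits(fit, "error")) {
        row$error <- conditionMessage(fit)
      } else {
        row$bic_int <- fit$bic_int
        row$converged <- fit$converged
        if (mn == spec$model) {
          est <- t(vapply(fit$subjects, `[[`, numeric(length(gen_pars)),
                          "theta_map"))
          for (pn in gen_pars)
            row[[paste0("recov_", pn)]] <-
              stats::cor(coh$truth[[paste0("t_", pn)]], est[, pn])
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
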