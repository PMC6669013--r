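#' @useDynLib revlearn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

resolve_model <- function(model) {
  if (inherits(model, "model_spec")) model else model_spec(model)
}

# merge free parameters with the model's fixed settings
full_params <- function(params, spec) {
  p <- as.list(params)
  missing <- setdiff(spec$par_names, names(p))
  if (length(missing))
    stop(sprintf("missing parameter(s): %s", paste(missing, collapse = ", ")))
  utils::modifyList(spec$fixed, p[spec$par_names])
}

# prepare integer choice / input codes from a trial sequence
prepare_sequence <- function(data) {
  need <- c("choice", "outcome", "hps_identity")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop(sprintf("data is missing column(s): %s", paste(miss, collapse = ", ")))
  ch <- match(data$choice, c("a", "b"))
  ch[data$choice == "missed"] <- 0L
  if (anyNA(ch)) stop("choice column contains values other than a/b/missed")
  valid <- ch != 0L
  if (!any(valid)) stop("all trials are missed; no choices to evaluate")
  if (anyNA(data$outcome[valid]))
    stop("non-missed trials must have an outcome")
  hps <- match(data$hps_identity, c("a", "b"))
  if (anyNA(hps)) stop("hps_identity must be 'a' or 'b'")
  out <- ifelse(valid, data$outcome, 0)
  reward <- as.numeric(out > 0)
  u <- numeric(length(ch))
  u[valid] <- encode_contingency((ch == hps)[valid], (out > 0)[valid])
  list(ch = as.integer(ch), outcome = as.numeric(out), reward = reward,
       u = u, hps = as.integer(hps), n_valid = sum(valid))
}

run_filter <- function(spec, params, prep) {
  p <- full_params(params, spec)
  switch(spec$name,
    DYNA = ,
    DYNA_STICK = .filter_dyna_cpp(prep$ch, prep$outcome, p$beta, p$gamma,
                                  p$rho, p$stick, p$alpha1, p$v0, p$pemag0,
                                  identical(p$f_form, "tanh")),
    PH = .filter_ph_cpp(prep$ch, prep$reward, p$S, p$alpha1, p$beta, p$v0),
    HGF = .filter_hgf_cpp(prep$ch, prep$u, prep$hps, p$kappa, p$omega,
                          p$theta, p$beta, p$mu2_0, p$sa2_0, p$mu3_0,
                          p$sa3_0),
    K1 = .filter_k1_cpp(prep$ch, prep$u, prep$hps, p$mu, p$h1, p$beta,
                        p$v0, p$b0))
}

#' Trial-wise latent trajectory of a fitted or hypothesized model
#'
#' Runs a model's recursions over one subject's choice/outcome sequence and
#' returns the full latent trajectory: pre-choice stimulus values, choice
#' probabilities, prediction errors, learning rates and the weighted
#' reward-prediction error `alpha * delta` used as the fMRI regressor of
#' interest. Latent state is carried through missed trials without update.
#'
#' @param model Model name or [model_spec()].
#' @param params Named native-space parameter values (free parameters of
#'   the model).
#' @param data A trial sequence: data frame with `choice`
#'   (`"a"`/`"b"`/`"missed"`), `outcome` (numeric, `NA` when missed) and
#'   `hps_identity` columns.
#' @return A data frame of per-trial latents (columns depend on the model;
#'   all models provide `p_a`, `p_obs`, `v_a`, `v_b`), with attributes
#'   `nll` (negative log likelihood of the observed choices) and `n_valid`.
#' @examples
#' seqd <- simulate_task(policy_random(), task_config(n_trials = 30), seed = 1)
#' tr <- model_trajectory("DYNA", c(beta = 1, gamma = 0.5, rho = 0.5), seqd)
#' head(tr)
#' @export
model_trajectory <- function(model, params, data) {
  spec <- resolve_model(model)
  prep <- prepare_sequence(data)
  res <- run_filter(spec, params, prep)
  if (!isTRUE(res$ok))
    stop(sprintf(
      "%s update became numerically unstable at trial %d for the supplied parameters",
      spec$name, res$bad_trial))
  out <- as.data.frame(res$latents)
  out$trial <- seq_len(nrow(out))
  attr(out, "nll") <- res$nll
  attr(out, "n_valid") <- res$n_valid
  attr(out, "model") <- spec$name
  out
}

#' Negative log likelihood of a choice sequence under a model
#'
#' Cross-entropy between observed and predicted choices, summed over
#' non-missed trials: `-sum(log p(observed choice))`. Returns `Inf` when the
#' model's recursions leave their numerically valid region (possible for
#' extreme HGF parameters).
#'
#' @inheritParams model_trajectory
#' @return Non-negative scalar.
#' @export
sequence_nll <- function(model, params, data) {
  spec <- resolve_model(model)
  prep <- prepare_sequence(data)
  run_filter(spec, params, prep)$nll
}

# fast path used by the fitting code: prep computed once per subject
.nll_prepared <- function(spec, params, prep) {
  run_filter(spec, params, prep)$nll
}

# prebound likelihood evaluator: fixed settings and sequence codes are
# captured once, leaving only scalar extraction per call (hot path of MAP
# optimization and integrated-BIC sampling)
make_nll_fn <- function(spec, prep) {
  fx <- spec$fixed
  switch(spec$name,
    DYNA = function(p)
      .filter_dyna_cpp(prep$ch, prep$outcome, p[["beta"]], p[["gamma"]],
                       p[["rho"]], fx$stick, fx$alpha1, fx$v0, fx$pemag0,
                       identical(fx$f_form, "tanh"))$nll,
    DYNA_STICK = function(p)
      .filter_dyna_cpp(prep$ch, prep$outcome, p[["beta"]], p[["gamma"]],
                       p[["rho"]], p[["stick"]], fx$alpha1, fx$v0,
                       fx$pemag0, identical(fx$f_form, "tanh"))$nll,
    PH = function(p)
      .filter_ph_cpp(prep$ch, prep$reward, p[["S"]], p[["alpha1"]],
                     p[["beta"]], fx$v0)$nll,
    HGF = function(p)
      .filter_hgf_cpp(prep$ch, prep$u, prep$hps, p[["kappa"]], fx$omega,
                      p[["theta"]], p[["beta"]], fx$mu2_0, fx$sa2_0,
                      fx$mu3_0, fx$sa3_0)$nll,
    K1 = function(p)
      .filter_k1_cpp(prep$ch, prep$u, prep$hps, p[["mu"]], p[["h1"]],
                     p[["beta"]], fx$v0, fx$b0)$nll)
}

# vectorized native-space mapper (fast equivalent of from_transformed)
make_native_fn <- function(spec) {
  types <- spec$transform$type
  uppers <- spec$transform$upper
  nms <- spec$par_names
  function(x) {
    out <- x
    for (j in seq_along(out)) {
      out[j] <- switch(types[j],
                       log = exp(x[j]),
                       logit = stats::plogis(x[j]),
                       logit_scaled = uppers[j] * stats::plogis(x[j]),
                       identity = x[j])
    }
    names(out) <- nms
    out
  }
}

#' Simulate a model-based agent playing the reversal task
#'
#' Interleaves the task dynamics ([step_task()]) with a learning model's
#' single-trial updates: on each trial the agent chooses by sampling from
#' its sigmoid choice rule, observes the outcome, and updates its latent
#' state. Contingency-space models (HGF, K1) receive inputs coded against
#' the task's current high-probability stimulus, as in fitting.
#'
#' @inheritParams model_trajectory
#' @param config A [task_config()].
#' @param subject Subject id stored in the output.
#' @param seed Optional seed for full reproducibility.
#' @param p_missed Probability of emitting a missed trial.
#' @return A `trial_sequence` data frame as from [simulate_task()].
#' @examples
#' s <- simulate_model_agent("DYNA_STICK",
#'   c(beta = 1, gamma = 0.5, rho = 0.5, stick = 0.2),
#'   task_config(n_trials = 40), seed = 2)
#' @export
simulate_model_agent <- function(model, params, config = task_config(),
                                 subject = "s01", seed = NULL,
                                 p_missed = 0) {
  spec <- resolve_model(model)
  p <- full_params(params, spec)
  if (!is.null(seed)) set.seed(as.integer(seed))
  st <- task_state(config)
  n <- config$n_trials
  choice <- character(n); outcome <- numeric(n); hps_id <- character(n)
  rev_trig <- logical(n); in_buf <- logical(n)
  ms <- switch(spec$name,
    DYNA = ,
    DYNA_STICK = list(v = c(a = p$v0, b = p$v0), alpha = p$alpha1,
                      pemag = p$pemag0),
    PH = list(v = c(a = p$v0, b = p$v0), alpha = p$alpha1),
    HGF = list(mu2 = p$mu2_0, sa2 = p$sa2_0, mu3 = p$mu3_0, sa3 = p$sa3_0),
    K1 = list(v = p$v0, h = p$h1, b = p$b0))
  stick <- if (is.null(p$stick)) 0 else p$stick
  prev <- "none"
  for (t in seq_len(n)) {
    vv <- switch(spec$name,
      DYNA = , DYNA_STICK = , PH = c(ms$v[["a"]], ms$v[["b"]]),
      HGF = {
        vh <- stats::plogis(ms$mu2)
        if (st$hps == "a") c(vh, 1 - vh) else c(1 - vh, vh)
      },
      K1 = if (st$hps == "a") c(ms$v, 1 - ms$v) else c(1 - ms$v, ms$v))
    if (p_missed > 0 && stats::runif(1) < p_missed) {
      ch <- "missed"
    } else {
      p_a <- choice_probability(vv[1], vv[2], p$beta, stick, prev)
      ch <- if (stats::runif(1) < p_a) "a" else "b"
    }
    was_hps <- ch == st$hps
    res <- step_task(st, ch)
    choice[t] <- ch
    outcome[t] <- if (is.na(res$outcome)) NA_real_ else res$outcome
    hps_id[t] <- res$hps_identity
    rev_trig[t] <- res$reversal_triggered
    in_buf[t] <- res$in_buffer
    if (ch != "missed") {
      pos <- outcome[t] > 0
      ms <- switch(spec$name,
        DYNA = , DYNA_STICK = dyna_step(ms, ch, outcome[t], p)$state,
        PH = pearce_hall_step(ms, ch, as.numeric(pos), p)$state,
        HGF = hgf_step(ms, encode_contingency(was_hps, pos), p)$state,
        K1 = k1_step(ms, encode_contingency(was_hps, pos), p)$state)
      prev <- ch
    }
  }
  out <- data.frame(subject = subject, trial = seq_len(n), choice = choice,
                    outcome = outcome, hps_identity = hps_id,
                    reversal_triggered = rev_trig, in_buffer = in_buf,
                    stringsAsFactors = FALSE)
  attr(out, "config") <- config
  class(out) <- c("trial_sequence", "data.frame")
  out
}
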