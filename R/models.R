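# Model registry: the five candidate trial-wise learning models.
#
# DYNA        surprise-weighted dynamic learning rate (smoothed |RPE| slope)
# DYNA_STICK  DYNA plus a choice-autocorrelation (stickiness) parameter
# PH          Pearce-Hall associability (unsigned PE as learning rate)
# HGF         three-level hierarchical Gaussian filter on binary input
# K1          Kalman-filter gain-adaptation variant (Sutton K1 family)
#
# DYNA operates on raw +/-10 outcomes with values initialized at 0; the
# other models operate in the binary space ({1,0} rewards for PH in stimulus
# space, contingency coding for HGF/K1) with values initialized at 0.5.

MODEL_NAMES <- c("DYNA", "DYNA_STICK", "PH", "HGF", "K1")

#' Model specification
#'
#' Returns the specification of one of the five candidate learning models:
#' free-parameter names, native bounds and transforms (log for rates and
#' inverse temperature, logit for probabilities and bounded parameters,
#' identity for the stickiness weight), default population prior in
#' transformed space, and fixed settings (initial conditions, the HGF's
#' fixed tonic volatility `omega = -4`).
#'
#' Priors follow the convention that a native prior mean is mapped through
#' the parameter's transform while the prior variance applies in the
#' transformed (estimation) space.
#'
#' @param name One of `"DYNA"`, `"DYNA_STICK"`, `"PH"`, `"HGF"`, `"K1"`.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("DYNA_STICK")$par_names
#' @export
model_spec <- function(name = MODEL_NAMES) {
  name <- match.arg(name)
  tr <- function(param, type, upper = NA_real_)
    data.frame(param = param, type = type, upper = upper,
               stringsAsFactors = FALSE)
  spec <- switch(name,
    DYNA = list(
      par_names = c("beta", "gamma", "rho"),
      transform = rbind(tr("beta", "log"), tr("gamma", "log"),
                        tr("rho", "logit")),
      prior_mean = c(beta = log(1), gamma = log(0.5), rho = stats::qlogis(0.5)),
      prior_var = c(beta = 100, gamma = 100, rho = 100),
      fixed = list(alpha1 = 0.5, v0 = 0, pemag0 = 0, f_form = "dsig",
                   stick = 0)),
    DYNA_STICK = list(
      par_names = c("beta", "gamma", "rho", "stick"),
      transform = rbind(tr("beta", "log"), tr("gamma", "log"),
                        tr("rho", "logit"), tr("stick", "identity")),
      prior_mean = c(beta = log(1), gamma = log(0.5),
                     rho = stats::qlogis(0.5), stick = 0),
      prior_var = c(beta = 100, gamma = 100, rho = 100, stick = 100),
      fixed = list(alpha1 = 0.5, v0 = 0, pemag0 = 0, f_form = "dsig")),
    PH = list(
      par_names = c("alpha1", "S", "beta"),
      transform = rbind(tr("alpha1", "logit"), tr("S", "log"),
                        tr("beta", "log")),
      prior_mean = c(alpha1 = stats::qlogis(0.5), S = log(0.1), beta = log(1)),
      prior_var = c(alpha1 = 1, S = 8, beta = 16),
      fixed = list(v0 = 0.5)),
    HGF = list(
      par_names = c("kappa", "theta", "beta"),
      transform = rbind(tr("kappa", "logit_scaled", upper = 3),
                        tr("theta", "logit_scaled", upper = 0.005),
                        tr("beta", "log")),
      # kappa native prior mean 2.2 within its (0, 3) bound; theta's stated
      # native mean exceeds its own upper bound, so its transformed prior is
      # centered at the bound-consistent midpoint (theta = 0.0025)
      prior_mean = c(kappa = stats::qlogis(2.2 / 3), theta = 0,
                     beta = log(1)),
      prior_var = c(kappa = 16, theta = 16, beta = 1),
      fixed = list(omega = -4, mu2_0 = 0, sa2_0 = 1, mu3_0 = 1, sa3_0 = 1)),
    K1 = list(
      par_names = c("mu", "h1", "beta"),
      transform = rbind(tr("mu", "log"), tr("h1", "log"), tr("beta", "log")),
      prior_mean = c(mu = log(1), h1 = log(0.005), beta = log(1)),
      prior_var = c(mu = 100, h1 = 16, beta = 1),
      fixed = list(v0 = 0.5, b0 = log(0.1)))
  )
  structure(c(list(name = name), spec), class = "model_spec")
}

#' Parameter transforms between native and estimation space
#'
#' Maps a named vector of native-space parameters to the unconstrained
#' estimation space defined by the model's transforms (`to_transformed`)
#' and back (`from_transformed`). The two are exact inverses for interior
#' parameter values; boundary values (for example `rho = 0`) have no finite
#' transform and raise an error.
#'
#' @param params Named numeric vector of native parameter values.
#' @param x Named numeric vector in transformed space.
#' @param spec A [model_spec()].
#' @return Named numeric vector in the other space.
#' @examples
#' sp <- model_spec("DYNA")
#' p <- c(beta = 1, gamma = 0.5, rho = 0.3)
#' all.equal(from_transformed(to_transformed(p, sp), sp), p)
#' @export
to_transformed <- function(params, spec) {
  stopifnot(inherits(spec, "model_spec"))
  out <- vapply(spec$par_names, function(pn) {
    v <- params[[pn]]
    row <- spec$transform[spec$transform$param == pn, ]
    z <- switch(row$type,
      log = log(v),
      logit = stats::qlogis(v),
      logit_scaled = stats::qlogis(v / row$upper),
      identity = v)
    if (!is.finite(z))
      stop(sprintf(
        "parameter '%s' = %g is on or outside its native bounds; start from an interior value",
        pn, v))
    z
  }, numeric(1))
  names(out) <- spec$par_names
  out
}

#' @rdname to_transformed
#' @export
from_transformed <- function(x, spec) {
  stopifnot(inherits(spec, "model_spec"))
  out <- vapply(spec$par_names, function(pn) {
    z <- x[[pn]]
    row <- spec$transform[spec$transform$param == pn, ]
    switch(row$type,
      log = exp(z),
      logit = stats::plogis(z),
      logit_scaled = row$upper * stats::plogis(z),
      identity = z)
  }, numeric(1))
  names(out) <- spec$par_names
  out
}

#' Contingency-space coding of a binary outcome
#'
#' Codes one trial's feedback into the binary input `u` used by the
#' contingency-space models (HGF, K1): `u = 1` when the outcome is
#' consistent with the current contingency mapping (positive feedback after
#' a high-probability-stimulus choice, or negative feedback after a
#' low-probability-stimulus choice), `u = 0` otherwise.
#'
#' @param choice_is_hps Logical; did the subject choose the HPS?
#' @param outcome_positive Logical; was the outcome positive?
#' @return 0/1 numeric vector.
#' @export
encode_contingency <- function(choice_is_hps, outcome_positive) {
  if (any(is.na(choice_is_hps)) || any(is.na(outcome_positive)))
    stop("missed trials have no contingency code; the caller must skip them")
  as.numeric(choice_is_hps == outcome_positive)
}

#' Double-sigmoid slope modulation of the learning rate
#'
#' Maps the normalized slope `m` of the smoothed unsigned prediction error
#' to a signed modulation factor in (-1, 1). The default form is
#' `f(m) = 2 / (1 + exp(-m / gamma)) - 1`, which is algebraically identical
#' to `tanh(m / (2 gamma))`; `form = "tanh"` uses the steeper alternative
#' `tanh(m / gamma)`. Larger `gamma` flattens the curve, yielding a more
#' surprise-invariant learning rate.
#'
#' @param m Normalized slope (vectorized).
#' @param gamma Positive steepness parameter.
#' @param form `"dsig"` (default) or `"tanh"`.
#' @return Values in (-1, 1) with the sign of `m`.
#' @export
slope_modulation <- function(m, gamma, form = c("dsig", "tanh")) {
  form <- match.arg(form)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0)
    stop("`gamma` must be a single positive number")
  if (form == "dsig") 2 / (1 + exp(-m / gamma)) - 1 else tanh(m / gamma)
}

#' Sigmoid choice rule with optional stickiness
#'
#' Probability of choosing stimulus `a` given the two stimulus values:
#' `p(a) = sigmoid(beta * (v_a - v_b) + stick * c)` where `c` is +1 after a
#' previous `a` choice, -1 after `b`, and 0 when no previous choice exists.
#' Computed through `plogis`, so it saturates without overflow at extreme
#' arguments.
#'
#' @param v_a,v_b Stimulus values.
#' @param beta Non-negative inverse temperature.
#' @param stick Choice-autocorrelation weight (0 for models without it).
#' @param prev_choice `"a"`, `"b"` or `"none"`.
#' @return Probability in (0, 1).
#' @export
choice_probability <- function(v_a, v_b, beta, stick = 0,
                               prev_choice = "none") {
  stopifnot(beta >= 0)
  cc <- switch(prev_choice, a = 1, b = -1, none = 0,
               stop("`prev_choice` must be 'a', 'b' or 'none'"))
  stats::plogis(beta * (v_a - v_b) + stick * cc)
}

#' One trial of the dynamic-learning-rate model
#'
#' Updates the DYNA latent state for one completed trial. The unsigned
#' prediction error is smoothed (`pemag`), its normalized slope `m` is
#' passed through the double sigmoid [slope_modulation()], and the learning
#' rate `alpha` moves toward 1 for positive slopes (surprise rising) and
#' toward 0 for negative slopes. Only the chosen stimulus value is updated,
#' by `alpha * delta` — the weighted reward prediction error.
#'
#' @param state List with `v` (named values `a`, `b`), `alpha`, `pemag`.
#' @param chosen `"a"` or `"b"`.
#' @param outcome Raw outcome (+10 / -10 under the default task).
#' @param params List with `rho` in (0,1), `gamma > 0`, optional `f_form`.
#' @return List with the updated `state` and a `latents` list
#'   (`delta`, `pemag`, `m`, `alpha`, `wrpe`).
#' @export
dyna_step <- function(state, chosen, outcome, params) {
  stopifnot(chosen %in% c("a", "b"))
  rho <- params$rho; gamma <- params$gamma
  if (rho <= 0 || rho >= 1) stop("`rho` must lie strictly in (0, 1)")
  form <- if (is.null(params$f_form)) "dsig" else params$f_form
  delta <- outcome - state$v[[chosen]]
  pemag_new <- rho * abs(delta) + (1 - rho) * state$pemag
  s <- pemag_new + state$pemag
  m <- if (s == 0) 0 else (pemag_new - state$pemag) / (s / 2)
  f <- slope_modulation(m, gamma, form)
  alpha <- state$alpha
  alpha_new <- if (m > 0) alpha + f * (1 - alpha)
  else if (m < 0) alpha + f * alpha
  else alpha
  v <- state$v
  v[[chosen]] <- v[[chosen]] + alpha_new * delta
  list(state = list(v = v, alpha = alpha_new, pemag = pemag_new),
       latents = list(delta = delta, pemag = pemag_new, m = m,
                      alpha = alpha_new, wrpe = alpha_new * delta))
}

#' One trial of the Pearce-Hall model
#'
#' The associability `alpha` is the previous trial's unsigned prediction
#' error (a free initial value on trial 1), scaled by the salience constant
#' `S`; rewards are coded in the unit space (`1` = positive outcome) so the
#' value initialization of 0.5 is commensurate.
#'
#' @param state List with `v` (named values, init 0.5) and `alpha`.
#' @param chosen `"a"` or `"b"`.
#' @param reward 0/1 coded outcome.
#' @param params List with `S > 0`.
#' @return Updated `state` plus `latents` (`delta`, `alpha`, `wrpe`).
#' @export
pearce_hall_step <- function(state, chosen, reward, params) {
  stopifnot(chosen %in% c("a", "b"))
  if (params$S < 0) stop("`S` must be non-negative")
  delta <- reward - state$v[[chosen]]
  v <- state$v
  v[[chosen]] <- v[[chosen]] + params$S * state$alpha * delta
  list(state = list(v = v, alpha = abs(delta)),
       latents = list(delta = delta, alpha = state$alpha,
                      wrpe = params$S * state$alpha * delta))
}

#' One trial of the three-level binary hierarchical Gaussian filter
#'
#' Variational one-step update of the level-2 (contingency tendency) and
#' level-3 (log volatility) posteriors given the binary contingency input
#' `u`. The predicted contingency probability is `sigmoid(mu2)`; updates are
#' precision-weighted prediction errors, with phasic (`kappa * mu3`) and
#' tonic (`omega`) components of the level-2 process variance and constant
#' level-3 variance `theta`.
#'
#' @param state List with `mu2`, `sa2`, `mu3`, `sa3` (variances positive).
#' @param u Binary input (0 or 1).
#' @param params List with `kappa`, `omega`, `theta`.
#' @return Updated `state` plus `latents` (`muhat1`, `delta1`, `delta2`,
#'   `pihat2`).
#' @export
hgf_step <- function(state, u, params) {
  stopifnot(u %in% c(0, 1), state$sa2 > 0, state$sa3 > 0)
  kappa <- params$kappa; omega <- params$omega; theta <- params$theta
  muhat1 <- stats::plogis(state$mu2)
  delta1 <- u - muhat1
  v2 <- exp(kappa * state$mu3 + omega)
  pihat2 <- 1 / (state$sa2 + v2)
  pi2 <- pihat2 + muhat1 * (1 - muhat1)
  mu2 <- state$mu2 + delta1 / pi2
  sa2 <- 1 / pi2
  pihat3 <- 1 / (state$sa3 + theta)
  w2 <- v2 * pihat2
  delta2 <- ((1 / pi2) + (mu2 - state$mu2)^2) * pihat2 - 1
  pi3 <- pihat3 + (kappa^2 / 2) * w2 * (w2 + (2 * w2 - 1) * delta2)
  if (!is.finite(pi3) || pi3 <= 0)
    stop(sprintf(
      "level-3 precision became non-positive (kappa = %g, omega = %g, theta = %g)",
      kappa, omega, theta))
  mu3 <- state$mu3 + (kappa / (2 * pi3)) * w2 * delta2
  sa3 <- 1 / pi3
  list(state = list(mu2 = mu2, sa2 = sa2, mu3 = mu3, sa3 = sa3),
       latents = list(muhat1 = muhat1, delta1 = delta1, delta2 = delta2,
                      pihat2 = pihat2))
}

#' One trial of the Kalman-filter gain-adaptation (K1) variant
#'
#' Tracks the contingency probability `v` with a learning rate that is an
#' exponentiated log-gain trace `b`, itself meta-learned at rate `mu` from
#' the product of the prediction error and a decaying eligibility trace
#' `h`. The log-gain is clipped above at 0 so the gain never exceeds 1.
#' A zero prediction error leaves the state untouched.
#'
#' @param state List with `v`, `h`, `b`.
#' @param u Binary contingency input (0 or 1).
#' @param params List with `mu > 0`.
#' @return Updated `state` plus `latents` (`delta`, `gain`, `wrpe`).
#' @export
k1_step <- function(state, u, params) {
  stopifnot(u %in% c(0, 1))
  if (params$mu < 0) stop("`mu` must be non-negative")
  delta <- u - state$v
  if (delta == 0)
    return(list(state = state,
                latents = list(delta = 0, gain = exp(state$b), wrpe = 0)))
  b_raw <- state$b + params$mu * delta * state$h
  if (b_raw > 0) warning("log-gain exceeded 0; clipped (gain capped at 1)")
  b <- min(b_raw, 0)
  k <- exp(b)
  v <- state$v + k * delta
  h <- state$h * max(0, 1 - k) + k * delta
  list(state = list(v = v, h = h, b = b),
       latents = list(delta = delta, gain = k, wrpe = k * delta))
}
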