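#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: a response peaking near `peak_delay`
#' seconds and an undershoot peaking near `undershoot_delay` seconds scaled
#' by `undershoot_ratio`, sampled on a grid of step `dt` and normalized to
#' unit peak.
#'
#' @param dt Sampling step in seconds (> 0).
#' @param duration Kernel length in seconds (default 32).
#' @param peak_delay,undershoot_delay Gamma shape parameters (seconds, with
#'   unit dispersion these equal the density shapes minus scale effects).
#' @param undershoot_ratio Relative undershoot amplitude (default 1/6).
#' @param dispersion Common gamma scale (default 1).
#' @return Numeric kernel sampled at `seq(0, duration, by = dt)`.
#' @export
hrf_double_gamma <- function(dt, duration = 32, peak_delay = 6,
                             undershoot_delay = 16, undershoot_ratio = 1 / 6,
                             dispersion = 1) {
  if (dt <= 0) stop("`dt` must be positive")
  if (peak_delay <= 0 || undershoot_delay <= 0 || dispersion <= 0 ||
      undershoot_ratio < 0)
    stop("HRF shape parameters must be positive")
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = peak_delay / dispersion, scale = dispersion) -
    undershoot_ratio *
    stats::dgamma(t, shape = undershoot_delay / dispersion,
                  scale = dispersion)
  h / max(h)
}

# boxcar-convolve one event set onto a TR grid with oversampling
convolve_events <- function(onsets, durations, amplitudes, n_frames, tr,
                            oversampling, kernel_args = list()) {
  dt <- tr / oversampling
  n_hi <- n_frames * oversampling
  x <- numeric(n_hi)
  for (i in seq_along(onsets)) {
    if (is.na(amplitudes[i]) || amplitudes[i] == 0) next
    i0 <- floor(onsets[i] / dt) + 1
    i1 <- ceiling((onsets[i] + durations[i]) / dt)
    if (i0 > n_hi) next
    idx <- i0:min(i1, n_hi)
    x[idx] <- x[idx] + amplitudes[i]
  }
  k <- do.call(hrf_double_gamma, c(list(dt = dt), kernel_args))
  y <- stats::convolve(x, rev(k), type = "open")[seq_len(n_hi)]
  y[seq(1, n_hi, by = oversampling)]
}

#' Build a model-derived first-level fMRI design matrix
#'
#' Constructs the task regressors of the first-level GLM from per-trial
#' event timing and a model's latent trajectory. Decision phase: parametric
#' expected value of the chosen and unchosen stimulus, an unmodulated
#' visual regressor, and a reaction-time-modulated motor regressor.
#' Outcome phase: the weighted reward-prediction error `alpha * delta`
#' (regressor of interest), the unsigned RPE magnitude, unmodulated
#' positive- and negative-outcome indicators, and (when missed trials
#' exist) a lost-trials nuisance regressor. Parametric modulators are
#' mean-centered across valid trials before convolution; all task
#' regressors are boxcars convolved with [hrf_double_gamma()] on a grid
#' oversampled `oversampling` times relative to the repetition time.
#' Motion columns, if supplied, are appended unconvolved.
#'
#' @param events Data frame with one row per trial: `onset_decision`,
#'   `onset_outcome` (seconds, strictly increasing), optional
#'   `dur_decision` (default 1.25), `dur_outcome` (default 0.65), `rt`
#'   (reaction time, seconds) and `missed` (logical).
#' @param trajectory Latent trajectory from [model_trajectory()], aligned
#'   to `events` by trial; needs columns `v_a`, `v_b`, `delta`, `wrpe` and
#'   the originating sequence's choices via the `choice` argument.
#' @param choice Character vector of choices (`"a"`/`"b"`/`"missed"`)
#'   aligned to trials (used to pick chosen/unchosen values).
#' @param motion Optional matrix of 6 motion parameters per frame.
#' @param tr Repetition time in seconds (default 2).
#' @param n_frames Number of volumes; default covers the last event plus
#'   24 s.
#' @param oversampling Convolution oversampling factor (default 16).
#' @return Object of class `design_matrix`: `matrix` (frames x regressors),
#'   `frame_times`, `provenance` (phase and modulator per column) and the
#'   [collinearity_check()] of the task columns.
#' @export
build_design <- function(events, trajectory, choice, motion = NULL, tr = 2,
                         n_frames = NULL, oversampling = 16) {
  n <- nrow(events)
  if (nrow(trajectory) != n || length(choice) != n)
    stop(sprintf("events (%d), trajectory (%d) and choice (%d) must align by trial",
                 n, nrow(trajectory), length(choice)))
  if (is.unsorted(events$onset_decision, strictly = TRUE) ||
      is.unsorted(events$onset_outcome, strictly = TRUE))
    stop("onsets must be strictly increasing")
  dur_dec <- if ("dur_decision" %in% names(events)) events$dur_decision
  else rep(1.25, n)
  dur_out <- if ("dur_outcome" %in% names(events)) events$dur_outcome
  else rep(0.65, n)
  rt <- if ("rt" %in% names(events)) events$rt else rep(0.5, n)
  missed <- if ("missed" %in% names(events)) events$missed
  else choice == "missed"
  valid <- !missed
  if (is.null(n_frames))
    n_frames <- ceiling((max(events$onset_outcome + dur_out) + 24) / tr)

  center <- function(x) {
    x[valid] <- x[valid] - mean(x[valid], na.rm = TRUE)
    x[!valid] <- 0
    x
  }
  ev_chosen <- ifelse(choice == "a", trajectory$v_a,
                      ifelse(choice == "b", trajectory$v_b, NA))
  ev_unchosen <- ifelse(choice == "a", trajectory$v_b,
                        ifelse(choice == "b", trajectory$v_a, NA))
  pos <- valid & !is.na(trajectory$delta) & trajectory$delta >= 0
  neg <- valid & !is.na(trajectory$delta) & trajectory$delta < 0

  cols <- list(
    ev_chosen = list(on = events$onset_decision[valid], du = dur_dec[valid],
                     am = center(ev_chosen)[valid], phase = "decision",
                     mod = "expected value, chosen"),
    ev_unchosen = list(on = events$onset_decision[valid],
                       du = dur_dec[valid], am = center(ev_unchosen)[valid],
                       phase = "decision", mod = "expected value, unchosen"),
    visual = list(on = events$onset_decision[valid], du = dur_dec[valid],
                  am = rep(1, sum(valid)), phase = "decision", mod = "none"),
    motor = list(on = events$onset_decision[valid], du = dur_dec[valid],
                 am = center(rt)[valid], phase = "decision",
                 mod = "reaction time"),
    wrpe = list(on = events$onset_outcome[valid], du = dur_out[valid],
                am = center(trajectory$wrpe)[valid], phase = "outcome",
                mod = "weighted RPE"),
    rpe_mag = list(on = events$onset_outcome[valid], du = dur_out[valid],
                   am = center(abs(trajectory$delta))[valid],
                   phase = "outcome", mod = "RPE magnitude"),
    outcome_pos = list(on = events$onset_outcome[valid & pos],
                       du = dur_out[valid & pos],
                       am = rep(1, sum(valid & pos)), phase = "outcome",
                       mod = "positive outcome"),
    outcome_neg = list(on = events$onset_outcome[valid & neg],
                       du = dur_out[valid & neg],
                       am = rep(1, sum(valid & neg)), phase = "outcome",
                       mod = "negative outcome"))
  if (stats::sd(rt[valid]) == 0) {
    # a constant RT carries no modulation: the regressor would reduce to a
    # copy of the visual boxcar, so it is dropped
    cols$motor <- NULL
  }
  if (any(missed))
    cols$lost <- list(on = events$onset_decision[missed],
                      du = dur_dec[missed], am = rep(1, sum(missed)),
                      phase = "decision", mod = "lost trials")

  X <- vapply(cols, function(cl)
    convolve_events(cl$on, cl$du, cl$am, n_frames, tr, oversampling),
    numeric(n_frames))
  prov <- data.frame(column = names(cols),
                     phase = vapply(cols, `[[`, character(1), "phase"),
                     modulator = vapply(cols, `[[`, character(1), "mod"),
                     stringsAsFactors = FALSE)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_frames)
      stop("motion parameters must have one row per frame")
    colnames(motion) <- paste0("motion_", seq_len(ncol(motion)))
    X <- cbind(X, motion)
    prov <- rbind(prov, data.frame(column = colnames(motion),
                                   phase = "nuisance",
                                   modulator = "motion"))
  }
  task_cols <- X[, seq_along(cols), drop = FALSE]
  sds <- apply(task_cols, 2, stats::sd)
  degenerate <- colnames(task_cols)[sds == 0]
  diag_ <- collinearity_check(task_cols[, sds > 0, drop = FALSE])
  if (length(degenerate)) {
    warning(sprintf("degenerate (all-zero) regressor(s): %s",
                    paste(degenerate, collapse = ", ")))
    diag_$singular <- TRUE
  }
  diag_$degenerate <- degenerate
  structure(list(matrix = X, frame_times = (seq_len(n_frames) - 1) * tr,
                 provenance = prov, collinearity = diag_, tr = tr),
            class = "design_matrix")
}

#' Collinearity diagnostics for a design matrix
#'
#' Condition number from the singular values of the column-standardized
#' matrix, plus variance-inflation factors from the inverse correlation
#' matrix. A zero-variance column is an error naming the column; an exactly
#' singular correlation matrix is reported with infinite VIFs and flagged.
#'
#' @param X Numeric matrix with at least 2 columns.
#' @return List with `condition_number`, `vif` (named), `singular` flag.
#' @export
collinearity_check <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 columns")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop(sprintf("zero-variance column(s): %s", paste(bad, collapse = ", ")))
  }
  Z <- scale(X)
  sv <- svd(Z, nu = 0, nv = 0)$d
  cond <- if (min(sv) < max(sv) * 1e-12) Inf else max(sv) / min(sv)
  R <- stats::cor(X)
  vif <- tryCatch(diag(solve(R)),
                  error = function(e) rep(Inf, ncol(X)))
  names(vif) <- colnames(X)
  list(condition_number = cond, vif = vif,
       singular = !is.finite(cond) || any(!is.finite(vif)))
}

#' Default event timing for a simulated sequence
#'
#' Generates a plain event table (decision and outcome onsets) for a
#' simulated task sequence, with fixed phase durations and inter-stimulus
#' intervals. Jittered presentation timing is a scanner-efficiency concern
#' only and is not modeled.
#'
#' @param data A trial sequence.
#' @param dur_decision,dur_outcome Phase durations in seconds.
#' @param isi Interval between decision offset and outcome onset.
#' @param iti Interval between outcome offset and the next trial.
#' @param rt Reaction times in seconds (recycled). The default is a
#'   deterministic pattern varying between 0.35 and 0.75 s so that the
#'   RT-modulated motor regressor is well defined.
#' @return Event data frame usable with [build_design()].
#' @export
make_event_table <- function(data, dur_decision = 1.25, dur_outcome = 0.65,
                             isi = 2, iti = 2, rt = NULL) {
  n <- nrow(data)
  if (is.null(rt)) rt <- 0.35 + 0.4 * (seq_len(n) %% 7) / 7
  trial_len <- dur_decision + isi + dur_outcome + iti
  onset_dec <- (seq_len(n) - 1) * trial_len
  data.frame(trial = seq_len(n), onset_decision = onset_dec,
             dur_decision = dur_decision,
             onset_outcome = onset_dec + dur_decision + isi,
             dur_outcome = dur_outcome, rt = rep_len(rt, n),
             missed = data$choice == "missed")
}
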