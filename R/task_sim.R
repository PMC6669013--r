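#' Configuration of the probabilistic reversal-learning task
#'
#' Builds the configuration object for the self-paced two-armed reversal
#' bandit. One stimulus (the high-probability stimulus, HPS) yields the
#' positive outcome with probability `p_pos_hps`, the other with
#' `1 - p_pos_hps`, so the expected values of the two stimuli are of equal
#' magnitude and opposite sign. Contingencies reverse once the subject has
#' chosen the HPS `criterion` times over the last `window` completed trials,
#' after a buffer of zero-truncated-Poisson length that conceals the rule.
#'
#' @param n_trials Number of trials (default 180).
#' @param p_pos_hps Probability of a positive outcome when the HPS is
#'   chosen (default 0.70).
#' @param outcome_values Numeric pair `c(positive, negative)` delivered as
#'   feedback (default `c(10, -10)`).
#' @param window Width of the sliding window of completed trials over which
#'   HPS choices are counted (default 6).
#' @param criterion Number of HPS choices within the window that triggers a
#'   reversal (default 5).
#' @param buffer_lambda Rate of the zero-truncated Poisson distribution from
#'   which the number of buffer trials before each reversal is drawn
#'   (default 2).
#' @return An object of class `task_config` (a list of the above fields).
#' @examples
#' cfg <- task_config()
#' cfg$n_trials
#' @export
task_config <- function(n_trials = 180L, p_pos_hps = 0.70,
                        outcome_values = c(10, -10), window = 6L,
                        criterion = 5L, buffer_lambda = 2.0) {
  n_trials <- as.integer(n_trials)
  window <- as.integer(window)
  criterion <- as.integer(criterion)
  stopifnot(n_trials >= 1L, window >= 1L, criterion >= 1L)
  if (p_pos_hps <= 0 || p_pos_hps >= 1)
    stop("`p_pos_hps` must lie strictly between 0 and 1")
  if (criterion > window)
    stop("`criterion` must not exceed `window`")
  if (length(outcome_values) != 2L || outcome_values[1] == outcome_values[2])
    stop("`outcome_values` must be two distinct numbers")
  if (!is.finite(buffer_lambda) || buffer_lambda <= 0)
    stop("`buffer_lambda` must be a positive rate")
  structure(list(n_trials = n_trials, p_pos_hps = p_pos_hps,
                 outcome_values = as.numeric(outcome_values),
                 window = window, criterion = criterion,
                 buffer_lambda = buffer_lambda),
            class = "task_config")
}

#' Draw a zero-truncated Poisson buffer length
#'
#' Samples the number of buffer trials interposed between a triggered
#' reversal and the actual contingency flip: Poisson(`lambda`) conditioned
#' on being at least 1, drawn by inverse-CDF on the truncated distribution.
#'
#' @param lambda Positive Poisson rate.
#' @param n Number of draws.
#' @return Integer vector of draws, each `>= 1`.
#' @examples
#' set.seed(1)
#' mean(sample_buffer_length(2, n = 1000))   # ~ 2 / (1 - exp(-2))
#' @export
sample_buffer_length <- function(lambda, n = 1L) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0)
    stop("`lambda` must be a single positive number")
  # inverse-CDF on the zero-truncated distribution: u uniform on
  # (P(X = 0), 1] picks a quantile of the untruncated Poisson >= 1
  p0 <- exp(-lambda)
  u <- p0 + stats::runif(n) * (1 - p0)
  k <- stats::qpois(pmin(u, 1 - 1e-16), lambda)
  pmax(as.integer(k), 1L)
}

#' Initialize task state
#'
#' @param config A [task_config()].
#' @param hps Initial identity of the high-probability stimulus,
#'   `"a"` or `"b"`.
#' @return An environment of class `task_state` holding the evolving task
#'   bookkeeping (current HPS, reversal window, buffer countdown).
#' @export
task_state <- function(config = task_config(), hps = "a") {
  stopifnot(inherits(config, "task_config"), hps %in% c("a", "b"))
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$hps <- hps
  st$trial <- 0L
  st$window_hps <- logical(0)  # HPS flags of completed trials since last flip
  st$in_buffer <- FALSE
  st$buffer_remaining <- 0L
  st$n_reversals <- 0L
  st$finished <- FALSE
  class(st) <- c("task_state", "environment")
  st
}

#' Advance the task by one trial
#'
#' Plays one choice against the current contingencies, mutating `state`.
#' Missed choices yield no outcome and are excluded from the reversal
#' window. The reversal criterion (`criterion`-of-last-`window` HPS choices)
#' is evaluated on completed trials only, once at least `criterion` of them
#' have accrued since the last reversal; during the buffer countdown the
#' pre-reversal contingencies remain in force and criterion counting is
#' suspended, and the HPS identity flips when the buffer expires.
#'
#' @param state A [task_state()]; modified in place.
#' @param choice `"a"`, `"b"` or `"missed"`.
#' @return A list with `outcome` (numeric, `NA` for a missed trial),
#'   `hps_identity` (HPS in force on this trial), `reversal_triggered` and
#'   `in_buffer` flags.
#' @export
step_task <- function(state, choice) {
  stopifnot(inherits(state, "task_state"))
  if (state$finished) stop("task is finished: all trials have been played")
  if (!choice %in% c("a", "b", "missed"))
    stop(sprintf("invalid choice '%s'", as.character(choice)[1]))
  cfg <- state$config
  state$trial <- state$trial + 1L
  hps_now <- state$hps
  in_buffer <- state$in_buffer

  if (choice == "missed") {
    outcome <- NA_real_
  } else {
    is_hps <- choice == hps_now
    p_pos <- if (is_hps) cfg$p_pos_hps else 1 - cfg$p_pos_hps
    outcome <- if (stats::runif(1) < p_pos) cfg$outcome_values[1] else
      cfg$outcome_values[2]
  }

  reversal_triggered <- FALSE
  if (in_buffer) {
    # countdown runs per trial, missed or not; contingencies unchanged
    state$buffer_remaining <- state$buffer_remaining - 1L
    if (state$buffer_remaining <= 0L) {
      state$hps <- if (state$hps == "a") "b" else "a"
      state$in_buffer <- FALSE
      state$window_hps <- logical(0)
      state$n_reversals <- state$n_reversals + 1L
    }
  } else if (choice != "missed") {
    w <- c(state$window_hps, choice == hps_now)
    if (length(w) > cfg$window) w <- w[(length(w) - cfg$window + 1L):length(w)]
    state$window_hps <- w
    if (length(w) >= cfg$criterion && sum(w) >= cfg$criterion) {
      reversal_triggered <- TRUE
      state$in_buffer <- TRUE
      state$buffer_remaining <- sample_buffer_length(cfg$buffer_lambda)
    }
  }

  if (state$trial >= cfg$n_trials) state$finished <- TRUE
  list(outcome = outcome, hps_identity = hps_now,
       reversal_triggered = reversal_triggered, in_buffer = in_buffer)
}

#' Simulate a full task sequence under an arbitrary policy
#'
#' @param policy A function `(history)` returning `"a"`, `"b"` or
#'   `"missed"`, where `history` is the data frame of trial records played
#'   so far (zero rows on the first trial). The history includes the
#'   `hps_identity` column, so omniscient benchmark policies can be written;
#'   behaviorally plausible policies should ignore it.
#' @param config A [task_config()].
#' @param subject Subject identifier stored in the output.
#' @param seed Optional integer seed; when given, the simulation is fully
#'   reproducible.
#' @param hps Initial HPS identity.
#' @return A data frame of class `trial_sequence` with one row per trial and
#'   columns `subject`, `trial`, `choice`, `outcome`, `hps_identity`,
#'   `reversal_triggered`, `in_buffer`. The config is attached as the
#'   `"config"` attribute.
#' @examples
#' seq <- simulate_task(policy_random(), task_config(), seed = 1)
#' nrow(seq)
#' @export
simulate_task <- function(policy, config = task_config(), subject = "s01",
                          seed = NULL, hps = "a") {
  stopifnot(is.function(policy))
  if (!is.null(seed)) set.seed(as.integer(seed))
  st <- task_state(config, hps = hps)
  n <- config$n_trials
  choice <- character(n); outcome <- numeric(n); hps_id <- character(n)
  rev_trig <- logical(n); in_buf <- logical(n)
  hist <- NULL
  for (t in seq_len(n)) {
    hist <- data.frame(subject = rep(subject, t - 1L),
                       trial = seq_len(t - 1L),
                       choice = choice[seq_len(t - 1L)],
                       outcome = outcome[seq_len(t - 1L)],
                       hps_identity = hps_id[seq_len(t - 1L)],
                       reversal_triggered = rev_trig[seq_len(t - 1L)],
                       in_buffer = in_buf[seq_len(t - 1L)],
                       stringsAsFactors = FALSE)
    ch <- policy(hist)
    if (!is.character(ch) || length(ch) != 1L ||
        !ch %in% c("a", "b", "missed"))
      stop(sprintf("policy returned an invalid choice on trial %d", t))
    res <- step_task(st, ch)
    choice[t] <- ch
    outcome[t] <- if (is.na(res$outcome)) NA_real_ else res$outcome
    hps_id[t] <- res$hps_identity
    rev_trig[t] <- res$reversal_triggered
    in_buf[t] <- res$in_buffer
  }
  out <- data.frame(subject = subject, trial = seq_len(n), choice = choice,
                    outcome = outcome, hps_identity = hps_id,
                    reversal_triggered = rev_trig, in_buffer = in_buf,
                    stringsAsFactors = FALSE)
  attr(out, "config") <- config
  class(out) <- c("trial_sequence", "data.frame")
  out
}

#' Benchmark policies for the reversal task
#'
#' `policy_always_hps()` picks the high-probability stimulus recorded on the
#' previous trial (it therefore lags the true identity by exactly one trial
#' after each concealed flip), `policy_never_hps()` avoids it, and
#' `policy_random()` picks uniformly, missing with probability `p_missed`.
#' For an exactly omniscient agent, drive [step_task()] directly with the
#' state's current `hps`.
#'
#' @param p_missed Probability that `policy_random()` emits a missed trial.
#' @return A policy function usable with [simulate_task()].
#' @export
policy_always_hps <- function() {
  function(history) {
    if (nrow(history) == 0L) return("a")
    history$hps_identity[nrow(history)]
  }
}

#' @rdname policy_always_hps
#' @export
policy_never_hps <- function() {
  function(history) {
    if (nrow(history) == 0L) return("b")
    if (history$hps_identity[nrow(history)] == "a") "b" else "a"
  }
}

#' @rdname policy_always_hps
#' @export
policy_random <- function(p_missed = 0) {
  function(history) {
    if (p_missed > 0 && stats::runif(1) < p_missed) return("missed")
    if (stats::runif(1) < 0.5) "a" else "b"
  }
}
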