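#' Exact binomial exceedance test
#'
#' Probability of observing at least `k` successes in `n` Bernoulli trials
#' with success probability `p0`, computed by direct summation of the
#' binomial mass — the test used to check that choice performance (or a
#' classifier's pooled accuracy) is better than chance. `alternative =
#' "two.sided"` sums all outcomes no more probable than the observed one.
#'
#' @param k Observed success count.
#' @param n Number of trials.
#' @param p0 Null success probability (default 0.5).
#' @param alternative `"greater"` (default, exceedance) or `"two.sided"`.
#' @return The p-value.
#' @examples
#' binomial_exceedance_test(10, 10)   # 1/1024
#' @export
binomial_exceedance_test <- function(k, n, p0 = 0.5,
                                     alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      k < 0 || n < 1 || k > n || k != round(k) || n != round(n))
    stop("`k` and `n` must be integers with 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) stop("`p0` must lie in (0, 1)")
  mass <- stats::dbinom(0:n, n, p0)
  if (alternative == "greater") {
    sum(mass[(k + 1):(n + 1)])
  } else {
    min(1, sum(mass[mass <= mass[k + 1] * (1 + 1e-7)]))
  }
}

#' Calibration of predicted choice propensities by quintile
#'
#' Bins predicted choice probabilities at their empirical quintiles
#' (right-closed edges) and compares each bin's mean prediction to the
#' observed choice frequency; the Pearson correlation across bins
#' summarizes calibration strength.
#'
#' @param predicted_probs Predicted probabilities of the indexed event.
#' @param choices 0/1 indicator (or logical) of the event per trial.
#' @param n_bins Number of bins (default 5).
#' @return List of class `calibration_table`: per-bin `mean_pred`,
#'   `freq_obs`, `count`, plus `r` (Pearson across bins).
#' @export
calibration_quintiles <- function(predicted_probs, choices, n_bins = 5) {
  choices <- as.numeric(choices)
  keep <- !is.na(predicted_probs) & !is.na(choices)
  p <- predicted_probs[keep]; y <- choices[keep]
  if (length(p) < n_bins) stop("need at least `n_bins` valid trials")
  edges <- stats::quantile(p, probs = seq(0, 1, length.out = n_bins + 1))
  if (anyDuplicated(edges))
    stop("degenerate bins: predicted propensities are too concentrated to split into quintiles")
  bin <- cut(p, breaks = edges, include.lowest = TRUE, right = TRUE)
  tab <- data.frame(
    bin = levels(bin),
    mean_pred = as.numeric(tapply(p, bin, mean)),
    freq_obs = as.numeric(tapply(y, bin, mean)),
    count = as.integer(table(bin)))
  structure(list(table = tab, r = stats::cor(tab$mean_pred, tab$freq_obs),
                 n = length(p), n_bins = n_bins),
            class = "calibration_table")
}

#' Average predictive probability of a fitted model
#'
#' Mean probability the model assigned to the choices actually observed,
#' either pooled over all valid trials (`mode = "pooled"`) or averaged
#' within subject first (`mode = "subject"`).
#'
#' @param p_obs Per-trial probability of the observed choice (`NA` on
#'   missed trials), e.g. the `p_obs` column of [model_trajectory()].
#' @param subject Optional subject ids, required for `mode = "subject"`.
#' @param mode Pooling mode.
#' @return Scalar in (0, 1).
#' @export
mean_predictive_probability <- function(p_obs, subject = NULL,
                                        mode = c("pooled", "subject")) {
  mode <- match.arg(mode)
  if (mode == "pooled") return(mean(p_obs, na.rm = TRUE))
  if (is.null(subject)) stop("`subject` is required for mode = 'subject'")
  mean(tapply(p_obs, subject, mean, na.rm = TRUE))
}

# percentage-bend measure of location (Wilcox)
pb_location <- function(x, bend) {
  w <- sort(abs(x - stats::median(x)))
  omega <- w[floor((1 - bend) * length(x))]
  if (omega <= 0) stop("zero scale: too many tied values for the bend constant")
  psi <- (x - stats::median(x)) / omega
  i1 <- sum(psi < -1); i2 <- sum(psi > 1)
  sx <- ifelse(psi < -1, 0, ifelse(psi > 1, 0, x))
  (sum(sx) + omega * (i2 - i1)) / (length(x) - i1 - i2)
}

#' Percentage-bend correlation
#'
#' Wilcox's robust correlation: each variable is centered at its
#' percentage-bend measure of location, scaled by the `(1 - bend)` quantile
#' of absolute deviations from the median, winsorized at +/-1, and the
#' normalized cross-product of the winsorized scores is returned. With
#' `bend = 0.2` this is the 20% bend correlation.
#'
#' @param x,y Numeric vectors of equal length (>= 4).
#' @param bend Bend constant in (0, 0.5) (default 0.2).
#' @return Correlation in `[-1, 1]`, with attributes `statistic` (the
#'   t-ratio) and `p_value` (two-sided, t with n - 2 df).
#' @export
percentage_bend_correlation <- function(x, y, bend = 0.2) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  score <- function(v) {
    w <- sort(abs(v - stats::median(v)))
    omega <- w[floor((1 - bend) * n)]
    if (omega <= 0) stop("zero scale: too many tied values for the bend constant")
    pmin(pmax((v - pb_location(v, bend)) / omega, -1), 1)
  }
  a <- score(x); b <- score(y)
  r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  structure(r, statistic = tstat,
            p_value = 2 * stats::pt(-abs(tstat), n - 2))
}

#' Robust linear regression with Tukey bisquare weights
#'
#' Iteratively reweighted least squares: residuals are scaled by the
#' median absolute residual divided by 0.6745, weighted by the Tukey
#' bisquare function with tuning constant `c` (default 4.685, 95%
#' Gaussian efficiency), and refitted until the weights change by less
#' than `tol`. Used to regress fitted model parameters on clinical
#' outcome without undue influence from outlying subjects.
#'
#' @param X Design matrix (an intercept column is added unless
#'   `intercept = FALSE`).
#' @param y Response vector.
#' @param c Bisquare tuning constant.
#' @param tol Convergence tolerance on the maximum weight change.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @param intercept Add an intercept column?
#' @return List with `coefficients`, `weights`, `iterations`, `converged`.
#' @export
robust_regression_bisquare <- function(X, y, c = 4.685, tol = 1e-8,
                                       max_iter = 200, intercept = TRUE) {
  X <- as.matrix(X)
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  w <- rep(1, nrow(X))
  beta <- NULL
  for (it in seq_len(max_iter)) {
    fit <- stats::lm.wfit(X, y, w)
    beta <- fit$coefficients
    r <- y - X %*% beta
    s <- stats::median(abs(r)) / 0.6745
    if (s < .Machine$double.eps^0.5) {
      # (near-)exact fit: weights are all 1 and nothing can change
      return(list(coefficients = beta, weights = rep(1, nrow(X)),
                  iterations = it, converged = TRUE))
    }
    u <- r / (c * s)
    w_new <- as.vector(ifelse(abs(u) < 1, (1 - u^2)^2, 0))
    if (max(abs(w_new - w)) < tol)
      return(list(coefficients = beta, weights = w_new, iterations = it,
                  converged = TRUE))
    w <- w_new
  }
  stop(sprintf("IRLS did not converge within %d iterations (last max weight change > %g)",
               max_iter, tol))
}

#' Choice accuracy: fraction of high-probability-stimulus choices
#'
#' @param data A trial sequence with `choice` and `hps_identity` columns.
#' @return Fraction of valid (non-missed) trials on which the HPS was
#'   chosen.
#' @export
choice_accuracy <- function(data) {
  valid <- data$choice != "missed"
  if (!any(valid)) stop("no valid trials")
  mean(data$choice[valid] == data$hps_identity[valid])
}
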