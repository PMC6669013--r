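# Classifier evaluation statistics. The classifiers themselves are
# pluggable components (linear SVC via e1071, L2 logistic regression via
# glmnet); the orchestration and the statistics around them are what this
# module provides.

#' Classifier specifications for the evaluation harness
#'
#' Returns a fit/score contract usable with [loso_nested_cv()]:
#' `"svc_linear"` is an L2-regularized linear support vector classifier
#' (cost hyperparameter `C`), `"logreg"` an L2-regularized logistic
#' regression (penalty hyperparameter `lambda`). Both accept per-class
#' misclassification weights inverse to training-class frequency.
#'
#' @param name `"svc_linear"` or `"logreg"`.
#' @param grid Hyperparameter grid searched in the inner loop.
#' @return A list with `name`, `grid`, `fit(x, y, hyper, positive)` and
#'   `score(model, x)` (higher = more positive-class) and
#'   `prob(model, x)` where available.
#' @export
make_classifier <- function(name = c("svc_linear", "logreg"), grid = NULL) {
  name <- match.arg(name)
  if (name == "svc_linear") {
    if (is.null(grid)) grid <- c(0.01, 0.1, 1, 10)
    list(
      name = name, grid = grid,
      fit = function(x, y, hyper, positive) {
        cw <- 1 / table(y)
        cw <- cw / sum(cw) * 2
        m <- e1071::svm(x = x, y = y, kernel = "linear", cost = hyper,
                        class.weights = cw, scale = FALSE)
        attr(m, "positive") <- positive
        m
      },
      score = function(model, x) {
        pr <- stats::predict(model, x, decision.values = TRUE)
        dv <- attr(pr, "decision.values")
        first <- strsplit(colnames(dv)[1], "/")[[1]][1]
        if (first == attr(model, "positive")) as.numeric(dv)
        else -as.numeric(dv)
      },
      prob = NULL)
  } else {
    if (is.null(grid)) grid <- c(0.01, 0.1, 1)
    list(
      name = name, grid = grid,
      fit = function(x, y, hyper, positive) {
        # glmnet codes the second factor level as 1
        y2 <- factor(y, levels = c(setdiff(levels(y), positive), positive))
        wt <- as.numeric(1 / (table(y2)[y2] / length(y2)) / 2)
        m <- glmnet::glmnet(x, y2, family = "binomial", alpha = 0,
                            lambda = hyper, weights = wt,
                            standardize = FALSE)
        attr(m, "positive") <- positive
        m
      },
      score = function(model, x)
        as.numeric(stats::predict(model, x, type = "link")),
      prob = function(model, x)
        as.numeric(stats::predict(model, x, type = "response")))
  }
}

# stratified fold assignment
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

standardizer <- function(x) {
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  list(apply = function(z) sweep(sweep(z, 2, mu), 2, sd_, `/`))
}

# univariate |t|-statistic feature screen fitted on `x`/`y`
screen_features <- function(x, y, k) {
  g1 <- y == levels(y)[1]
  t_abs <- abs(vapply(seq_len(ncol(x)), function(j) {
    a <- x[g1, j]; b <- x[!g1, j]
    s <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    if (s == 0) 0 else (mean(a) - mean(b)) / s
  }, numeric(1)))
  order(t_abs, decreasing = TRUE)[seq_len(min(k, ncol(x)))]
}

loso_engine <- function(x, y, classifier, grid, inner_folds, positive,
                        screen_k, screen_peek, seed) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("feature table contains missing values")
  y <- factor(y)
  if (nlevels(y) != 2) stop("labels must be binary")
  n <- nrow(x)
  if (n < 6) stop("need at least 6 subjects")
  if (any(table(y) < 2)) stop("each class needs at least 2 subjects")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(positive)) positive <- levels(y)[2]

  peek_idx <- NULL
  if (!is.null(screen_k) && screen_peek)
    peek_idx <- screen_features(x, y, screen_k)   # deliberate leakage

  scores <- numeric(n)
  probs <- rep(NA_real_, n)
  pred <- character(n)
  chosen_hyper <- numeric(n)
  for (i in seq_len(n)) {
    tr_x <- x[-i, , drop = FALSE]; tr_y <- droplevels(y[-i])
    if (nlevels(tr_y) != 2)
      stop("a training fold lost one class entirely")
    if (!is.null(screen_k)) {
      keep <- if (screen_peek) peek_idx else screen_features(tr_x, tr_y,
                                                             screen_k)
      tr_x <- tr_x[, keep, drop = FALSE]
      te_x <- x[i, keep, drop = FALSE]
    } else te_x <- x[i, , drop = FALSE]
    # inner loop: 5-fold stratified CV over the hyperparameter grid
    fold <- stratified_folds(tr_y, inner_folds)
    inner_ba <- vapply(grid, function(hy) {
      cm <- matrix(0, 2, 2)   # rows: positive/negative truth
      for (f in seq_len(inner_folds)) {
        itr <- fold != f
        if (nlevels(droplevels(tr_y[itr])) != 2) next
        st <- standardizer(tr_x[itr, , drop = FALSE])
        m <- classifier$fit(st$apply(tr_x[itr, , drop = FALSE]), tr_y[itr],
                            hy, positive)
        sc <- classifier$score(m, st$apply(tr_x[!itr, , drop = FALSE]))
        ph <- ifelse(sc > 0, positive, setdiff(levels(tr_y), positive))
        truth <- as.character(tr_y[!itr])
        cm[1, 1] <- cm[1, 1] + sum(ph == positive & truth == positive)
        cm[1, 2] <- cm[1, 2] + sum(ph != positive & truth == positive)
        cm[2, 1] <- cm[2, 1] + sum(ph != positive & truth != positive)
        cm[2, 2] <- cm[2, 2] + sum(ph == positive & truth != positive)
      }
      sens <- if (sum(cm[1, ]) == 0) 0 else cm[1, 1] / sum(cm[1, ])
      spec <- if (sum(cm[2, ]) == 0) 0 else cm[2, 1] / sum(cm[2, ])
      (sens + spec) / 2
    }, numeric(1))
    hy <- grid[which.max(inner_ba)]
    chosen_hyper[i] <- hy
    st <- standardizer(tr_x)
    m <- classifier$fit(st$apply(tr_x), tr_y, hy, positive)
    sc <- classifier$score(m, st$apply(te_x))
    scores[i] <- sc
    pred[i] <- if (sc > 0) positive else setdiff(levels(y), positive)
    if (!is.null(classifier$prob))
      probs[i] <- classifier$prob(m, st$apply(te_x))
  }
  truth <- as.character(y)
  tp <- sum(pred == positive & truth == positive)
  fn <- sum(pred != positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  fp <- sum(pred == positive & truth != positive)
  post <- balanced_accuracy_posterior(tp, fn, tn, fp)
  auc <- auc_trapezoid(scores, y == positive)
  structure(list(
    scores = scores, probabilities = probs, predicted = pred,
    truth = truth, positive = positive, hyper = chosen_hyper,
    confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    balanced_accuracy = (tp / (tp + fn) + tn / (tn + fp)) / 2,
    posterior = post, auc = auc,
    p_binomial = binomial_exceedance_test(tp + tn, n, 0.5),
    classifier = classifier$name, leaky = screen_peek),
    class = "classification_result")
}

#' Nested leave-one-subject-out cross-validation
#'
#' Outer loop: each subject is held out once; inner loop: 5-fold
#' stratified cross-validation over the classifier's hyperparameter grid,
#' selecting the hyperparameter with the best inner balanced accuracy.
#' Feature-wise standardization (and the optional univariate feature
#' screen) is fitted inside each training fold only, so no statistic of
#' the held-out subject ever reaches the training pipeline. Class weights
#' are set inversely proportional to training-class frequency.
#'
#' @param x Subjects x features matrix (no missing values).
#' @param y Binary labels (factor or coercible).
#' @param classifier A [make_classifier()] spec.
#' @param grid Hyperparameter grid (defaults to the classifier's).
#' @param inner_folds Inner CV folds (default 5).
#' @param positive Label treated as the positive class (default: second
#'   factor level).
#' @param screen_k Optional: keep only the `k` features with the largest
#'   absolute two-sample t statistic, computed on the training fold.
#' @param seed Seed for fold assignment.
#' @return A `classification_result`: per-fold scores and predictions,
#'   confusion counts, sensitivity/specificity/PPV/NPV, balanced accuracy
#'   with its posterior ([balanced_accuracy_posterior()]), trapezoidal AUC,
#'   and the one-sided binomial p-value of pooled accuracy against chance.
#' @export
loso_nested_cv <- function(x, y, classifier = make_classifier("svc_linear"),
                           grid = classifier$grid, inner_folds = 5,
                           positive = NULL, screen_k = NULL, seed = NULL) {
  loso_engine(x, y, classifier, grid, inner_folds, positive, screen_k,
              screen_peek = FALSE, seed = seed)
}

#' Negative control: leave-one-subject-out CV with deliberate leakage
#'
#' Identical to [loso_nested_cv()] except that the univariate feature
#' screen is fitted once on the *full* dataset, including each held-out
#' subject — a deliberate violation of the no-leakage contract. This
#' exists solely to demonstrate, e.g. on permuted labels, how badly such
#' peeking inflates apparent accuracy; never use it to report performance.
#'
#' @inheritParams loso_nested_cv
#' @return A `classification_result` with `leaky = TRUE`.
#' @export
loso_cv_peeking <- function(x, y, classifier = make_classifier("svc_linear"),
                            grid = classifier$grid, inner_folds = 5,
                            positive = NULL, screen_k = 10, seed = NULL) {
  warning("loso_cv_peeking() deliberately leaks the held-out subject into feature screening; results are biased by construction")
  loso_engine(x, y, classifier, grid, inner_folds, positive, screen_k,
              screen_peek = TRUE, seed = seed)
}

#' Posterior of the balanced accuracy
#'
#' Treats sensitivity and specificity as independent Beta posteriors under
#' flat priors — `Beta(tp + 1, fn + 1)` and `Beta(tn + 1, fp + 1)` — and
#' summarizes the posterior of their average. The posterior mean has the
#' closed form `((tp+1)/(tp+fn+2) + (tn+1)/(tn+fp+2)) / 2`; the credible
#' interval is obtained by seeded Monte Carlo.
#'
#' @param tp,fn,tn,fp Non-negative integer confusion counts.
#' @param level Credible level (default 0.95).
#' @param n_draws Monte-Carlo draws (default 1e5).
#' @param seed Seed for the draws.
#' @return List with `mean`, `lower`, `upper`, `level`.
#' @export
balanced_accuracy_posterior <- function(tp, fn, tn, fp, level = 0.95,
                                        n_draws = 1e5, seed = 1) {
  counts <- c(tp, fn, tn, fp)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  if (tp + fn == 0 || tn + fp == 0)
    stop("both classes must contain at least one subject")
  post_mean <- ((tp + 1) / (tp + fn + 2) + (tn + 1) / (tn + fp + 2)) / 2
  old <- .Random.seed_save()
  set.seed(as.integer(seed))
  draws <- (stats::rbeta(n_draws, tp + 1, fn + 1) +
              stats::rbeta(n_draws, tn + 1, fp + 1)) / 2
  .Random.seed_restore(old)
  qs <- stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2))
  list(mean = post_mean, lower = unname(qs[1]), upper = unname(qs[2]),
       level = level)
}

# save/restore the global RNG state so seeded sub-computations do not
# disturb an enclosing simulation
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Area under the ROC curve by the trapezoidal rule
#'
#' Empirical ROC over descending score thresholds (tied scores grouped, so
#' ties receive half credit) integrated with trapezoids.
#'
#' @param scores Numeric classifier scores, higher = more positive.
#' @param labels Logical (or coercible) positive-class indicator.
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # cumulative counts at each distinct threshold
  last <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, cumsum(l)[last] / n1)
  fpr <- c(0, cumsum(!l)[last] / n0)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Percentile interval over `n_boot` resamples; stratified resampling
#' draws subjects within class, preserving class sizes. A degenerate
#' resample (a class absent, possible only unstratified) is redrawn and
#' counted.
#'
#' @param scores,labels As in [auc_trapezoid()].
#' @param n_boot Number of replicates (default 2000).
#' @param stratified Resample within class (default TRUE).
#' @param level Confidence level.
#' @param seed Seed; fixed seeds reproduce the interval exactly.
#' @return List with `auc`, `lower`, `upper`, `n_boot`, `n_redrawn`.
#' @export
auc_bootstrap <- function(scores, labels, n_boot = 2000, stratified = TRUE,
                          level = 0.95, seed = NULL) {
  labels <- as.logical(labels)
  if (sum(labels) < 2 || sum(!labels) < 2)
    stop("each class needs at least 2 members")
  if (!is.null(seed)) set.seed(as.integer(seed))
  pos_idx <- which(labels); neg_idx <- which(!labels)
  aucs <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- if (stratified)
        c(sample(pos_idx, replace = TRUE), sample(neg_idx, replace = TRUE))
      else sample(seq_along(labels), replace = TRUE)
      if (any(labels[idx]) && any(!labels[idx])) break
      n_redrawn <- n_redrawn + 1L
    }
    aucs[b] <- auc_trapezoid(scores[idx], labels[idx])
  }
  qs <- stats::quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2))
  list(auc = auc_trapezoid(scores, labels), lower = unname(qs[1]),
       upper = unname(qs[2]), n_boot = n_boot, n_redrawn = n_redrawn)
}

#' Paired bootstrap comparison of two AUCs
#'
#' Two score sets over the same subjects are compared by
#' `D = (AUC1 - AUC2) / SD_boot(delta AUC)` where the bootstrap standard
#' deviation comes from paired stratified resampling (the same subjects
#' enter both AUCs in every replicate), with a two-sided normal p-value.
#'
#' @param scores_1,scores_2 Score vectors over the same subjects.
#' @param labels Positive-class indicator.
#' @param n_boot Number of paired replicates (default 2000).
#' @param seed Seed.
#' @return List with `D`, `p_value`, `auc1`, `auc2`.
#' @export
auc_compare <- function(scores_1, scores_2, labels, n_boot = 2000,
                        seed = NULL) {
  if (length(scores_1) != length(scores_2) ||
      length(scores_1) != length(labels))
    stop("score vectors and labels must align on the same subjects")
  labels <- as.logical(labels)
  auc1 <- auc_trapezoid(scores_1, labels)
  auc2 <- auc_trapezoid(scores_2, labels)
  if (identical(scores_1, scores_2))
    return(list(D = 0, p_value = 1, auc1 = auc1, auc2 = auc2))
  if (!is.null(seed)) set.seed(as.integer(seed))
  pos_idx <- which(labels); neg_idx <- which(!labels)
  dauc <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- c(sample(pos_idx, replace = TRUE), sample(neg_idx, replace = TRUE))
    dauc[b] <- auc_trapezoid(scores_1[idx], labels[idx]) -
      auc_trapezoid(scores_2[idx], labels[idx])
  }
  s <- stats::sd(dauc)
  D <- if (s == 0) 0 else (auc1 - auc2) / s
  list(D = D, p_value = if (s == 0) 1 else 2 * stats::pnorm(-abs(D)),
       auc1 = auc1, auc2 = auc2)
}

#' Elastic-net feature selection
#'
#' Regularized logistic regression with the elastic-net penalty, tuned by
#' grid search over the mixing parameter `alpha` and the penalty `lambda`
#' with stratified k-fold cross-validation; the nonzero-coefficient mask of
#' the best (alpha, lambda) pair is returned. The elastic net produces
#' sparse solutions while selecting correlated features in and out
#' together. Backed by the glmnet coordinate-descent solver.
#'
#' @param x Standardized feature matrix (standardized internally if not).
#' @param y Binary labels.
#' @param alpha_grid Elastic-net mixing values in (0, 1].
#' @param lambda_grid Optional lambda sequence (glmnet's default path if
#'   `NULL`).
#' @param inner_folds CV folds (default 5).
#' @param seed Seed for fold assignment.
#' @return List with `mask` (logical per feature), `weights` (coefficients
#'   at the selected pair), `alpha`, `lambda`.
#' @export
feature_select_elastic_net <- function(x, y, alpha_grid = c(0.1, 0.5, 0.9),
                                       lambda_grid = NULL, inner_folds = 5,
                                       seed = NULL) {
  x <- as.matrix(x)
  y <- factor(y)
  stopifnot(nlevels(y) == 2)
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- scale(x)
  foldid <- stratified_folds(y, inner_folds)
  best <- NULL
  for (a in alpha_grid) {
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = a,
                            foldid = foldid, lambda = lambda_grid,
                            standardize = FALSE)
    cvm_min <- min(cv$cvm)
    if (is.null(best) || cvm_min < best$cvm) {
      best <- list(cvm = cvm_min, alpha = a, lambda = cv$lambda.min,
                   fit = cv$glmnet.fit)
    }
  }
  co <- as.numeric(stats::coef(best$fit, s = best$lambda))[-1]  # drop intercept
  mask <- co != 0
  names(mask) <- colnames(x)
  if (!any(mask))
    warning("elastic net selected no features at any grid point; returning an empty mask")
  list(mask = mask, weights = stats::setNames(co, colnames(x)),
       alpha = best$alpha, lambda = best$lambda)
}

#' Correlate probabilistic classifier outputs with a continuous outcome
#'
#' Robust 20% bend correlation between per-subject predicted response
#' probabilities and the continuous clinical outcome (e.g. percent symptom
#' change); delegates to [percentage_bend_correlation()].
#'
#' @param probabilities Predicted probabilities per subject.
#' @param continuous_outcome Aligned continuous outcome.
#' @param bend Bend constant (default 0.2).
#' @return As [percentage_bend_correlation()].
#' @export
probabilistic_output_correlation <- function(probabilities,
                                             continuous_outcome,
                                             bend = 0.2) {
  percentage_bend_correlation(probabilities, continuous_outcome, bend = bend)
}
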