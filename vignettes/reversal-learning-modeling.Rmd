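---
title: "Modeling choice behavior in a self-paced reversal-learning task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling choice behavior in a self-paced reversal-learning task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(revlearn)
```

This vignette is the package's account of its science: the task model,
the five candidate learning models and their estimation, the statistics
built around them, and — importantly — the places where the design was
genuinely open and the package had to commit to a choice.

## The task

The paradigm is a two-armed bandit with asymmetric probabilistic
contingencies: the high-probability stimulus (HPS) yields +10 with
probability 0.70 and −10 otherwise, while the low-probability stimulus
(LPS) mirrors this, so the two expected values have equal magnitude and
opposite sign. A session has 180 trials. Reversals are *self-paced*:
whenever the subject has chosen the HPS five times over the last six
completed trials, a run of buffer trials of zero-truncated-Poisson length
is played under the old contingencies, after which the HPS identity
flips. The buffer exists to keep subjects from discovering the
deterministic trigger rule.

Three details are under-determined by that description, and
`task_config()` commits to the following:

* **Trigger timing.** The 5-of-6 criterion is evaluated as soon as at
  least 5 completed (non-missed) trials have accrued since the last
  flip, counting HPS choices over the last `min(6, n)` completed trials.
  Because a single trial can raise the count by at most one, the count at
  the moment of every trigger is then exactly 5 — which is also the
  property the test suite asserts. (Requiring a full window of 6 before
  the first check would let a perfect performer reach a count of 6 at the
  first eligible trial.) Counting restarts after each flip, and is
  suspended during the buffer, so a segment can trigger at most once.
* **Buffer rate.** The Poisson rate of the buffer length is not a
  published constant; it is exposed as `buffer_lambda` with default 2.0
  (mean length ≈ 2.3 trials), short enough that reversals stay frequent
  and long enough to conceal the rule.
* **Missed trials.** A policy may emit `"missed"`; such trials yield no
  outcome, are excluded from the criterion window, but still count toward
  the buffer countdown (the display runs regardless of responding).

Stimulus screen position is not modeled; it has no consequence for any
model considered here.

## The five learning models

All models share the sigmoid choice rule
$p(\text{choose } a) = \sigma\!\big(\beta (v_a - v_b) + \text{stick}\cdot c\big)$,
with $c = +1$ after a previous $a$ choice, $-1$ after $b$, and $0$ before
the first completed trial. Only the dynamic-learning-rate model has a
stickiness variant; the others fix stick at 0.

**DYNA / DYNA_STICK (dynamic learning rate).** Operates on the raw ±10
outcomes with values initialized at 0. With prediction error
$\delta_t = r_t - v_{c_t}$, the unsigned prediction error is smoothed,

$$\mathrm{pemag}_t = \rho\,|\delta_t| + (1-\rho)\,\mathrm{pemag}_{t-1},$$

its normalized slope is
$m_t = (\mathrm{pemag}_t - \mathrm{pemag}_{t-1}) /
\big((\mathrm{pemag}_t + \mathrm{pemag}_{t-1})/2\big)$ (defined as 0 when
both terms vanish, and bounded in $[-2, 2]$), and the learning rate moves
toward 1 when surprise is rising and toward 0 when it is falling:

$$\alpha_t = \alpha_{t-1} + f(m_t)\,(1-\alpha_{t-1}) \;\; (m_t > 0),
\qquad
\alpha_t = \alpha_{t-1} + f(m_t)\,\alpha_{t-1} \;\; (m_t < 0).$$

Only the chosen value is updated, $v \mathrel{+}= \alpha_t \delta_t$; the
update term $\alpha_t\delta_t$ is the *weighted reward prediction error*
used later as the fMRI regressor of interest.

The modulation function was a genuinely open design point: a
"double sigmoid mapping the slope to $[0,1]$" cannot serve the
$\alpha$-update above, which needs $f < 0$ for negative slopes. The
package therefore uses the sign-preserving form
$f(m;\gamma) = 2/(1+e^{-m/\gamma}) - 1 \in (-1, 1)$, which is
algebraically $\tanh(m/2\gamma)$ and has $|f|$ strictly decreasing in
$\gamma$ — matching the interpretation that large $\gamma$ yields a
surprise-invariant, stable learning rate. A steeper `tanh(m/γ)`
alternative is selectable via the model's `f_form` setting. Initial
conditions: $v = 0$ (stated), $\mathrm{pemag}_0 = 0$ and
$\alpha_1 = 0.5$ (not stated; config-exposed). Within a trial the order
is $\delta \to \mathrm{pemag} \to m \to \alpha \to v$, i.e. $\alpha_t$
uses the current $|\delta_t|$.

**Pearce-Hall.** Values initialize at 0.5, which only makes sense on the
unit outcome scale, so outcomes are recoded to $\{1, 0\}$
(positive/negative). The associability is the *previous* trial's unsigned
prediction error, $\alpha_t = |\delta_{t-1}|$, with a free initial
$\alpha^1$ — the reading consistent with $\alpha^1$ carrying its own
prior; the simultaneous-$|\delta_t|$ reading would make $\alpha^1$
meaningless. The update is $v \mathrel{+}= S\,\alpha_t\,\delta_t$ with
salience constant $S$.

**HGF.** The three-level hierarchical Gaussian filter receives the binary
contingency input $u$, where $u = 1$ codes outcomes consistent with the
current mapping (+ after HPS, − after LPS). Level 2 tracks the
contingency tendency in logit space with process variance
$\exp(\kappa x_3 + \omega)$ (phasic and tonic components); level 3 tracks
log volatility with constant variance $\vartheta$. The standard
variational one-step updates are used (precision-weighted prediction
errors); the predicted contingency probability $\sigma(\mu_2)$ is mapped
back to stimulus space ($v_{\mathrm{HPS}} = \sigma(\mu_2)$,
$v_{\mathrm{LPS}} = 1 - \sigma(\mu_2)$) for the choice rule. $\omega$ is
fixed at −4; $\kappa$ is bounded in $(0, 3)$ via a scaled logit. The
stated prior mean for $\vartheta$ (0.025) exceeds its own stated upper
bound (0.005); the package resolves this in favor of the bound,
parameterizing $\vartheta = 0.005\,\sigma(x)$ with transformed prior mean
0. A level-3 precision that turns non-positive mid-sequence is reported
as a numerical-stability error naming the trial (in fitting, such
parameter regions simply receive zero likelihood).

**K1 (gain adaptation).** The published description defers the exact
recursions to a reference implementation, so the package fixes the
*family* and documents its constants: a single contingency-space value
$v$ (init 0.5) is updated with gain $k = e^{b}$, where the log-gain is
meta-learned, $b \mathrel{+}= \mu\,\delta\,h$, clipped above at 0 so the
gain never exceeds 1, and the eligibility trace decays as
$h \leftarrow h\,\max(0, 1-k) + k\,\delta$ (trace init $h^1$, log-gain
init $\log 0.1$, both config-exposed). A trial with $\delta = 0$ — a
measure-zero event under these contingencies — leaves the state entirely
untouched, which reconciles the decaying-trace recursion with the
invariance property the estimator contract demands.

### Transforms and priors

Free parameters are estimated in an unconstrained space: log for $\beta$,
$\gamma$, $S$, $\mu$, $h^1$; logit for $\rho$, $\alpha^1$; scaled logit
for the bounded $\kappa$ and $\vartheta$; identity for stick. Prior pairs
are read as (mean, variance), with native means mapped through the
transform and variances applied in the transformed space — e.g.
DYNA_STICK's natives (1, 0.5, 0.5, 0) for $(\beta,\gamma,\rho,\text{stick})$
become transformed means $(0, \log 0.5, 0, 0)$ with variance 100 each.

## Hierarchical estimation

`fit_map()` maximizes
$\log p(C\mid\theta) + \log \mathcal N(\theta;\xi)$ by BFGS with numerical
gradients. Restart policy: the first two starts are deterministic (warm
start if available, then the prior mean); further restarts jitter around
the prior mean with SD `min(prior SD, 2)` — a full prior-SD jitter under
variance-100 priors would launch searches from useless likelihood
plateaus (e.g. $\beta = e^{\pm 20}$). The Laplace covariance is the
inverse of a central-difference Hessian (step $10^{-4}$). Because the
penalized Hessian provably dominates the prior precision, its eigenvalues
are floored at $\min_j(1/v_j)$ before inversion: a direction the data do
not constrain then inherits the prior variance rather than an arbitrary
ceiling, which keeps both the M-step and the marginal-likelihood
trajectory stable.

`run_em()` alternates these MAP/Laplace fits (E-step) with moment
updates of the population mean and variance (M-step),
$v_j = \tfrac1N\sum_i (\mu_{ij}^2 + \Sigma_{i,jj}) - m_j^2$, until the
largest hyperparameter change drops below `tol` (default $10^{-3}$) or
`max_iter`. Two guards keep the recorded Laplace objective well behaved:
E-steps warm-start from the previous optimum, and if a fresh fit lands in
a basin whose Laplace marginal under the *current* prior is worse than
the previous optimum's, the previous optimum is kept. Negative M-step
variances (possible with near-degenerate cohorts) are floored at
$10^{-6}$ with a warning.

`integrated_bic()` draws 1000 parameter vectors from the Gaussian
population prior, averages each subject's sequence likelihood over them
in log space (log-sum-exp; overflowed draws contribute zero likelihood),
and penalizes with $q\log N$ where $N$ is the total valid choice count
and $q = 2d$ counts the fitted hyperparameters — a mean and a variance
per free parameter. Penalizing per subject would multiply-count the
hyperparameters, which are shared; this group-level penalty is the one
deliberate point where the scoring rule had to be pinned down beyond the
published description.

## fMRI design matrices

`build_design()` assembles the first-level regressors from event timing
and a model trajectory: decision-phase chosen/unchosen expected values
(parametric), an unmodulated visual regressor and an RT-modulated motor
regressor; outcome-phase weighted RPE $\alpha\delta$ (parametric), RPE
magnitude $|\delta|$, positive/negative outcome indicators, and — when
missed trials exist — a lost-trials nuisance column. Choices the package
makes explicit because the source leaves them implicit: parametric
modulators are mean-centered over valid trials before convolution
(separating modulation from the main effect); boxcar durations default to
the stimulus presentation times (1.25 s decision, 0.65 s outcome);
convolution uses a 16× oversampled grid before down-sampling to the 2 s
repetition time; the double-gamma kernel peaks near 5 s with a 1/6
undershoot and unit peak normalization. Degenerate regressors (an
all-zero modulator, or an RT column without variance, which would
duplicate the visual boxcar) are dropped or flagged rather than silently
included, and `collinearity_check()` reports the condition number of the
column-standardized matrix plus per-column variance-inflation factors.

## Classifier evaluation

`loso_nested_cv()` holds out one subject per outer fold; within each
training fold, feature standardization (and the optional univariate
screen) is refit, an inner 5-fold stratified CV picks the hyperparameter
with the best inner balanced accuracy, and class weights are set inverse
to training-class frequency. Nothing computed from a held-out subject
ever reaches its training pipeline; `loso_cv_peeking()` exists purely as
a negative control that breaks this on purpose, so the test suite can
demonstrate how much a leaky screen inflates permuted-label accuracy.
Balanced accuracy is summarized by its posterior under flat Beta priors
on sensitivity and specificity — the mean has the closed form
$\tfrac12\big(\tfrac{tp+1}{tp+fn+2} + \tfrac{tn+1}{tn+fp+2}\big)$, and
the credible interval is computed by seeded Monte Carlo ($10^5$ draws),
since the convolution of two Beta densities has no elementary closed
form. AUC uses the trapezoidal rule (tied scores grouped, half credit),
its CI 2000 stratified bootstrap replicates, and paired classifier
comparisons the statistic
$D = (\mathrm{AUC}_1 - \mathrm{AUC}_2)/\mathrm{SD}_{boot}(\Delta)$ with a
two-sided normal p-value. Elastic-net feature selection is a grid search
over the mixing and penalty parameters with stratified 5-fold CV, backed
by the glmnet coordinate-descent solver; the classifiers themselves
(linear SVC, L2 logistic regression) are deliberately pluggable
components — the statistics around them are the contribution here.

## The synthetic cohort generator

Because the original patient data are unavailable, every estimator is
exercised on synthetic cohorts with known ground truth. The defaults
emulate the study's structure: 19 responders and 18 nonresponders, 180
trials each, generated from DYNA_STICK with per-group Gaussians in
transformed space. Where the generator needed values the source does not
provide, they were chosen once on realism grounds and not revisited:

* transformed means $(\log 0.2, \log 0.5, 0, 0.1)$ for
  $(\beta, \gamma, \rho, \text{stick})$ — on the raw ±10 value scale an
  inverse temperature near 0.2 produces visibly stochastic choice and
  above-chance accuracy, as human subjects show; larger $\beta$ makes
  agents near-deterministic reversal-chasers;
* population SDs $(0.5, 0.5, 0.8, 0.3)$;
* the group effect: responders' logit-$\rho$ mean sits 0.8 population SDs
  below the nonresponders' (responders smooth more over past unsigned
  prediction errors) and their stickiness one SD higher — the *signs*
  follow the published finding, the magnitudes are harness choices for
  recovery studies, not claims about the real effect;
* a continuous outcome resembling percent symptom improvement is a noisy
  decreasing function of logit-$\rho$, clipped to $[-100, 100]$.

What the generator does *not* emulate: reaction-time distributions,
session-level nonstationarity (fatigue, attention), dropout mechanisms,
any fMRI signal, or the true effect sizes of the clinical study. Passing
recovery tests therefore shows that the estimators work when their
assumptions hold — it does not validate the substantive clinical claims,
which would require the original data.

## Problem sizes and numerical choices in the test suite

The suites run at sizes chosen to make the statistics meaningful:
parameter recovery uses 40 subjects × 180 trials; model recovery 20
replicate cohorts of 10 subjects fitting three models each (EM capped at
10 iterations, hyperparameter tolerance $10^{-2}$, 1000 BIC draws); the
EM monotonicity audit a 20-subject cohort; the null-classification audit
10 permutation seeds at n = 40 with 200 features; simulator contingencies
50,000 choices. Optimizer and EM tolerances are as described above;
quintile calibration requires non-degenerate bins and at least 5 valid
trials; the percentage-bend correlation refuses inputs whose winsorized
scale collapses to zero.

## Known limitations

* $\gamma$ (and to a lesser degree $\rho$) is only weakly identified at
  180 trials: recovery correlations for $\rho$ fluctuate roughly between
  0.4 and 0.7 across cohorts, consistent with the likelihood-profile
  information in single sequences. Group-level contrasts on $\rho$ remain
  detectable on average.
* The EM objective is an approximate (Laplace) marginal likelihood;
  monotonicity is engineered via warm starts and basin guards, not
  guaranteed by theory.
* The HGF is included as a candidate model, but in a two-armed task whose
  contingencies are perfectly anti-correlated, volatility tracking has
  little leverage; its role here is as a comparison model, and its
  $\vartheta$ prior follows the bound-consistent reading noted above.
* Classifiers operate on tabular feature matrices; no imaging formats are
  ingested.
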