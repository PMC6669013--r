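// Trial-loop sequence filters for the five learning models.
//
// Each filter runs the model's recursions over one subject's sequence and
// returns the trial-wise latents plus the negative log likelihood of the
// observed choices (cross-entropy over non-missed trials). Latent state is
// carried through missed trials without update. These are the hot path of
// MAP fitting, EM and integrated-BIC sampling; the single-trial R step
// functions in R/models.R define the same recursions and are cross-checked
// against these filters in the test suite.

#include <Rcpp.h>
using namespace Rcpp;

// log(sigmoid(x)), stable for large |x|
static inline double log_sigmoid(double x) {
  if (x < 0.0) return x - log1p(std::exp(x));
  return -log1p(std::exp(-x));
}

static inline double sigmoid(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// choice coding: 1 = a, 2 = b, 0 = missed; prev in {0, +1, -1}
static inline double decision_arg(double va, double vb, double beta,
                                  double stick, int prev) {
  return beta * (va - vb) + stick * prev;
}

// [[Rcpp::export(name = ".filter_dyna_cpp")]]
List filter_dyna_cpp(IntegerVector choice, NumericVector outcome,
                     double beta, double gamma, double rho, double stick,
                     double alpha1, double v0, double pemag0,
                     bool use_tanh) {
  const int n = choice.size();
  NumericMatrix lat(n, 9);
  CharacterVector nm = CharacterVector::create(
    "p_a", "p_obs", "v_a", "v_b", "delta", "pemag", "m", "alpha", "wrpe");
  colnames(lat) = nm;
  std::fill(lat.begin(), lat.end(), NA_REAL);

  double v[2] = {v0, v0};
  double alpha = alpha1, pemag = pemag0;
  int prev = 0;
  double nll = 0.0;
  int n_valid = 0;

  for (int t = 0; t < n; ++t) {
    const int c = choice[t];
    const double x = decision_arg(v[0], v[1], beta, stick, prev);
    lat(t, 0) = sigmoid(x);
    lat(t, 2) = v[0];
    lat(t, 3) = v[1];
    if (c == 0) continue;                      // missed: no update, no nll
    const int ci = c - 1;
    const double lp = (c == 1) ? log_sigmoid(x) : log_sigmoid(-x);
    lat(t, 1) = std::exp(lp);
    nll -= lp;
    if (!std::isfinite(nll)) { nll = R_PosInf; break; }
    ++n_valid;

    const double delta = outcome[t] - v[ci];
    const double pemag_new = rho * std::fabs(delta) + (1.0 - rho) * pemag;
    const double s = pemag_new + pemag;
    const double m = (s == 0.0) ? 0.0 : (pemag_new - pemag) / (s / 2.0);
    const double f = use_tanh ? std::tanh(m / gamma)
                              : 2.0 * sigmoid(m / gamma) - 1.0;
    if (m > 0.0)      alpha = alpha + f * (1.0 - alpha);
    else if (m < 0.0) alpha = alpha + f * alpha;
    v[ci] += alpha * delta;
    pemag = pemag_new;
    prev = (c == 1) ? 1 : -1;

    lat(t, 4) = delta;
    lat(t, 5) = pemag;
    lat(t, 6) = m;
    lat(t, 7) = alpha;
    lat(t, 8) = alpha * delta;
  }
  return List::create(_["latents"] = lat, _["nll"] = nll,
                      _["n_valid"] = n_valid, _["ok"] = true);
}

// [[Rcpp::export(name = ".filter_ph_cpp")]]
List filter_ph_cpp(IntegerVector choice, NumericVector reward,
                   double S, double alpha1, double beta, double v0) {
  const int n = choice.size();
  NumericMatrix lat(n, 7);
  colnames(lat) = CharacterVector::create(
    "p_a", "p_obs", "v_a", "v_b", "delta", "alpha", "wrpe");
  std::fill(lat.begin(), lat.end(), NA_REAL);

  double v[2] = {v0, v0};
  double alpha = alpha1;
  double nll = 0.0;
  int n_valid = 0;

  for (int t = 0; t < n; ++t) {
    const int c = choice[t];
    const double x = decision_arg(v[0], v[1], beta, 0.0, 0);
    lat(t, 0) = sigmoid(x);
    lat(t, 2) = v[0];
    lat(t, 3) = v[1];
    if (c == 0) continue;
    const int ci = c - 1;
    const double lp = (c == 1) ? log_sigmoid(x) : log_sigmoid(-x);
    lat(t, 1) = std::exp(lp);
    nll -= lp;
    if (!std::isfinite(nll)) { nll = R_PosInf; break; }
    ++n_valid;

    const double delta = reward[t] - v[ci];
    v[ci] += S * alpha * delta;
    lat(t, 4) = delta;
    lat(t, 5) = alpha;
    lat(t, 6) = S * alpha * delta;
    alpha = std::fabs(delta);
  }
  return List::create(_["latents"] = lat, _["nll"] = nll,
                      _["n_valid"] = n_valid, _["ok"] = true);
}

// [[Rcpp::export(name = ".filter_hgf_cpp")]]
List filter_hgf_cpp(IntegerVector choice, NumericVector u,
                    IntegerVector hps,  // 1 if stimulus a is HPS, 2 if b
                    double kappa, double omega, double theta, double beta,
                    double mu2_0, double sa2_0, double mu3_0, double sa3_0) {
  const int n = choice.size();
  NumericMatrix lat(n, 11);
  colnames(lat) = CharacterVector::create(
    "p_a", "p_obs", "v_a", "v_b", "muhat1", "mu2", "sa2", "mu3", "sa3",
    "delta1", "delta2");
  std::fill(lat.begin(), lat.end(), NA_REAL);

  double mu2 = mu2_0, sa2 = sa2_0, mu3 = mu3_0, sa3 = sa3_0;
  double nll = 0.0;
  int n_valid = 0;
  bool ok = true;
  int bad_trial = -1;

  for (int t = 0; t < n; ++t) {
    const double muhat1 = sigmoid(mu2);
    // contingency value mapped back to stimulus space via HPS identity
    const double v_hps = muhat1, v_lps = 1.0 - muhat1;
    const double va = (hps[t] == 1) ? v_hps : v_lps;
    const double vb = (hps[t] == 1) ? v_lps : v_hps;
    const double x = decision_arg(va, vb, beta, 0.0, 0);
    lat(t, 0) = sigmoid(x);
    lat(t, 2) = va;
    lat(t, 3) = vb;
    lat(t, 4) = muhat1;

    const int c = choice[t];
    if (c == 0) { lat(t, 5) = mu2; lat(t, 7) = mu3; continue; }
    const double lp = (c == 1) ? log_sigmoid(x) : log_sigmoid(-x);
    lat(t, 1) = std::exp(lp);
    nll -= lp;
    if (!std::isfinite(nll)) { nll = R_PosInf; break; }
    ++n_valid;

    const double delta1 = u[t] - muhat1;
    const double v2 = std::exp(kappa * mu3 + omega);
    const double pihat2 = 1.0 / (sa2 + v2);
    const double pi2 = pihat2 + muhat1 * (1.0 - muhat1);
    const double mu2_new = mu2 + delta1 / pi2;
    const double pihat3 = 1.0 / (sa3 + theta);
    const double w2 = v2 * pihat2;
    const double delta2 =
      ((1.0 / pi2) + (mu2_new - mu2) * (mu2_new - mu2)) * pihat2 - 1.0;
    const double pi3 =
      pihat3 + (kappa * kappa / 2.0) * w2 * (w2 + (2.0 * w2 - 1.0) * delta2);
    if (!std::isfinite(pi3) || pi3 <= 0.0) {
      ok = false; bad_trial = t + 1; nll = R_PosInf; break;
    }
    mu3 = mu3 + (kappa / (2.0 * pi3)) * w2 * delta2;
    sa3 = 1.0 / pi3;
    mu2 = mu2_new;
    sa2 = 1.0 / pi2;

    lat(t, 5) = mu2;
    lat(t, 6) = sa2;
    lat(t, 7) = mu3;
    lat(t, 8) = sa3;
    lat(t, 9) = delta1;
    lat(t, 10) = delta2;
  }
  return List::create(_["latents"] = lat, _["nll"] = nll,
                      _["n_valid"] = n_valid, _["ok"] = ok,
                      _["bad_trial"] = bad_trial);
}

// [[Rcpp::export(name = ".filter_k1_cpp")]]
List filter_k1_cpp(IntegerVector choice, NumericVector u,
                   IntegerVector hps, double mu, double h1, double beta,
                   double v0, double b0) {
  const int n = choice.size();
  NumericMatrix lat(n, 7);
  colnames(lat) = CharacterVector::create(
    "p_a", "p_obs", "v_a", "v_b", "delta", "gain", "wrpe");
  std::fill(lat.begin(), lat.end(), NA_REAL);

  double v = v0, h = h1, b = b0;
  double nll = 0.0;
  int n_valid = 0;

  for (int t = 0; t < n; ++t) {
    const double va = (hps[t] == 1) ? v : 1.0 - v;
    const double vb = (hps[t] == 1) ? 1.0 - v : v;
    const double x = decision_arg(va, vb, beta, 0.0, 0);
    lat(t, 0) = sigmoid(x);
    lat(t, 2) = va;
    lat(t, 3) = vb;
    const int c = choice[t];
    if (c == 0) continue;
    const double lp = (c == 1) ? log_sigmoid(x) : log_sigmoid(-x);
    lat(t, 1) = std::exp(lp);
    nll -= lp;
    if (!std::isfinite(nll)) { nll = R_PosInf; break; }
    ++n_valid;

    const double delta = u[t] - v;
    if (delta != 0.0) {
      b = std::min(b + mu * delta * h, 0.0);   // gain capped at 1
      const double k = std::exp(b);
      v += k * delta;
      h = h * std::max(0.0, 1.0 - k) + k * delta;
      lat(t, 5) = k;
      lat(t, 6) = k * delta;
    } else {
      lat(t, 5) = std::exp(b);
      lat(t, 6) = 0.0;
    }
    lat(t, 4) = delta;
  }
  return List::create(_["latents"] = lat, _["nll"] = nll,
                      _["n_valid"] = n_valid, _["ok"] = true);
}
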