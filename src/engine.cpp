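#include <Rcpp.h>
using namespace Rcpp;

// Trial-stepping value-learning engine shared by all candidate models.
//
// Returns, for every trial, the probability assigned to choosing the
// ground-truth-higher item under the hierarchy in force on that trial.
// Value updates are keyed to the feedback outcome (the winner is the
// higher-ranked item), never to the simulated choice, and occur only on
// feedback trials.  Mirrors the pure-R reference engine simulate_agent();
// the two are held equal by tests.
//
// Model codes / parameter layout (see model_spec() on the R side):
//   1 qsymm:   alpha, eta, tau
//   2 qasymm:  alpha_plus, alpha_minus, eta, tau
//   3 qasymm2: alpha_plus_pre, alpha_minus_pre, alpha_plus_post,
//              alpha_minus_post, eta, tau
//   4 qadapt:  alpha0, omega, eta, tau
// [[Rcpp::export]]
NumericVector ti_probs_cpp(int model, NumericVector par,
                           IntegerVector left, IntegerVector right,
                           IntegerVector correct, LogicalVector feedback,
                           LogicalVector post, int n_items) {
  const int nt = left.size();
  NumericVector q(n_items);  // item values start at 0
  NumericVector out(nt);
  double eta, tau;
  switch (model) {
  case 1: eta = par[1]; tau = par[2]; break;
  case 2: eta = par[2]; tau = par[3]; break;
  case 3: eta = par[4]; tau = par[5]; break;
  case 4: eta = par[2]; tau = par[3]; break;
  default: stop("unknown model code");
  }
  if (tau <= 0) stop("tau must be positive");
  for (int t = 0; t < nt; ++t) {
    int hi = correct[t] - 1;
    int lo = (left[t] - 1 == hi) ? right[t] - 1 : left[t] - 1;
    double p = 1.0 / (1.0 + std::exp(-(q[hi] - q[lo]) / tau));
    out[t] = p;
    if (feedback[t]) {
      double ap, am;
      if (model == 1) {
        ap = par[0]; am = par[0];
      } else if (model == 2) {
        ap = par[0]; am = par[1];
      } else if (model == 3) {
        ap = post[t] ? par[2] : par[0];
        am = post[t] ? par[3] : par[1];
      } else {
        // preference-adaptive split of the base rate across winner/loser,
        // modulated by the pre-update probability assigned to the winner
        double a0 = par[0], om = par[1];
        double lam = -4.0 * om * p * p + 4.0 * om * p + 1.0 - om;
        double shift = (a0 < 0) ? a0 : 0.0;
        ap = a0 * (1.0 + lam) / 2.0 - shift;
        am = a0 * (1.0 - lam) / 2.0 - shift;
      }
      // relative-difference term from pre-update values, shared by both
      // updates; rectifiers clip negative winner / positive loser updates
      double d = eta * (q[hi] - q[lo]);
      double up_w = ap * (1.0 - d - q[hi]);
      double up_l = am * (-1.0 + d - q[lo]);
      if (up_w < 0) up_w = 0;
      if (up_l > 0) up_l = 0;
      q[hi] += up_w;
      q[lo] += up_l;
    }
  }
  return out;
}
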