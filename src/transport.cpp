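#include <Rcpp.h>
using namespace Rcpp;

// Outward sweep of the equilibrium carbohydrate profile along one radial
// file. Cells are indexed 1..n from the cell adjacent to the phloem inward;
// given a trial concentration in the innermost living cell (theta_n), each
// cell's Michaelis-Menten wall demand is evaluated and the inter-cell flux
// balance theta[j-1] = theta[j] + eta * sum_{k >= j} dM_k is applied until
// the phloem boundary is reconstructed. The root of
// theta0(theta_n) - theta_p = 0 is located by Brent's method in R.

// [[Rcpp::export]]
double transport_theta0(double theta_n, NumericVector dM_max, double Km,
                        double eta) {
  const int n = dM_max.size();
  double th = theta_n;
  double S = 0.0;  // running sum of demands inward of (and at) cell j
  for (int j = n - 1; j >= 0; --j) {
    const double dM = dM_max[j] * th / (th + Km);
    S += dM;
    th += eta * S;  // concentration in cell j-1 (phloem when j == 0)
  }
  return th;
}

// Collapse a sign-changing bracket around the root of
// theta0(theta_n) - theta_p to adjacent doubles by bisection. The residual
// amplifies small perturbations of theta_n (each cell contributes a factor
// > 1), so root polishing to the last ulp is needed to meet tight residual
// tolerances at the phloem boundary.
// [[Rcpp::export]]
double transport_polish(double lo, double hi, NumericVector dM_max, double Km,
                        double eta, double theta_p) {
  double f_lo = transport_theta0(lo, dM_max, Km, eta) - theta_p;
  double f_hi = transport_theta0(hi, dM_max, Km, eta) - theta_p;
  if (f_lo > 0 || f_hi < 0) return NA_REAL;  // caller widens the bracket
  for (int it = 0; it < 200; ++it) {
    const double mid = 0.5 * (lo + hi);
    if (mid <= lo || mid >= hi) break;  // bracket is two adjacent doubles
    const double f = transport_theta0(mid, dM_max, Km, eta) - theta_p;
    if (f < 0) { lo = mid; f_lo = f; } else { hi = mid; f_hi = f; }
  }
  return (-f_lo < f_hi) ? lo : hi;
}

// [[Rcpp::export]]
List transport_profile(double theta_n, NumericVector dM_max, double Km,
                       double eta) {
  const int n = dM_max.size();
  NumericVector theta(n), dM(n);
  double th = theta_n;
  double S = 0.0;
  for (int j = n - 1; j >= 0; --j) {
    theta[j] = th;
    dM[j] = dM_max[j] * th / (th + Km);
    S += dM[j];
    th += eta * S;
  }
  return List::create(_["theta0"] = th, _["theta"] = theta, _["dM"] = dM);
}
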