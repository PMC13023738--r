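#include <Rcpp.h>
using namespace Rcpp;

// Coordinate descent for the per-view subproblem
//   min_w  S * w'Gw - 2 c'w + sum_l ridge_l w_l^2 + l1 * sum_l |w_l|
// with G = X'X cached by the caller.  Maintains r = G w so each coordinate
// update costs O(p) only when the coordinate actually moves.
// [[Rcpp::export(name = ".cd_quad_lasso")]]
NumericVector cd_quad_lasso(const NumericMatrix& G, const NumericVector& c,
                            double S, const NumericVector& ridge, double l1,
                            NumericVector w0, int max_sweeps, double tol) {
  const int p = G.nrow();
  NumericVector w = clone(w0);
  std::vector<double> r(p, 0.0);
  for (int l = 0; l < p; ++l) {
    if (w[l] != 0.0) {
      const double wl = w[l];
      for (int i = 0; i < p; ++i) r[i] += G(i, l) * wl;
    }
  }
  const double half_l1 = 0.5 * l1;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double max_delta = 0.0;
    for (int l = 0; l < p; ++l) {
      const double gll = G(l, l);
      const double denom = S * gll + ridge[l];
      if (denom <= 0.0) continue;
      const double rho = c[l] - S * (r[l] - gll * w[l]);
      double wnew = 0.0;
      if (rho > half_l1) wnew = (rho - half_l1) / denom;
      else if (rho < -half_l1) wnew = (rho + half_l1) / denom;
      const double delta = wnew - w[l];
      if (delta != 0.0) {
        for (int i = 0; i < p; ++i) r[i] += G(i, l) * delta;
        w[l] = wnew;
        const double ad = std::fabs(delta);
        if (ad > max_delta) max_delta = ad;
      }
    }
    if (max_delta < tol) break;
  }
  return w;
}
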