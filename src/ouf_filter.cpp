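#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact Kalman innovation decomposition for the OUF position process
// (state = position + velocity), run jointly on the data series and the
// constant-1 mean regressor, in sigma2 = 1 units.  Transition and process
// noise use the closed-form exact discretisation; the 2x2 algebra is
// unrolled for speed since this sits inside the likelihood optimiser.
// [[Rcpp::export]]
List ouf_innovations_cpp(NumericVector z, NumericVector tt,
                         double tau_p, double tau_v) {
  int n = z.size();
  double f1 = 1.0 / tau_p, f2 = 1.0 / tau_v;
  double vinf = f1 * f2; // stationary velocity variance
  NumericVector ed(n), ec(n), S(n);
  // state means for (data, regressor): m[comp][series]
  double m00 = 0, m01 = 0, m10 = 0, m11 = 0;
  // covariance (symmetric 2x2), start at stationary
  double P00 = 1.0, P01 = 0.0, P11 = vinf;
  double prev_dt = -1.0;
  double F00 = 0, F01 = 0, F10 = 0, F11 = 0; // transition
  double Q00 = 0, Q01 = 0, Q11 = 0;          // process noise
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      double dt = tt[i] - tt[i - 1];
      if (dt != prev_dt) {
        double e1 = std::exp(-f1 * dt), e2 = std::exp(-f2 * dt);
        double denom = f2 - f1;
        // Phi = (e1 (A + f2 I) - e2 (A + f1 I)) / (f2 - f1),
        // A = [[0, 1], [-f1 f2, -(f1 + f2)]]
        F00 = (e1 * f2 - e2 * f1) / denom;
        F01 = (e1 - e2) / denom;
        F10 = -f1 * f2 * F01;
        F11 = (e1 * (f2 - (f1 + f2)) - e2 * (f1 - (f1 + f2))) / denom;
        // Q = Pinf - Phi Pinf Phi^T, Pinf = diag(1, vinf)
        Q00 = 1.0 - (F00 * F00 + vinf * F01 * F01);
        Q01 = -(F00 * F10 + vinf * F01 * F11);
        Q11 = vinf - (F10 * F10 + vinf * F11 * F11);
        prev_dt = dt;
      }
      double a00 = F00 * m00 + F01 * m10, a01 = F00 * m01 + F01 * m11;
      double a10 = F10 * m00 + F11 * m10, a11 = F10 * m01 + F11 * m11;
      m00 = a00; m01 = a01; m10 = a10; m11 = a11;
      double T00 = F00 * P00 + F01 * P01, T01 = F00 * P01 + F01 * P11;
      double T10 = F10 * P00 + F11 * P01, T11 = F10 * P01 + F11 * P11;
      P00 = T00 * F00 + T01 * F01 + Q00;
      P01 = T00 * F10 + T01 * F11 + Q01;
      P11 = T10 * F10 + T11 * F11 + Q11;
    }
    double Si = P00;
    ed[i] = z[i] - m00;
    ec[i] = 1.0 - m01;
    S[i] = Si;
    double K0 = 1.0, K1 = P01 / Si; // gain (position component = 1)
    m00 += K0 * ed[i]; m01 += K0 * ec[i];
    m10 += K1 * ed[i]; m11 += K1 * ec[i];
    P11 -= K1 * K1 * Si;
    P01 -= K1 * Si * K0;
    P00 -= K0 * K0 * Si; // = 0: position fully observed
    if (P00 < 0) P00 = 0;
    if (P11 < 0) P11 = 0;
  }
  return List::create(_["ed"] = ed, _["ec"] = ec, _["S"] = S);
}
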