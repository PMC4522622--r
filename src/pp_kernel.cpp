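#include <Rcpp.h>
using namespace Rcpp;

// Counting-process accumulation for the inverse-expected-survival-weighted
// net-survival estimator.
//
// Patients arrive sorted by follow-up time (ascending); `brk` is the
// strictly increasing vector of evaluation breakpoints, containing every
// follow-up time, every whole-year boundary (where the per-patient annual
// hazard changes) and any extra subdivision points. Because every
// follow-up time is a breakpoint, the risk set is constant on each open
// interval and per-patient expected cumulative hazards can be updated
// multiplicatively: E_i <- E_i * exp(lam_ik * dt), where E_i = 1/S_Pi is
// the patient's weight.
//
// Per breakpoint b_j this returns:
//   s1     sum of weights over the risk set at b_j
//   dnw    sum of weights over deaths at b_j
//   dvar   sum of squared weights over deaths at b_j
//   dlam2  increment of the population (expected) hazard integral over
//          (b_{j-1}, b_j]: exact numerator sum_i [E_i(b)-E_i(a)] divided
//          by the weighted risk-set size at the interval midpoint
//   nrisk, nevent  unweighted counts
// [[Rcpp::export(name = ".pp_accumulate")]]
List pp_accumulate(NumericVector t, IntegerVector status,
                   NumericMatrix lam, NumericVector brk) {
  const int n = t.size();
  const int K = lam.ncol();
  const int m = brk.size();
  std::vector<double> E(n, 1.0);
  NumericVector s1(m), dnw(m), dvar(m), dlam2(m);
  IntegerVector nrisk(m), nevent(m);
  int ptr = 0;
  double a = 0.0;
  for (int j = 0; j < m; ++j) {
    double b = brk[j];
    while (ptr < n && t[ptr] <= a) ++ptr;
    int ki = (int)std::floor(a + 1e-12);
    if (ki > K - 1) ki = K - 1;
    double dt = b - a;
    double num2 = 0.0, den2 = 0.0, S1 = 0.0, DNW = 0.0, DVAR = 0.0;
    int nev = 0;
    for (int i = ptr; i < n; ++i) {
      double g = std::exp(lam(i, ki) * dt);
      double Enew = E[i] * g;
      num2 += Enew - E[i];
      den2 += E[i] * std::sqrt(g);
      E[i] = Enew;
      S1 += Enew;
      if (t[i] == b && status[i] == 1) {
        DNW += Enew;
        DVAR += Enew * Enew;
        ++nev;
      }
    }
    s1[j] = S1;
    dnw[j] = DNW;
    dvar[j] = DVAR;
    dlam2[j] = (den2 > 0.0) ? num2 / den2 : 0.0;
    nrisk[j] = n - ptr;
    nevent[j] = nev;
    a = b;
  }
  return List::create(_["s1"] = s1, _["dnw"] = dnw, _["dvar"] = dvar,
                      _["dlam2"] = dlam2, _["nrisk"] = nrisk,
                      _["nevent"] = nevent);
}
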