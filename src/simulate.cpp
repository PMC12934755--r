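#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama walkers with reflecting boundaries at [smin, 1].
// drift_type: 1 = -D/(2 s), 2 = zero, 3 = constant k.
// [[Rcpp::export]]
NumericVector sim_em_cpp(NumericVector init, int n_steps, double dt,
                         double D, double smin, int drift_type, double k) {
  int n = init.size();
  NumericVector s = clone(init);
  double sig = std::sqrt(2.0 * D * dt);
  RNGScope scope;
  for (int step = 0; step < n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      double a;
      switch (drift_type) {
        case 1: a = -D / (2.0 * s[i]); break;
        case 2: a = 0.0; break;
        default: a = k;
      }
      double x = s[i] + a * dt + sig * norm_rand();
      // reflect until inside; step-size guard upstream keeps this short
      while (x < smin || x > 1.0) {
        if (x < smin) x = 2.0 * smin - x;
        if (x > 1.0) x = 2.0 - x;
      }
      s[i] = x;
    }
  }
  return s;
}
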