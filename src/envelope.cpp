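#include <Rcpp.h>
using namespace Rcpp;

// One-pole attack/release envelope follower on instantaneous band power.
// Attack smoothing applies while power is rising above the envelope,
// release while falling; alphas are exp(-1 / (rate * tau)).
// [[Rcpp::export]]
NumericVector env_follow(NumericVector x2, double alpha_attack,
                         double alpha_release, double init) {
  int n = x2.size();
  NumericVector env(n);
  double e = init;
  for (int i = 0; i < n; ++i) {
    double a = (x2[i] > e) ? alpha_attack : alpha_release;
    e = a * e + (1.0 - a) * x2[i];
    env[i] = e;
  }
  return env;
}
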