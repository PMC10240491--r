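#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Phase-accumulation kernel for the ballistic scatterer-sum speckle model.
//
// Each column of v0/phi0 is one independent speckle realization (one pixel x
// one coherence mode): ns point scatterers with initial phases phi0 and
// velocities v0 (units such that qdt * v is the per-frame phase increment at
// unit speed factor). Between frames t-1 and t the phase of scatterer j
// advances by qdt * speed[t] * v_j; velocity redraw events (evFrame, evReal,
// evScat, evVel; sorted by realization then frame, all 0-based) replace v_j
// at the start of the step. Returns |sum_j exp(i phi_j)|^2 / ns, so the
// ensemble-mean intensity is 1.
// [[Rcpp::export]]
NumericMatrix speckleFieldIntensity(NumericMatrix v0, NumericMatrix phi0,
                                    double qdt, NumericVector speed,
                                    IntegerVector evFrame,
                                    IntegerVector evReal,
                                    IntegerVector evScat,
                                    NumericVector evVel) {
  const int ns = v0.nrow();
  const int nreal = v0.ncol();
  const int nf = speed.size();
  const int ne = evFrame.size();
  NumericMatrix out(nf, nreal);
  std::vector<double> v(ns), ph(ns);
  int e = 0;
  for (int r = 0; r < nreal; ++r) {
    for (int j = 0; j < ns; ++j) {
      v[j] = v0(j, r);
      ph[j] = phi0(j, r);
    }
    double re = 0.0, im = 0.0;
    for (int j = 0; j < ns; ++j) {
      re += std::cos(ph[j]);
      im += std::sin(ph[j]);
    }
    out(0, r) = (re * re + im * im) / ns;
    for (int t = 1; t < nf; ++t) {
      while (e < ne && evReal[e] == r && evFrame[e] == t) {
        v[evScat[e]] = evVel[e];
        ++e;
      }
      const double step = qdt * speed[t];
      re = 0.0;
      im = 0.0;
      for (int j = 0; j < ns; ++j) {
        ph[j] += step * v[j];
        re += std::cos(ph[j]);
        im += std::sin(ph[j]);
      }
      out(t, r) = (re * re + im * im) / ns;
    }
    // skip any leftover events of this realization (frame 0 events allowed)
    while (e < ne && evReal[e] == r) ++e;
  }
  return out;
}
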