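#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step leaky integrate-and-fire soma.
//
// i_exc  : excitatory drive per step, in mV (already multiplied by input
//          resistance), added to the membrane equation directly.
// g_inh  : dimensionless inhibitory conductance (relative to leak); pulls
//          the membrane toward e_inh.
// noise  : per-step current noise in mV drive units (pre-scaled so the
//          stationary voltage s.d. is independent of dt).
//
// During the absolute refractory period the membrane is clamped at v_reset.
// [[Rcpp::export]]
List soma_integrate(NumericVector i_exc, NumericVector g_inh, double dt,
                    double tau_m, double v_rest, double v_thresh,
                    double v_reset, double e_inh, double refrac_ms,
                    NumericVector noise, bool keep_trace) {
  const int n = i_exc.size();
  NumericVector trace;
  if (keep_trace) trace = NumericVector(n);
  std::vector<double> spikes;
  double v = v_rest;
  double refrac_until = -1.0;
  const bool has_noise = noise.size() == n;

  for (int i = 0; i < n; ++i) {
    double t = i * dt;
    if (t >= refrac_until) {
      double dv = (v_rest - v) + i_exc[i] - g_inh[i] * (v - e_inh);
      if (has_noise) dv += noise[i];
      v += dt / tau_m * dv;
      if (v >= v_thresh) {
        spikes.push_back(t);
        v = v_reset;
        refrac_until = t + refrac_ms;
      }
    } else {
      v = v_reset;
    }
    if (keep_trace) trace[i] = v;
  }

  return List::create(_["spikes"] = wrap(spikes), _["trace"] = trace);
}
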