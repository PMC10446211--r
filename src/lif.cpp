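#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integration of a leaky integrate-and-fire membrane,
//   tau dV/dt = -V + I_offset + I(t) + sqrt(2D) xi(t),
// with threshold/reset.  Times are in ms (dt, tau); returned spike times in ms.
// `drive` holds I(t) per integration step; a length-1 drive is treated as a
// constant current.  Noise uses R's RNG (norm_rand), so set.seed() on the R
// side makes runs reproducible.  theta = Inf disables the threshold (useful
// for free-membrane statistics).
// [[Rcpp::export(name = ".lif_run")]]
List lif_run(NumericVector drive, int n_steps, double dt, double tau,
             double i_offset, double noise_2d, double theta, double v_reset,
             double v0, bool record_v, double ref_ms = 0.0) {
  const double lam = dt / tau;
  const double noise_amp = noise_2d > 0 ? std::sqrt(noise_2d * dt) / tau : 0.0;
  const bool const_drive = drive.size() == 1;
  const bool has_thresh = R_finite(theta);
  const int ref_steps = ref_ms > 0 ? (int)std::lround(ref_ms / dt) : 0;
  double v = v0;
  int refrac = 0;
  std::vector<double> spikes;
  NumericVector vtrace(record_v ? n_steps : 0);

  for (int k = 0; k < n_steps; ++k) {
    if (refrac > 0) {
      --refrac;
      if (record_v) vtrace[k] = v;
      continue;
    }
    const double cur = const_drive ? drive[0] : drive[k];
    v += lam * (-v + i_offset + cur);
    if (noise_amp > 0.0) v += noise_amp * norm_rand();
    if (has_thresh && v >= theta) {
      spikes.push_back((k + 1) * dt);
      v = v_reset;
      refrac = ref_steps;
    }
    if (record_v) vtrace[k] = v;
  }

  return List::create(_["spikes_ms"] = wrap(spikes), _["voltage"] = vtrace);
}

// Accumulate spike counts into uniform bins with a rigid time shift applied
// to all spikes (conduction delay / alignment).  Spikes shifted outside
// [0, n_bins/rate) are dropped; the number dropped is returned.
// [[Rcpp::export(name = ".bin_spikes")]]
List bin_spikes(NumericVector times, double shift, double rate, int n_bins,
                NumericVector counts) {
  int dropped = 0;
  for (int i = 0; i < times.size(); ++i) {
    const double t = times[i] + shift;
    const int idx = (int)std::floor(t * rate);
    if (idx < 0 || idx >= n_bins) {
      ++dropped;
      continue;
    }
    counts[idx] += 1.0;
  }
  return List::create(_["counts"] = counts, _["dropped"] = dropped);
}
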