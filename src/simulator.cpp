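#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Izhikevich network simulation (forward Euler).
//
// Excitatory (regular-spiking pyramidal):
//   100 dv/dt = 0.7 (v+60)(v+40) - u + I,   du/dt = 0.03(-2(v+60)) - u
//   v >= 35  ->  v = -50, u = u + 100
// Inhibitory (fast-spiking interneuron):
//   20 dv/dt = (v+55)(v+40) - u + I,        du/dt = 0.2 (U(v) - u)
//   U(v) = 0.025 (v - v_b)^3 for v >= v_b else 0;  v >= 25 -> v = -45
//
// Synaptic events (weight w, onset delay t_X after the presynaptic spike)
// are delivered either as instantaneous voltage increments (input_mode = 0,
// the default: w is the maximum voltage increase of the postsynaptic cell)
// or summed into I as gated exponentials w * exp(-(t - t_X - t_k)/tau)
// (input_mode = 1). An external Poisson drive per neuron injects events of
// Gaussian amplitude through the same route.
//
// All randomness goes through R's RNG so set.seed() governs the run.

// [[Rcpp::export]]
List simulate_izhikevich_cpp(NumericMatrix weights, IntegerVector type,
                             double duration, double dt,
                             double rate_exc, double rate_inh,
                             double amp_mean, double amp_sd,
                             int input_mode, double v_b, double tau,
                             double t_delay_exc, double t_delay_inh) {
  const int n = weights.nrow();
  const long nsteps = (long) std::llround(duration / dt);
  const int del_e = (int) std::llround(t_delay_exc / dt);
  const int del_i = (int) std::llround(t_delay_inh / dt);
  const int ring = std::max(del_e, del_i) + 1;
  const double decay = std::exp(-dt / tau);

  // adjacency lists: postsynaptic targets of each neuron
  std::vector< std::vector<int> > post(n);
  std::vector< std::vector<double> > w(n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (weights(i, j) != 0.0) { post[j].push_back(i); w[j].push_back(weights(i, j)); }

  std::vector<double> v(n), u(n, 0.0), g(n, 0.0);
  for (int i = 0; i < n; ++i) v[i] = (type[i] == 0) ? -60.0 : -55.0;

  // ring buffer of pending synaptic increments
  std::vector<double> pend((size_t) ring * n, 0.0);
  std::vector< std::vector<double> > spikes(n);

  const double p_exc = rate_exc * dt / 1000.0;  // rates in Hz, dt in ms
  const double p_inh = rate_inh * dt / 1000.0;

  bool unstable = false;
  for (long step = 0; step < nsteps && !unstable; ++step) {
    const double t = step * dt;
    const int slot = (int)(step % ring);
    for (int i = 0; i < n; ++i) {
      double arriving = pend[(size_t) slot * n + i];
      pend[(size_t) slot * n + i] = 0.0;

      // external Poisson drive
      const double p_drive = (type[i] == 0) ? p_exc : p_inh;
      if (p_drive > 0.0 && unif_rand() < p_drive)
        arriving += amp_mean + amp_sd * norm_rand();

      double I = 0.0;
      if (input_mode == 1) {          // decay waveform summed into I
        g[i] = g[i] * decay + arriving;
        I = g[i];
      } else {                        // voltage-increment delivery
        v[i] += arriving;
      }

      double vv = v[i], uu = u[i];
      if (type[i] == 0) {
        v[i] += dt * (0.7 * (vv + 60.0) * (vv + 40.0) - uu + I) / 100.0;
        u[i] += dt * (0.03 * (-2.0 * (vv + 60.0)) - uu);
        if (v[i] >= 35.0) {
          v[i] = -50.0; u[i] += 100.0;
          spikes[i].push_back(t);
          const int dslot = (int)((step + del_e) % ring);
          for (size_t s = 0; s < post[i].size(); ++s)
            pend[(size_t) dslot * n + post[i][s]] += w[i][s];
        }
      } else {
        const double U = (vv >= v_b) ? 0.025 * std::pow(vv - v_b, 3.0) : 0.0;
        v[i] += dt * ((vv + 55.0) * (vv + 40.0) - uu + I) / 20.0;
        u[i] += dt * 0.2 * (U - uu);
        if (v[i] >= 25.0) {
          v[i] = -45.0;
          spikes[i].push_back(t);
          const int dslot = (int)((step + del_i) % ring);
          for (size_t s = 0; s < post[i].size(); ++s)
            pend[(size_t) dslot * n + post[i][s]] += w[i][s];
        }
      }
      if (!std::isfinite(v[i]) || std::fabs(v[i]) > 1e3) unstable = true;
    }
  }

  List times(n);
  for (int i = 0; i < n; ++i) times[i] = wrap(spikes[i]);
  return List::create(_["spike_times"] = times,
                      _["unstable"] = unstable);
}
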