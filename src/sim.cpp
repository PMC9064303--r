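// Network of Izhikevich neurons with all-to-all excitatory synapses
// developing under additive exponential-window STDP. Membrane equations are
// integrated in millisecond units with the classic two-half-step update for
// v. A presynaptic spike increments the target's synaptic current by the
// synaptic weight; the current decays exponentially with time constant
// tau_syn, so recruitment during population events spreads over a few
// milliseconds instead of being instantaneous. tau_syn = 0 degenerates to
// instantaneous voltage kicks of size w.
#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_simulate_izhikevich(int n, double duration_s, double dt_s,
                             NumericVector drive, double noise_sd,
                             NumericMatrix w0, double g_max, double a_plus,
                             double a_minus, double tau_plus_s,
                             double tau_minus_s, double tau_syn_s,
                             double izh_a, double izh_b, double izh_c,
                             double izh_d, NumericVector snapshot_times_s,
                             int seed) {
  if (w0.nrow() != n || w0.ncol() != n) stop("w0 must be n x n");
  if (drive.size() != n) stop("drive must have length n");
  double dt = dt_s * 1000.0;  // ms
  double duration = duration_s * 1000.0;
  long n_steps = (long)std::ceil(duration / dt);
  double dec_plus = std::exp(-dt / (tau_plus_s * 1000.0));
  double dec_minus = std::exp(-dt / (tau_minus_s * 1000.0));
  bool filtered = tau_syn_s > 0;
  double dec_syn = filtered ? std::exp(-dt / (tau_syn_s * 1000.0)) : 0.0;
  // scale so that one presynaptic spike injects a total depolarisation of
  // w mV regardless of tau_syn
  double syn_gain = filtered ? 1.0 / (tau_syn_s * 1000.0) : 0.0;

  std::vector<double> v(n, izh_c), u(n), w((size_t)n * n), gsyn(n, 0.0);
  std::vector<double> xtr(n, 0.0), ytr(n, 0.0);  // pre / post traces
  for (int i = 0; i < n; ++i) u[i] = izh_b * v[i];
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) w[(size_t)j * n + i] = w0(j, i);  // j -> i

  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> norm(0.0, 1.0);

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  std::vector<int> spiked;
  spiked.reserve(n);

  int n_snap = snapshot_times_s.size();
  List snapshots(n_snap);
  int next_snap = 0;

  for (long step = 0; step < n_steps; ++step) {
    double t_ms = step * dt;
    // membrane update (two half-steps for v, as in the reference scheme)
    for (int i = 0; i < n; ++i) {
      double I = drive[i] + (noise_sd > 0 ? noise_sd * norm(rng) : 0.0) +
                 (filtered ? syn_gain * gsyn[i] : 0.0);
      double vi = v[i], ui = u[i];
      vi += 0.5 * dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I);
      vi += 0.5 * dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I);
      ui += dt * izh_a * (izh_b * vi - ui);
      if (!std::isfinite(vi))
        stop("membrane potential diverged; reduce the integration step dt");
      v[i] = vi;
      u[i] = ui;
    }
    spiked.clear();
    for (int i = 0; i < n; ++i) {
      if (v[i] >= 30.0) {
        spiked.push_back(i);
        spike_t.push_back((t_ms + dt) / 1000.0);
        spike_id.push_back(i + 1);
        v[i] = izh_c;
        u[i] += izh_d;
      }
    }
    if (!spiked.empty()) {
      for (int s : spiked) {
        // as postsynaptic neuron: potentiate incoming weights (pre-before-post)
        for (int j = 0; j < n; ++j) {
          if (j == s) continue;
          double& wij = w[(size_t)j * n + s];
          wij += a_plus * xtr[j];
          if (wij > g_max) wij = g_max;
        }
        // as presynaptic neuron: depress outgoing weights (post-before-pre)
        // and deliver the synaptic input to all targets
        for (int i = 0; i < n; ++i) {
          if (i == s) continue;
          double& wsi = w[(size_t)s * n + i];
          wsi -= a_minus * ytr[i];
          if (wsi < 0.0) wsi = 0.0;
          if (filtered) {
            gsyn[i] += wsi;
          } else {
            v[i] += wsi;
          }
        }
      }
      for (int s : spiked) {
        xtr[s] += 1.0;
        ytr[s] += 1.0;
      }
    }
    for (int i = 0; i < n; ++i) {
      xtr[i] *= dec_plus;
      ytr[i] *= dec_minus;
      if (filtered) gsyn[i] *= dec_syn;
    }
    while (next_snap < n_snap &&
           snapshot_times_s[next_snap] * 1000.0 <= t_ms + dt) {
      NumericMatrix snap(n, n);
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i) snap(j, i) = w[(size_t)j * n + i];
      snapshots[next_snap] = snap;
      ++next_snap;
    }
  }

  return List::create(Named("times") = wrap(spike_t),
                      Named("ids") = wrap(spike_id),
                      Named("snapshots") = snapshots);
}
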