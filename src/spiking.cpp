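#include <Rcpp.h>
using namespace Rcpp;

// Two mutually inhibiting pools of leaky integrate-and-fire neurons with a
// calcium-like spike-triggered adaptation current (the local fatigue of the
// rate model) and short-term depression of the cross-pool inhibitory
// synapses (the nonlocal fatigue). Time in ms; voltage scaled so rest = 0,
// threshold = 1. Euler-Maruyama with per-step white current noise.
// [[Rcpp::export(name = ".spiking_sim_cpp")]]
List spiking_sim_cpp(int M, double tau_m, double t_ref, double tau_w,
                     double b_w, double tau_syn, double J_inh, double U_dep,
                     double tau_dep, double sigma, double dt, double t_end,
                     double I_on, double I_bg, NumericMatrix windows,
                     IntegerMatrix win_pools) {
  const int N = 2 * M;
  std::vector<double> V(N), w(N, 0.0), x(N, 1.0), last_spike(N, -1e9);
  double G[2] = {0.0, 0.0}; // inhibitory drive generated by each pool
  RNGScope scope;
  for (int k = 0; k < N; ++k) V[k] = 0.5 * unif_rand();

  std::vector<double> sp_t, sp_id;
  sp_t.reserve(1 << 16);
  sp_id.reserve(1 << 16);

  const int n_steps = (int)std::ceil(t_end / dt);
  const double dec_syn = std::exp(-dt / tau_syn);
  const double sq_dt = std::sqrt(dt);
  int hint = 0;
  const int nw = windows.nrow();

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    while (hint < nw && t >= windows(hint, 1)) ++hint;
    bool in_pulse = hint < nw && t >= windows(hint, 0) && t < windows(hint, 1);
    double drive[2] = {I_bg, I_bg};
    if (in_pulse) {
      if (win_pools(hint, 0)) drive[0] += I_on;
      if (win_pools(hint, 1)) drive[1] += I_on;
    }
    double g_new[2] = {0.0, 0.0};
    for (int k = 0; k < N; ++k) {
      int p = k < M ? 0 : 1;
      w[k] -= dt * w[k] / tau_w;
      x[k] += dt * (1.0 - x[k]) / tau_dep;
      if (t - last_spike[k] < t_ref) continue;
      double I = drive[p] - J_inh * G[1 - p] - w[k];
      V[k] += dt * (-V[k] + I) / tau_m + sigma * sq_dt * norm_rand();
      if (V[k] >= 1.0) {
        V[k] = 0.0;
        last_spike[k] = t;
        w[k] += b_w;
        g_new[p] += x[k] / M;
        x[k] *= (1.0 - U_dep);
        sp_t.push_back(t);
        sp_id.push_back(k + 1);
      }
      if (!std::isfinite(V[k]))
        stop("spiking simulation diverged at t = %f ms", t);
    }
    G[0] = G[0] * dec_syn + g_new[0];
    G[1] = G[1] * dec_syn + g_new[1];
  }
  return List::create(_["time_ms"] = wrap(sp_t), _["neuron"] = wrap(sp_id));
}
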