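#include <Rcpp.h>
using namespace Rcpp;

// Gain: hard variant is sqrt of the positive part; smoothed variant replaces
// the infinite slope at threshold by a finite one (scale eps) while staying
// zero below threshold, non-decreasing and concave on x > 0, and converging
// pointwise to the hard variant as eps -> 0.
static inline double gain(double x, int variant, double eps) {
  if (x <= 0.0) return 0.0;
  if (variant == 0) return std::sqrt(x);
  return std::sqrt(x + eps) - std::sqrt(eps);
}

struct RateSys {
  int N;
  const double *beta;    // N x N, column-major, signed (beta[i + N*j] = j -> i)
  double gamma, phi, tau_a, tau_s;
  int gain_variant;
  double gain_eps;
};

// y layout: u[0..N-1], a[N..2N-1], s[2N..2N+N*N-1] (column-major s_ij, j presyn)
static void deriv(const RateSys &sys, const double *y, const double *drive,
                  double *dy) {
  const int N = sys.N;
  const double *u = y, *a = y + N, *s = y + 2 * N;
  double *du = dy, *da = dy + N, *ds = dy + 2 * N;
  for (int i = 0; i < N; ++i) {
    double arg = drive[i] - sys.gamma * a[i];
    for (int j = 0; j < N; ++j)
      arg += s[i + N * j] * sys.beta[i + N * j] * u[j];
    du[i] = -u[i] + gain(arg, sys.gain_variant, sys.gain_eps); // tau_u = 1
    da[i] = (-a[i] + u[i]) / sys.tau_a;
  }
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i)
      ds[i + N * j] = (1.0 - s[i + N * j] - sys.phi * s[i + N * j] * u[j]) /
                      sys.tau_s;
}

// Deterministic part of the drive at time t: background + any pulse window
// containing t. Windows are sorted by start and non-overlapping; *hint is a
// cursor so repeated calls with increasing t are O(1) amortized.
static void drive_at(double t, int N, const NumericVector &bg,
                     const NumericMatrix &win, const NumericMatrix &amp,
                     int *hint, double *out) {
  for (int i = 0; i < N; ++i) out[i] = bg[i];
  int nw = win.nrow();
  while (*hint < nw && t >= win(*hint, 1)) ++(*hint);
  if (*hint < nw && t >= win(*hint, 0) && t < win(*hint, 1))
    for (int i = 0; i < N; ++i) out[i] += amp(*hint, i);
}

// [[Rcpp::export(name = ".rate_sim_cpp")]]
List rate_sim_cpp(NumericVector u0, NumericVector a0, NumericMatrix s0,
                  NumericMatrix beta, double gamma, double phi, double tau_a,
                  double tau_s, int gain_variant, double gain_eps, double t0,
                  double dt, int n_steps, NumericVector bg, double sigma,
                  NumericMatrix windows, NumericMatrix win_amp,
                  int record_every, NumericVector probe_steps) {
  const int N = u0.size();
  const int dim = 2 * N + N * N;
  RateSys sys{N,    REAL(beta), gamma,        phi,
              tau_a, tau_s,      gain_variant, gain_eps};

  std::vector<double> y(dim), k1(dim), k2(dim), k3(dim), k4(dim), yt(dim);
  std::vector<double> drv(N), noise(N, 0.0), drv_stage(N);
  for (int i = 0; i < N; ++i) { y[i] = u0[i]; y[N + i] = a0[i]; }
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) y[2 * N + i + N * j] = s0(i, j);

  int n_rec = n_steps / record_every + 1 +
              ((n_steps % record_every) ? 1 : 0);
  NumericVector rt(n_rec);
  NumericMatrix rU(n_rec, N), rA(n_rec, N), rS(n_rec, N * N), rD(n_rec, N);

  int n_probe = probe_steps.size();
  NumericMatrix pU(n_probe, N), pA(n_probe, N), pS(n_probe, N * N);
  int probe_i = 0;

  RNGScope scope; // gaussian background uses R's RNG stream

  int hint = 0, rec = 0;
  double t = t0;
  // per-step drive: deterministic part re-evaluated at each RK4 stage time,
  // gaussian background drawn once per step and held constant within it
  for (int step = 0;; ++step) {
    if (step % record_every == 0 || step == n_steps) {
      int h2 = hint;
      drive_at(t, N, bg, windows, win_amp, &h2, drv.data());
      rt[rec] = t;
      for (int i = 0; i < N; ++i) {
        rU(rec, i) = y[i];
        rA(rec, i) = y[N + i];
        rD(rec, i) = drv[i] + (sigma > 0.0 ? noise[i] : 0.0);
      }
      for (int k = 0; k < N * N; ++k) rS(rec, k) = y[2 * N + k];
      ++rec;
    }
    while (probe_i < n_probe && probe_steps[probe_i] == step) {
      for (int i = 0; i < N; ++i) {
        pU(probe_i, i) = y[i];
        pA(probe_i, i) = y[N + i];
      }
      for (int k = 0; k < N * N; ++k) pS(probe_i, k) = y[2 * N + k];
      ++probe_i;
    }
    if (step == n_steps) break;

    if (sigma > 0.0)
      for (int i = 0; i < N; ++i) noise[i] = sigma * norm_rand();

    // RK4 stages
    int h = hint;
    drive_at(t, N, bg, windows, win_amp, &h, drv_stage.data());
    if (sigma > 0.0) for (int i = 0; i < N; ++i) drv_stage[i] += noise[i];
    deriv(sys, y.data(), drv_stage.data(), k1.data());

    for (int k = 0; k < dim; ++k) yt[k] = y[k] + 0.5 * dt * k1[k];
    h = hint;
    drive_at(t + 0.5 * dt, N, bg, windows, win_amp, &h, drv_stage.data());
    if (sigma > 0.0) for (int i = 0; i < N; ++i) drv_stage[i] += noise[i];
    deriv(sys, yt.data(), drv_stage.data(), k2.data());

    for (int k = 0; k < dim; ++k) yt[k] = y[k] + 0.5 * dt * k2[k];
    deriv(sys, yt.data(), drv_stage.data(), k3.data());

    for (int k = 0; k < dim; ++k) yt[k] = y[k] + dt * k3[k];
    h = hint;
    drive_at(t + dt, N, bg, windows, win_amp, &h, drv_stage.data());
    if (sigma > 0.0) for (int i = 0; i < N; ++i) drv_stage[i] += noise[i];
    deriv(sys, yt.data(), drv_stage.data(), k4.data());

    for (int k = 0; k < dim; ++k)
      y[k] += dt / 6.0 * (k1[k] + 2.0 * k2[k] + 2.0 * k3[k] + k4[k]);
    // clip tiny negative overshoot from the kinked gain (preserves u,a >= 0)
    for (int i = 0; i < 2 * N; ++i)
      if (y[i] < 0.0 && y[i] > -1e-12) y[i] = 0.0;
    t = t0 + (step + 1) * dt;
    drive_at(t, N, bg, windows, win_amp, &hint, drv.data());

    if (step % 200 == 0) {
      bool bad = false;
      for (int k = 0; k < dim; ++k)
        if (!std::isfinite(y[k])) bad = true;
      if (bad) stop("integration diverged: non-finite state at t = %f", t);
    }
  }
  for (int k = 0; k < dim; ++k)
    if (!std::isfinite(y[k]))
      stop("integration diverged: non-finite state at t = %f", t);

  return List::create(
      _["times"] = rt, _["u"] = rU, _["a"] = rA, _["s"] = rS,
      _["drive"] = rD, _["probe_u"] = pU, _["probe_a"] = pA,
      _["probe_s"] = pS);
}
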