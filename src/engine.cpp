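// Compiled network integrators.
//
// Both steppers advance all neurons of one (or, via a block-structured
// coupling matrix, two) population(s) with
//   I_syn_j = (G s)_j * (v_rev - v_j)
// where G is the pre-scaled coupling matrix (spatial kernel times
// g_bar_s / (c_n * N), zero diagonal, feedforward blocks allowed) and s the
// synaptic gates.  Background noise is an exactly updated
// Ornstein-Uhlenbeck process per neuron (stationary initial draw), using
// R's RNG so runs are reproducible from set.seed().  Stimulation enters as
// stim_gain_j * W(t) * X(t) with W the charge-balanced biphasic pulse
// train and X the on/off window indicator.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double pulse_w(double t, double period, double tpos,
                             double tneg, double apos, double aneg) {
  double tt = t - period * std::floor(t / period);
  if (tt < tpos) return apos;
  if (tt < tpos + tneg) return aneg;
  return 0.0;
}

static inline double stim_at(double t, const double *wave, double won,
                             double woff) {
  if (t < won || t >= woff) return 0.0;
  return pulse_w(t, wave[0], wave[1], wave[2], wave[3], wave[4]);
}

// Morris-Lecar lattice with delayed slow feedback current, fixed-step RK4.
// wave = {period, t_pos, t_neg, amp_pos, amp_neg} in integrator time units.
// tau is the feedback delay in time units; the v history is kept in a ring
// buffer at step resolution and sampled with linear interpolation at the
// RK4 stage times.  History before t = 0 is the constant initial state.
// [[Rcpp::export]]
List cpp_simulate_ml(NumericMatrix G, NumericVector stim_gain,
                     NumericVector v0, NumericVector w0, NumericVector i0,
                     NumericVector s0, NumericVector eps, List prm, List gate,
                     double v_rev, NumericVector wave, double win_on,
                     double win_off, double D_noise, double tau_noise,
                     double dt, int n_steps, int stride, double tau) {
  const int N = v0.size();
  if (G.nrow() != N || G.ncol() != N || stim_gain.size() != N)
    stop("coupling matrix / stimulation gain dimension mismatch");

  const double g_ca = prm["g_ca"], g_k = prm["g_k"], g_l = prm["g_l"];
  const double v_ca = prm["v_ca"], v_k = prm["v_k"], v_l = prm["v_l"];
  const double p1 = prm["v1"], p2 = prm["v2"], p3 = prm["v3"], p4 = prm["v4"];
  const double C = prm["C"], phi = prm["phi"];
  const double v_star = prm["v_star"], alpha = prm["alpha"];
  const double a_s = gate["alpha_s"], b_s = gate["beta_s"];
  const double th_s = gate["theta_s"], sg_s = gate["sigma_s"];

  const int tau_steps = (tau > 0.0) ? (int)std::ceil(tau / dt) : 0;
  const int hb = tau_steps + 3;  // ring buffer length (steps of v history)

  const int n_rec = (n_steps - 1) / stride + 1;
  NumericMatrix V(N, n_rec), S(N, n_rec), Iion(N, n_rec);
  NumericVector times(n_rec);

  std::vector<double> v(N), w(N), isl(N), s(N), noi(N, 0.0);
  for (int j = 0; j < N; ++j) {
    v[j] = v0[j]; w[j] = w0[j]; isl[j] = i0[j]; s[j] = s0[j];
  }

  // OU update coefficients (exact exponential scheme)
  const double edt = std::exp(-dt / tau_noise);
  const double sig_eq = D_noise * std::sqrt(tau_noise / 2.0);
  const double sig_up = sig_eq * std::sqrt(1.0 - edt * edt);
  if (D_noise > 0.0)
    for (int j = 0; j < N; ++j) noi[j] = sig_eq * norm_rand();

  std::vector<double> hist((size_t)hb * N);
  for (int h = 0; h < hb; ++h)
    for (int j = 0; j < N; ++j) hist[(size_t)h * N + j] = v0[j];

  std::vector<double> av(N), aw(N), ai(N), as_(N);   // stage state
  std::vector<double> kv(4 * N), kw(4 * N), ki(4 * N), ks(4 * N);
  std::vector<double> Gs(N);

  const double *Gp = G.begin();

  // derivative of the full population at stage state (av, aw, ai, as_),
  // stage time t, delayed v sampled (steps_back) steps before step `step`
  auto deriv = [&](int step, double t, double steps_back, double *dv,
                   double *dw, double *di, double *ds, double *iion) {
    // synaptic drive: Gs = G * s
    std::fill(Gs.begin(), Gs.end(), 0.0);
    for (int k = 0; k < N; ++k) {
      const double sk = as_[k];
      if (sk == 0.0) continue;
      const double *col = Gp + (size_t)k * N;
      for (int j = 0; j < N; ++j) Gs[j] += col[j] * sk;
    }
    const double wv = stim_at(t, wave.begin(), win_on, win_off);
    // delayed membrane potential: linear interpolation in the ring buffer
    int f = 0; double frac = 0.0; bool delayed = (tau > 0.0);
    if (delayed) {
      double x = (double)step - steps_back;    // fractional step index
      if (x > (double)step) x = (double)step;  // never read ahead of history
      f = (int)std::floor(x);
      frac = x - f;
    }
    for (int j = 0; j < N; ++j) {
      double vd;
      if (delayed) {
        int s0i = ((f % hb) + hb) % hb;
        int s1i = (s0i + 1) % hb;
        vd = (1.0 - frac) * hist[(size_t)s0i * N + j] +
             frac * hist[(size_t)s1i * N + j];
      } else {
        vd = av[j];
      }
      const double vv = av[j];
      const double m_inf = 0.5 * (1.0 + std::tanh((vv - p1) / p2));
      const double w_inf = 0.5 * (1.0 + std::tanh((vv - p3) / p4));
      const double tau_w = 1.0 / std::cosh((vv - p3) / (2.0 * p4));
      const double istim = stim_gain[j] * wv;
      const double rhs = -g_ca * m_inf * (vv - v_ca) - g_k * aw[j] * (vv - v_k)
                         - g_l * (vv - v_l) + ai[j] + Gs[j] * (v_rev - vv)
                         + noi[j] + istim;
      dv[j] = rhs / C;
      dw[j] = phi * (w_inf - aw[j]) / tau_w;
      di[j] = eps[j] * (v_star - vd - alpha * ai[j]);
      const double h_inf = 1.0 / (1.0 + std::exp(-(vv - th_s) / sg_s));
      ds[j] = a_s * h_inf * (1.0 - as_[j]) - b_s * as_[j];
      if (iion) iion[j] = rhs - istim;  // all currents except stimulation (C = 1 scale)
    }
  };

  int rec = 0;
  const double tau_over_dt = (tau > 0.0) ? tau / dt : 0.0;
  for (int i = 0; i < n_steps; ++i) {
    const double t = i * dt;
    // write current v into the history ring before taking the step
    {
      int slot = i % hb;
      for (int j = 0; j < N; ++j) hist[(size_t)slot * N + j] = v[j];
    }
    const bool record = (i % stride == 0);
    // k1
    for (int j = 0; j < N; ++j) { av[j] = v[j]; aw[j] = w[j]; ai[j] = isl[j]; as_[j] = s[j]; }
    deriv(i, t, tau_over_dt, &kv[0], &kw[0], &ki[0], &ks[0],
          record ? &Iion(0, rec) : (double *)nullptr);
    if (record) {
      times[rec] = t;
      for (int j = 0; j < N; ++j) { V(j, rec) = v[j]; S(j, rec) = s[j]; }
      // Iion column was filled via the deriv call (column-major stride N)
      ++rec;
    }
    // k2
    for (int j = 0; j < N; ++j) {
      av[j] = v[j] + 0.5 * dt * kv[j]; aw[j] = w[j] + 0.5 * dt * kw[j];
      ai[j] = isl[j] + 0.5 * dt * ki[j]; as_[j] = s[j] + 0.5 * dt * ks[j];
    }
    deriv(i, t + 0.5 * dt, tau_over_dt - 0.5, &kv[N], &kw[N], &ki[N], &ks[N], nullptr);
    // k3
    for (int j = 0; j < N; ++j) {
      av[j] = v[j] + 0.5 * dt * kv[N + j]; aw[j] = w[j] + 0.5 * dt * kw[N + j];
      ai[j] = isl[j] + 0.5 * dt * ki[N + j]; as_[j] = s[j] + 0.5 * dt * ks[N + j];
    }
    deriv(i, t + 0.5 * dt, tau_over_dt - 0.5, &kv[2 * N], &kw[2 * N], &ki[2 * N], &ks[2 * N], nullptr);
    // k4
    for (int j = 0; j < N; ++j) {
      av[j] = v[j] + dt * kv[2 * N + j]; aw[j] = w[j] + dt * kw[2 * N + j];
      ai[j] = isl[j] + dt * ki[2 * N + j]; as_[j] = s[j] + dt * ks[2 * N + j];
    }
    deriv(i, t + dt, tau_over_dt - 1.0, &kv[3 * N], &kw[3 * N], &ki[3 * N], &ks[3 * N], nullptr);

    for (int j = 0; j < N; ++j) {
      v[j] += dt / 6.0 * (kv[j] + 2.0 * kv[N + j] + 2.0 * kv[2 * N + j] + kv[3 * N + j]);
      w[j] += dt / 6.0 * (kw[j] + 2.0 * kw[N + j] + 2.0 * kw[2 * N + j] + kw[3 * N + j]);
      isl[j] += dt / 6.0 * (ki[j] + 2.0 * ki[N + j] + 2.0 * ki[2 * N + j] + ki[3 * N + j]);
      s[j] += dt / 6.0 * (ks[j] + 2.0 * ks[N + j] + 2.0 * ks[2 * N + j] + ks[3 * N + j]);
    }
    if (D_noise > 0.0)
      for (int j = 0; j < N; ++j) noi[j] = noi[j] * edt + sig_up * norm_rand();

    if ((i & 1023) == 0) {
      for (int j = 0; j < N; ++j)
        if (!std::isfinite(v[j]))
          stop("non-finite membrane potential at step %d, neuron %d", i, j + 1);
    }
  }
  for (int j = 0; j < N; ++j)
    if (!std::isfinite(v[j]))
      stop("non-finite membrane potential at final step, neuron %d", j + 1);

  return List::create(_["times"] = times, _["V"] = V, _["S"] = S,
                      _["I_ion"] = Iion);
}

// Izhikevich chattering network, forward Euler with post-step reset.
// Time base is milliseconds.  Spike (reset) events are returned exactly.
// [[Rcpp::export]]
List cpp_simulate_izh(NumericMatrix G, NumericVector stim_gain,
                      NumericVector v0, NumericVector u0, NumericVector s0,
                      NumericVector drive, List prm, List gate, double v_rev,
                      NumericVector wave, double win_on, double win_off,
                      double D_noise, double tau_noise, double dt,
                      int n_steps, int stride) {
  const int N = v0.size();
  if (G.nrow() != N || G.ncol() != N || stim_gain.size() != N ||
      drive.size() != N)
    stop("coupling matrix / stimulation gain dimension mismatch");

  const double a = prm["a"], b = prm["b"], c_reset = prm["c_reset"];
  const double d = prm["d"], cut = prm["spike_cut"];
  const double a_s = gate["alpha_s"], b_s = gate["beta_s"];
  const double th_s = gate["theta_s"], sg_s = gate["sigma_s"];

  const int n_rec = (n_steps - 1) / stride + 1;
  NumericMatrix V(N, n_rec), S(N, n_rec), Iion(N, n_rec);
  NumericVector times(n_rec);

  std::vector<double> v(N), u(N), s(N), noi(N, 0.0), Gs(N);
  for (int j = 0; j < N; ++j) { v[j] = v0[j]; u[j] = u0[j]; s[j] = s0[j]; }

  const double edt = std::exp(-dt / tau_noise);
  const double sig_eq = D_noise * std::sqrt(tau_noise / 2.0);
  const double sig_up = sig_eq * std::sqrt(1.0 - edt * edt);
  if (D_noise > 0.0)
    for (int j = 0; j < N; ++j) noi[j] = sig_eq * norm_rand();

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  spike_t.reserve(4096); spike_id.reserve(4096);

  const double *Gp = G.begin();
  int rec = 0;
  for (int i = 0; i < n_steps; ++i) {
    const double t = i * dt;
    std::fill(Gs.begin(), Gs.end(), 0.0);
    for (int k = 0; k < N; ++k) {
      const double sk = s[k];
      if (sk == 0.0) continue;
      const double *col = Gp + (size_t)k * N;
      for (int j = 0; j < N; ++j) Gs[j] += col[j] * sk;
    }
    const double wv = stim_at(t, wave.begin(), win_on, win_off);
    const bool record = (i % stride == 0);
    if (record) times[rec] = t;
    for (int j = 0; j < N; ++j) {
      const double vv = v[j];
      const double istim = stim_gain[j] * wv;
      const double iion = 0.04 * vv * vv + 5.0 * vv + 140.0 - u[j] + drive[j]
                          + Gs[j] * (v_rev - vv) + noi[j];
      const double dv = iion + istim;
      const double du = a * (b * vv - u[j]);
      const double h_inf = 1.0 / (1.0 + std::exp(-(vv - th_s) / sg_s));
      const double ds = a_s * h_inf * (1.0 - s[j]) - b_s * s[j];
      if (record) { V(j, rec) = vv; S(j, rec) = s[j]; Iion(j, rec) = iion; }
      v[j] = vv + dt * dv;
      u[j] += dt * du;
      s[j] += dt * ds;
      if (v[j] >= cut) {
        spike_t.push_back(t + dt);
        spike_id.push_back(j + 1);
        v[j] = c_reset;
        u[j] += d;
      }
    }
    if (record) ++rec;
    if (D_noise > 0.0)
      for (int j = 0; j < N; ++j) noi[j] = noi[j] * edt + sig_up * norm_rand();
    if ((i & 1023) == 0) {
      for (int j = 0; j < N; ++j)
        if (!std::isfinite(v[j]))
          stop("non-finite membrane potential at step %d, neuron %d (reduce dt)", i, j + 1);
    }
  }
  for (int j = 0; j < N; ++j)
    if (!std::isfinite(v[j]))
      stop("non-finite membrane potential at final step, neuron %d", j + 1);

  return List::create(_["times"] = times, _["V"] = V, _["S"] = S,
                      _["I_ion"] = Iion, _["spike_t"] = wrap(spike_t),
                      _["spike_id"] = wrap(spike_id));
}
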