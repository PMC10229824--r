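#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fixed-step Heun (explicit trapezoid) integration of a network of
// second-order synaptic channels with delayed sigmoid coupling.
//
// Each population carries two receptor channels (0 = excitatory, 1 =
// inhibitory); a channel is the state-space realization of the alpha kernel
// p(t) = (H / tau) t exp(-t / tau):
//
//   v' = z
//   z' = (H / tau) u(t) - (2 / tau) z - v / tau^2        (t, tau in ms)
//
// u(t) is the delayed, gain-weighted sum of presynaptic normalized firing
// rates S(V) = 1 / (1 + exp(-r V)) - 1/2 plus sampled exogenous drive.
// The composite membrane potential of a population is v[exc] - v[inh]; it
// is the sigmoid argument for outgoing connections and, scaled by a
// lead-field gain, the observed quantity for output populations.
//
// Delays are honoured through a per-population history of composite
// potentials. Both Heun stages of every step sample the history on the step
// grid whenever delay/dt is integral (the default configuration), so the
// sigmoid of each (population, step) pair is computed once and memoized;
// non-integral delays fall back to linear interpolation of the potential.

static inline double sig_rate(double v, double r) {
  return 1.0 / (1.0 + std::exp(-r * v)) - 0.5;
}

// [[Rcpp::export(name = ".simulate_network_cpp")]]
List simulate_network_cpp(int n_pop,
                          NumericVector H,          // 2 * n_pop, channel-major
                          NumericVector tau,        // 2 * n_pop
                          IntegerVector conn_from,  // presynaptic population, 0-based
                          IntegerVector conn_chan,  // target channel 2*pop + c, 0-based
                          NumericVector conn_gain,
                          NumericVector conn_delay, // ms
                          NumericMatrix exo,        // (n_steps + 1) x n_exo, sampled drive
                          IntegerVector exo_chan,   // target channel per exo column
                          double r,
                          double dt,
                          int n_steps,
                          int out_every,
                          IntegerVector obs_pop,    // observed populations, 0-based
                          NumericVector obs_gain,
                          bool return_states) {
  const int n_chan = 2 * n_pop;
  const int n_conn = conn_from.size();
  const int n_exo  = exo_chan.size();
  const int n_obs  = obs_pop.size();

  if ((int)H.size() != n_chan || (int)tau.size() != n_chan)
    stop("H and tau must have one entry per receptor channel");
  if (n_exo > 0 && exo.nrow() != n_steps + 1)
    stop("exogenous drive must be sampled on the step grid (n_steps + 1 rows)");

  // per-connection delay in (possibly fractional) steps
  std::vector<double> dsteps(n_conn);
  std::vector<int> dint(n_conn);     // -1 if not integral
  for (int j = 0; j < n_conn; ++j) {
    if (conn_delay[j] < dt) stop("connection delays must be at least dt");
    double s = conn_delay[j] / dt;
    dsteps[j] = s;
    double rs = std::round(s);
    dint[j] = (std::fabs(s - rs) < 1e-9) ? (int)rs : -1;
  }

  std::vector<double> v(n_chan, 0.0), z(n_chan, 0.0);
  std::vector<double> v1(n_chan), z1(n_chan);
  std::vector<double> dv1(n_chan), dz1(n_chan), dv2(n_chan), dz2(n_chan);
  std::vector<double> u(n_chan);

  // composite-potential history and memoized sigmoid, step-major
  std::vector<double> hist((n_steps + 1) * (size_t)n_pop, 0.0);
  std::vector<double> smem((n_steps + 1) * (size_t)n_pop, 0.0);
  std::vector<char> shave((n_steps + 1) * (size_t)n_pop, 0);
  for (int p = 0; p < n_pop; ++p) { smem[p] = 0.0; shave[p] = 1; }

  std::vector<double> a1(n_chan), a2(n_chan), b(n_chan);
  for (int c = 0; c < n_chan; ++c) {
    if (tau[c] <= 0) stop("receptor time constants must be positive");
    a1[c] = 2.0 / tau[c];
    a2[c] = 1.0 / (tau[c] * tau[c]);
    b[c]  = H[c] / tau[c];
  }

  const int n_out = n_steps / out_every;
  NumericMatrix y(n_obs, n_out);
  NumericMatrix states;
  if (return_states) states = NumericMatrix(n_out, n_pop);
  const double* exo_ptr = n_exo ? REAL(exo) : nullptr;
  const int exo_nrow = n_exo ? exo.nrow() : 0;

  // sigmoid of population pop at step grid index k (k <= current step)
  auto s_at = [&](int pop, int k) -> double {
    size_t ix = (size_t)k * n_pop + pop;
    if (!shave[ix]) { smem[ix] = sig_rate(hist[ix], r); shave[ix] = 1; }
    return smem[ix];
  };

  // delayed rate for connection j when the current stage sits at grid
  // index k_stage (stage time = k_stage * dt)
  auto delayed_rate = [&](int j, int k_stage) -> double {
    if (dint[j] >= 0) {
      int k = k_stage - dint[j];
      if (k <= 0) return 0.0;
      return s_at(conn_from[j], k);
    }
    double s = (double)k_stage - dsteps[j];
    if (s <= 0.0) return 0.0;
    int i0 = (int)s;
    double w = s - i0;
    const double* hp = &hist[(size_t)i0 * n_pop + conn_from[j]];
    double vd = (1.0 - w) * hp[0] + w * hp[n_pop];
    return sig_rate(vd, r);
  };

  auto derivs = [&](int k_stage, const std::vector<double>& vv,
                    const std::vector<double>& zz,
                    std::vector<double>& dv, std::vector<double>& dz) {
    std::fill(u.begin(), u.end(), 0.0);
    for (int j = 0; j < n_conn; ++j)
      u[conn_chan[j]] += conn_gain[j] * delayed_rate(j, k_stage);
    for (int j = 0; j < n_exo; ++j)
      u[exo_chan[j]] += exo_ptr[(size_t)j * exo_nrow + k_stage];
    for (int c = 0; c < n_chan; ++c) {
      dv[c] = zz[c];
      dz[c] = b[c] * u[c] - a1[c] * zz[c] - a2[c] * vv[c];
    }
  };

  int out_i = 0;
  for (int k = 0; k < n_steps; ++k) {
    derivs(k, v, z, dv1, dz1);
    for (int c = 0; c < n_chan; ++c) {
      v1[c] = v[c] + dt * dv1[c];
      z1[c] = z[c] + dt * dz1[c];
    }
    derivs(k + 1, v1, z1, dv2, dz2);
    for (int c = 0; c < n_chan; ++c) {
      v[c] += 0.5 * dt * (dv1[c] + dv2[c]);
      z[c] += 0.5 * dt * (dz1[c] + dz2[c]);
    }
    double* hrow = &hist[(size_t)(k + 1) * n_pop];
    for (int p = 0; p < n_pop; ++p) {
      double comp = v[2 * p] - v[2 * p + 1];
      if (!std::isfinite(comp))
        stop("non-finite state in population %d at t = %.1f ms",
             p + 1, (k + 1) * dt);
      hrow[p] = comp;
    }
    if ((k + 1) % out_every == 0) {
      for (int s = 0; s < n_obs; ++s)
        y(s, out_i) = obs_gain[s] * hrow[obs_pop[s]];
      if (return_states)
        for (int p = 0; p < n_pop; ++p) states(out_i, p) = hrow[p];
      ++out_i;
    }
  }

  List out = List::create(_["y"] = y);
  if (return_states) out["states"] = states;
  return out;
}
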