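#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"
using namespace Rcpp;

// Exact stochastic gating of voltage-dependent calcium channels.
// Five-state linear chain C1 <-> C2 <-> C3 <-> C4 <-> O with voltage-
// dependent rates a_i(v) = a0_i * exp(v / v_i) (forward) and
// b_i(v) = b0_i * exp(-v / v_i) (backward), piecewise-constant voltage.
// State codes 0..4; state 4 is the open, conducting state.

// t: sample edges (ms), length nt; v_mv piecewise constant on [t[k], t[k+1]).
// Returns one jump record per transition: channel, time, new state.
// [[Rcpp::export]]
DataFrame cpp_simulate_vdcc(NumericVector t, NumericVector v_mv,
                            NumericVector a0, NumericVector b0,
                            NumericVector vk, int n_channels,
                            NumericVector seeds, int init_state) {
  const int nt = t.size();
  if ((int)v_mv.size() != nt - 1) stop("voltage must have length(t) - 1 values");
  if ((int)seeds.size() != n_channels) stop("one seed per channel required");
  if (a0.size() != 4 || b0.size() != 4 || vk.size() != 4)
    stop("need 4 rate pairs");

  // per-interval rates (4 forward, 4 backward), precomputed
  std::vector<double> fw(4 * (nt - 1)), bw(4 * (nt - 1));
  for (int k = 0; k < nt - 1; ++k)
    for (int i = 0; i < 4; ++i) {
      fw[4 * k + i] = a0[i] * std::exp(v_mv[k] / vk[i]);
      bw[4 * k + i] = b0[i] * std::exp(-v_mv[k] / vk[i]);
    }

  std::vector<int> out_ch, out_state;
  std::vector<double> out_time;

  for (int ch = 0; ch < n_channels; ++ch) {
    Xoshiro rng(static_cast<uint64_t>(seeds[ch]));
    int s = init_state;
    for (int k = 0; k < nt - 1; ++k) {
      double now = t[k];
      const double tend = t[k + 1];
      const double* f = &fw[4 * k];
      const double* b = &bw[4 * k];
      while (now < tend) {
        double rf = s < 4 ? f[s] : 0.0;
        double rb = s > 0 ? b[s - 1] : 0.0;
        double R = rf + rb;
        if (R <= 0.0) { now = tend; break; }
        double dt = rng.expo() / R;
        if (now + dt >= tend) { now = tend; break; }
        now += dt;
        s += (rng.unif() * R < rf) ? 1 : -1;
        out_ch.push_back(ch);
        out_time.push_back(now);
        out_state.push_back(s);
      }
    }
  }

  return DataFrame::create(_["channel"] = out_ch,
                           _["time_ms"] = out_time,
                           _["state"] = out_state);
}

// Poisson ion-injection schedule from open intervals.
// open: matrix with columns (channel, t_open, t_close); counts drawn per dt.
// [[Rcpp::export]]
DataFrame cpp_flux_events(NumericMatrix open, double flux_open, double dt,
                          double t_end, double seed) {
  if (dt <= 0) stop("dt must be positive");
  if (flux_open < 0) stop("flux must be nonnegative");
  Xoshiro rng(static_cast<uint64_t>(seed));
  std::vector<int> out_ch, out_n;
  std::vector<double> out_t;
  for (int i = 0; i < open.nrow(); ++i) {
    int ch = (int)open(i, 0);
    double t0 = open(i, 1), t1 = std::min(open(i, 2), t_end);
    for (double s = t0; s < t1; s += dt) {
      double w = std::min(dt, t1 - s);
      int n = rng.poisson(flux_open * w);
      if (n > 0) {
        out_ch.push_back(ch);
        out_t.push_back(s);
        out_n.push_back(n);
      }
    }
  }
  return DataFrame::create(_["channel"] = out_ch, _["time_ms"] = out_t,
                           _["ions"] = out_n);
}
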