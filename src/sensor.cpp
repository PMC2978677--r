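#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"
using namespace Rcpp;

// Exact stochastic simulation of the dual calcium-sensor release machinery of
// an active zone, driven by piecewise-constant calcium traces.
//
// State per docked vesicle: (ns in 0..n_sync, na in 0..n_async).
// Transitions (rates in /ms, concentrations in uM, k_on in /uM/ms):
//   ns -> ns+1 : (n_sync - ns) * ks_plus * C
//   ns -> ns-1 : ns * ks_minus * b^(ns-1)
//   na -> na+1 : (n_async - na) * ka_plus * C
//   na -> na-1 : na * ka_minus * b^(na-1)   (or b^0 if b_async = 0)
//   fusion     : gamma from ns = n_sync (synchronous),
//                a * gamma from na = n_async (asynchronous),
//                delta from (0,0) (spontaneous; or any state if delta_any)
// A zone-wide gate disables all fusion transitions for an exponentially
// distributed interval (mean epsilon_ms) after every release; calcium
// binding continues while the gate is shut.

struct ZonePar {
  double ksp, ksm, kap, kam, b, gamma, a, delta, eps;
  int n_sync, n_async, n_ves;
  bool b_async, delta_any, refractory, refr_det, depletion_free;
  bool sync_ko, async_ko, phenom;
  double refr_dead;
  double async_gamma; // fusion rate from the asynchronous fully-bound state
};

static ZonePar parse_par(const List& par) {
  ZonePar p;
  p.ksp   = as<double>(par["ks_plus"]);
  p.ksm   = as<double>(par["ks_minus"]);
  p.kap   = as<double>(par["ka_plus"]);
  p.kam   = as<double>(par["ka_minus"]);
  p.b     = as<double>(par["b"]);
  p.gamma = as<double>(par["gamma"]);
  p.a     = as<double>(par["a"]);
  p.delta = as<double>(par["delta"]);
  p.eps   = as<double>(par["epsilon_ms"]);
  p.n_sync  = as<int>(par["n_sync"]);
  p.n_async = as<int>(par["n_async"]);
  p.n_ves   = as<int>(par["n_vesicles"]);
  p.b_async = as<bool>(par["b_async"]);
  p.delta_any = as<bool>(par["delta_any"]);
  p.refractory = as<bool>(par["refractory"]);
  p.refr_det   = as<bool>(par["refractory_deterministic"]);
  p.refr_dead  = as<double>(par["refractory_dead_ms"]);
  p.depletion_free = as<bool>(par["depletion_free"]);
  p.sync_ko  = as<bool>(par["sync_ko"]);
  p.async_ko = as<bool>(par["async_ko"]);
  p.phenom   = as<bool>(par["phenomenological"]);
  p.async_gamma = as<double>(par["async_gamma"]);
  return p;
}

struct Ves {
  int ns, na;
  bool docked;
  // rates refreshed whenever C or state changes
  double bs, us, ba, ua, fus_s, fus_a, fus_d;
  double r_bind, r_fus;
};

static inline void refresh(Ves& v, double C, const ZonePar& p,
                           const std::vector<double>& bpow) {
  if (!v.docked) {
    v.bs = v.us = v.ba = v.ua = v.fus_s = v.fus_a = v.fus_d = 0.0;
    v.r_bind = v.r_fus = 0.0;
    return;
  }
  if (p.sync_ko) {
    v.bs = v.us = 0.0;
  } else {
    v.bs = (p.n_sync - v.ns) * p.ksp * C;
    v.us = v.ns > 0 ? v.ns * p.ksm * bpow[v.ns - 1] : 0.0;
  }
  if (p.async_ko) {
    v.ba = v.ua = 0.0;
  } else {
    v.ba = (p.n_async - v.na) * p.kap * C;
    v.ua = v.na > 0 ? v.na * p.kam * (p.b_async ? bpow[v.na - 1] : 1.0) : 0.0;
  }
  v.fus_s = (!p.sync_ko && v.ns == p.n_sync) ? p.gamma : 0.0;
  v.fus_a = (!p.async_ko && v.na == p.n_async) ? p.async_gamma : 0.0;
  v.fus_d = (p.delta_any || (v.ns == 0 && v.na == 0)) ? p.delta : 0.0;
  v.r_bind = v.bs + v.us + v.ba + v.ua;
  v.r_fus = v.fus_s + v.fus_a + v.fus_d;
}

// t: length nt vector of sample edges (ms); the calcium trace is piecewise
// constant on [t[k], t[k+1]) with value baseline + scale * ca(k, vesicle).
// ca: (nt-1) x n_ves matrix of stimulus components (uM above baseline),
// or a single column recycled across vesicles.
// [[Rcpp::export]]
DataFrame cpp_simulate_zone(NumericVector t, NumericMatrix ca, List par,
                            int n_trials, NumericVector trial_seeds,
                            NumericVector trial_scale, double baseline) {
  ZonePar p = parse_par(par);
  const int nt = t.size();
  const int nint = nt - 1;
  if (ca.nrow() != nint) stop("calcium trace must have length(t) - 1 rows");
  const bool recycle = (ca.ncol() == 1);
  if (!recycle && ca.ncol() != p.n_ves)
    stop("calcium trace must have 1 or n_vesicles columns");
  if ((int)trial_seeds.size() != n_trials) stop("one seed per trial required");
  if ((int)trial_scale.size() != n_trials) stop("one scale per trial required");

  int nmax = std::max(p.n_sync, p.n_async);
  std::vector<double> bpow(nmax, 1.0);
  for (int i = 1; i < nmax; ++i) bpow[i] = bpow[i - 1] * p.b;

  std::vector<int> out_trial, out_ves, out_path;
  std::vector<double> out_time;

  std::vector<Ves> ves(p.n_ves);

  for (int trial = 0; trial < n_trials; ++trial) {
    Xoshiro rng(static_cast<uint64_t>(trial_seeds[trial]));
    double scale = trial_scale[trial];
    for (int v = 0; v < p.n_ves; ++v) {
      ves[v].ns = 0; ves[v].na = 0; ves[v].docked = true;
    }
    double gate_t = -1.0; // time the gate re-opens; gate open if now >= gate_t
    for (int k = 0; k < nint; ++k) {
      double now = t[k];
      const double tend = t[k + 1];
      bool dirty = true; // refresh all vesicle rates on entry (C changed)
      double Rb = 0.0, Rf = 0.0;
      while (now < tend) {
        if (dirty) {
          Rb = 0.0; Rf = 0.0;
          for (int v = 0; v < p.n_ves; ++v) {
            double C = baseline + scale * ca(k, recycle ? 0 : v);
            refresh(ves[v], C, p, bpow);
            Rb += ves[v].r_bind; Rf += ves[v].r_fus;
          }
          dirty = false;
        }
        bool open = now >= gate_t;
        double bound = tend;
        if (!open && gate_t < tend) bound = gate_t;
        double R = Rb + (open ? Rf : 0.0);
        if (R <= 0.0) { now = bound; continue; }
        double dt = rng.expo() / R;
        if (now + dt >= bound) { now = bound; continue; }
        now += dt;
        // choose vesicle and transition
        double u = rng.unif() * R;
        int hit = -1; int ev = -1;
        for (int v = 0; v < p.n_ves; ++v) {
          double tot = ves[v].r_bind + (open ? ves[v].r_fus : 0.0);
          if (u < tot) {
            const Ves& w = ves[v];
            if ((u -= w.bs) < 0) { hit = v; ev = 0; break; }
            if ((u -= w.us) < 0) { hit = v; ev = 1; break; }
            if ((u -= w.ba) < 0) { hit = v; ev = 2; break; }
            if ((u -= w.ua) < 0) { hit = v; ev = 3; break; }
            if (open) {
              if ((u -= w.fus_s) < 0) { hit = v; ev = 4; break; }
              if ((u -= w.fus_a) < 0) { hit = v; ev = 5; break; }
              if ((u -= w.fus_d) < 0) { hit = v; ev = 6; break; }
            }
            hit = -1; break; // rounding slack inside this vesicle: no event
          }
          u -= tot;
        }
        if (hit < 0) continue; // rounding slack: no event
        Ves& w = ves[hit];
        Rb -= w.r_bind; Rf -= w.r_fus;
        switch (ev) {
          case 0: w.ns += 1; break;
          case 1: w.ns -= 1; break;
          case 2: w.na += 1; break;
          case 3: w.na -= 1; break;
          default: {
            // fusion: ev 4 synchronous, 5 asynchronous, 6 spontaneous
            out_trial.push_back(trial);
            out_time.push_back(now);
            out_ves.push_back(hit);
            out_path.push_back(ev - 3);
            if (p.depletion_free || p.phenom) {
              if (p.depletion_free && !p.phenom) { w.ns = 0; w.na = 0; }
              // phenomenological gate keeps its occupancy
            } else {
              w.docked = false;
            }
            if (p.refractory) {
              double closure = p.refr_det ? p.refr_dead : p.eps * rng.expo();
              if (now + closure > gate_t) gate_t = now + closure;
            }
            break;
          }
        }
        double C = baseline + scale * ca(k, recycle ? 0 : hit);
        refresh(w, C, p, bpow);
        Rb += w.r_bind; Rf += w.r_fus;
      }
    }
  }

  return DataFrame::create(
      _["trial"] = out_trial,
      _["time_ms"] = out_time,
      _["vesicle"] = out_ves,
      _["pathway"] = out_path);
}
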