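#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include "rng.h"
using namespace Rcpp;

// Particle-based 3D reaction-diffusion of free calcium, the mobile buffer
// calbindin-D28k (2 high- + 2 medium-affinity sites per molecule) and
// immobile PMCA pumps in a box-shaped axon segment, with the free-calcium
// concentration clamped in thin slabs at both x-ends.
//
// Units: nm, ms, uM. Diffusion constants in nm^2/ms; on-rates in /uM/ms.
//
// Binding uses a cell-local mass-action probability: a free ion in a grid
// cell binds in dt with probability 1 - exp(-k_on * [free sites]_cell * dt),
// which recovers the macroscopic on-rate in a well-mixed volume. Molecules
// carrying bound calcium diffuse at the calbindin rate; a small set of
// "tagged" ions can be tracked individually (including through binding) to
// measure effective diffusion.

static const double IONS_PER_UM3_PER_UM = 6.02214076e-7; // ions per nm^3 per uM

struct Grid {
  int nx, ny, nz;
  double cell, inv_cell;
  double Lx, Ly, Lz;
  inline int idx(double x, double y, double z) const {
    int i = std::min(nx - 1, std::max(0, (int)(x * inv_cell)));
    int j = std::min(ny - 1, std::max(0, (int)(y * inv_cell)));
    int k = std::min(nz - 1, std::max(0, (int)(z * inv_cell)));
    return (i * ny + j) * nz + k;
  }
  int ncell() const { return nx * ny * nz; }
};

static inline void reflect(double& x, double L) {
  while (x < 0.0 || x > L) {
    if (x < 0.0) x = -x;
    if (x > L) x = 2.0 * L - x;
  }
}

// [[Rcpp::export]]
List cpp_simulate_bouton(List geom, List par, NumericMatrix inj,
                         double flux_open, NumericMatrix probes, List opt,
                         double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed));

  const double Lx = as<double>(geom["Lx"]), Ly = as<double>(geom["Ly"]),
               Lz = as<double>(geom["Lz"]);
  const double clamp_nm = as<double>(geom["clamp_nm"]);

  const double D_ca = as<double>(par["D_ca"]), D_cb = as<double>(par["D_cb"]);
  double dt_ca = as<double>(par["dt_ca"]), dt_other = as<double>(par["dt_other"]);
  const double t_fine = as<double>(par["t_fine_ms"]);
  const double coarse = as<double>(par["coarse_mult"]);
  const double resting = as<double>(par["resting_uM"]);
  const double clamp_uM = as<double>(par["clamp_uM"]);
  const double cb_conc = as<double>(par["cb_conc_uM"]);
  const double khp = as<double>(par["kh_plus"]), khm = as<double>(par["kh_minus"]);
  const double kmp = as<double>(par["km_plus"]), kmm = as<double>(par["km_minus"]);
  const int sites_h = as<int>(par["sites_high"]), sites_m = as<int>(par["sites_medium"]);
  const double pmca_density = as<double>(par["pmca_density_per_nm2"]);
  const double kpm1 = as<double>(par["kpm1"]), kpm2 = as<double>(par["kpm2"]),
               kpm3 = as<double>(par["kpm3"]), kpm4 = as<double>(par["kpm4"]);
  const double leak = as<double>(par["leak_per_ms"]);
  const double cell_nm = as<double>(par["cell_nm"]);

  const double t_end = as<double>(opt["t_end_ms"]);
  const double out_dt = as<double>(opt["out_dt_ms"]);
  const int n_tagged = as<int>(opt["n_tagged"]);
  const double tag_dt = as<double>(opt["tag_dt_ms"]);
  NumericVector tag_origin = as<NumericVector>(opt["tag_origin"]);

  Grid g;
  std::vector<int> fill_buf;
  g.cell = cell_nm; g.inv_cell = 1.0 / cell_nm; g.Lx = Lx; g.Ly = Ly; g.Lz = Lz;
  g.nx = std::max(1, (int)std::round(Lx / cell_nm));
  g.ny = std::max(1, (int)std::round(Ly / cell_nm));
  g.nz = std::max(1, (int)std::round(Lz / cell_nm));
  const double vol = Lx * Ly * Lz;
  const double conv_box = vol * IONS_PER_UM3_PER_UM;          // ions per uM, whole box
  const double cell_vol = (Lx / g.nx) * (Ly / g.ny) * (Lz / g.nz);
  const double conv_cell = cell_vol * IONS_PER_UM3_PER_UM;    // ions per uM, one cell
  const double uM_per_site = 1.0 / conv_cell;

  // ---- free calcium ------------------------------------------------------
  std::vector<double> cax, cay, caz;
  int n0 = rng.poisson(resting * conv_box);
  cax.reserve(n0 + 1024); cay.reserve(n0 + 1024); caz.reserve(n0 + 1024);
  for (int i = 0; i < n0; ++i) {
    cax.push_back(rng.unif() * Lx);
    cay.push_back(rng.unif() * Ly);
    caz.push_back(rng.unif() * Lz);
  }

  // ---- calbindin ---------------------------------------------------------
  const int n_cb = (int)std::round(cb_conc * conv_box);
  std::vector<double> cbx(n_cb), cby(n_cb), cbz(n_cb);
  std::vector<signed char> bh(n_cb, 0), bm(n_cb, 0), th(n_cb, 0), tm(n_cb, 0);
  const double kd_h = khm / khp, kd_m = kmm / kmp;
  const double occ_h = resting / (resting + kd_h);
  const double occ_m = resting / (resting + kd_m);
  for (int i = 0; i < n_cb; ++i) {
    cbx[i] = rng.unif() * Lx; cby[i] = rng.unif() * Ly; cbz[i] = rng.unif() * Lz;
    for (int s = 0; s < sites_h; ++s) if (rng.unif() < occ_h) bh[i]++;
    for (int s = 0; s < sites_m; ++s) if (rng.unif() < occ_m) bm[i]++;
  }

  // per-cell free-site sums and molecule lists
  std::vector<double> SH(g.ncell(), 0.0), SM(g.ncell(), 0.0);
  std::vector<int> cb_cell(n_cb);
  std::vector<int> cell_start(g.ncell() + 1, 0), mol_sorted(n_cb);
  auto rebuild_cb = [&]() {
    std::fill(SH.begin(), SH.end(), 0.0);
    std::fill(SM.begin(), SM.end(), 0.0);
    std::fill(cell_start.begin(), cell_start.end(), 0);
    for (int i = 0; i < n_cb; ++i) {
      int c = g.idx(cbx[i], cby[i], cbz[i]);
      cb_cell[i] = c;
      SH[c] += sites_h - bh[i];
      SM[c] += sites_m - bm[i];
      cell_start[c + 1]++;
    }
    for (int c = 0; c < g.ncell(); ++c) cell_start[c + 1] += cell_start[c];
    std::vector<int> fill = cell_start;
    for (int i = 0; i < n_cb; ++i) mol_sorted[fill[cb_cell[i]]++] = i;
  };
  rebuild_cb();

  // ---- PMCA pumps --------------------------------------------------------
  const double area = 2.0 * (Lx * Ly + Lx * Lz + Ly * Lz);
  const int n_pump = (int)std::round(pmca_density * area);
  std::vector<double> px(n_pump), py(n_pump), pz(n_pump);
  std::vector<signed char> pstate(n_pump);
  {
    // equilibrium cycle occupancy at resting calcium
    double r1 = kpm1 * resting, p1 = r1 / (kpm2 + kpm3);
    double p2 = p1 * kpm3 / kpm4;
    double z0 = 1.0 + p1 + p2;
    double w[6] = {Lx * Ly, Lx * Ly, Lx * Lz, Lx * Lz, Ly * Lz, Ly * Lz};
    double wtot = 0; for (double v2 : w) wtot += v2;
    for (int i = 0; i < n_pump; ++i) {
      double u = rng.unif() * wtot; int f = 0;
      while (u > w[f]) { u -= w[f]; ++f; }
      double a = rng.unif(), b2 = rng.unif();
      switch (f) {
        case 0: px[i] = a * Lx; py[i] = b2 * Ly; pz[i] = 0.5; break;
        case 1: px[i] = a * Lx; py[i] = b2 * Ly; pz[i] = Lz - 0.5; break;
        case 2: px[i] = a * Lx; py[i] = 0.5; pz[i] = b2 * Lz; break;
        case 3: px[i] = a * Lx; py[i] = Ly - 0.5; pz[i] = b2 * Lz; break;
        case 4: px[i] = 0.5; py[i] = a * Ly; pz[i] = b2 * Lz; break;
        default: px[i] = Lx - 0.5; py[i] = a * Ly; pz[i] = b2 * Lz; break;
      }
      double u2 = rng.unif() * z0;
      pstate[i] = u2 < 1.0 ? 0 : (u2 < 1.0 + p1 ? 1 : 2);
    }
  }
  std::vector<int> pump_cell(n_pump);
  for (int i = 0; i < n_pump; ++i) pump_cell[i] = g.idx(px[i], py[i], pz[i]);

  // ---- tagged ions -------------------------------------------------------
  std::vector<double> tx(n_tagged), ty(n_tagged), tz(n_tagged);
  std::vector<int> tstate(n_tagged, 0);  // 0 free, 1 bound-high, 2 bound-medium
  std::vector<int> tmol(n_tagged, -1);
  for (int i = 0; i < n_tagged; ++i) {
    tx[i] = tag_origin[0]; ty[i] = tag_origin[1]; tz[i] = tag_origin[2];
  }

  // ---- outputs -----------------------------------------------------------
  const int n_probe = probes.nrow();
  const int n_out = (int)std::ceil(t_end / out_dt);
  NumericMatrix probe_out(n_out, n_probe);
  NumericVector probe_t(n_out);
  NumericVector bulk_out(n_out);
  std::vector<double> probe_acc(n_probe, 0.0);
  int acc_n = 0;
  std::vector<double> probe_conv(n_probe);
  for (int p = 0; p < n_probe; ++p) {
    double r = probes(p, 3);
    double v = (4.0 / 3.0) * M_PI * r * r * r;
    // clip the sampling sphere against the box faces (spherical caps)
    double d[6] = {probes(p, 0), Lx - probes(p, 0), probes(p, 1),
                   Ly - probes(p, 1), probes(p, 2), Lz - probes(p, 2)};
    for (int f = 0; f < 6; ++f) {
      if (d[f] < r) {
        double h = r - d[f];
        v -= M_PI * h * h * (3.0 * r - h) / 3.0;
      }
    }
    probe_conv[p] = v * IONS_PER_UM3_PER_UM;
  }
  int n_tag_out = n_tagged > 0 ? (int)std::floor(t_end / tag_dt) + 1 : 0;
  NumericMatrix tag_out(n_tagged > 0 ? n_tag_out * n_tagged : 0, 5);
  int tag_row = 0;

  long long injected = 0, extruded = 0, leaked = 0, clamp_add = 0, clamp_rm = 0;
  long long init_free = (long long)cax.size();
  long long init_bound = 0;
  for (int i = 0; i < n_cb; ++i) init_bound += bh[i] + bm[i];
  long long init_pump_held = 0;
  for (int i = 0; i < n_pump; ++i) if (pstate[i] == 1) ++init_pump_held;

  // per-cell untagged free-ion counts (for pumps), rebuilt each dt_other
  std::vector<int> ca_count(g.ncell(), 0);

  auto record_tags = [&](double now) {
    for (int i = 0; i < n_tagged; ++i) {
      double x = tx[i], y = ty[i], z = tz[i];
      if (tstate[i] != 0) { x = cbx[tmol[i]]; y = cby[tmol[i]]; z = cbz[tmol[i]]; }
      tag_out(tag_row, 0) = i; tag_out(tag_row, 1) = now;
      tag_out(tag_row, 2) = x; tag_out(tag_row, 3) = y; tag_out(tag_row, 4) = z;
      ++tag_row;
    }
  };
  double next_tag = 0.0;
  if (n_tagged > 0) { record_tags(0.0); next_tag = tag_dt; }

  const int n_inj = inj.nrow();

  double now = 0.0;
  int out_i = 0;
  bool coarse_on = false;

  while (now < t_end - 1e-12) {
    if (!coarse_on && now >= t_fine) {
      dt_ca *= coarse; dt_other *= coarse; coarse_on = true;
    }
    double step = std::min(dt_other, t_end - now);
    int nsub = std::max(1, (int)std::round(step / dt_ca));
    double sub = step / nsub;
    double sig_ca = std::sqrt(2.0 * D_ca * sub);

    // ---- calcium substeps: diffusion, injection, buffer binding ----------
    for (int ss = 0; ss < nsub; ++ss) {
      double tnow = now + ss * sub;
      // injection from open channels
      if (flux_open > 0.0) {
        for (int r = 0; r < n_inj; ++r) {
          if (tnow >= inj(r, 3) && tnow < inj(r, 4)) {
            int n = rng.poisson(flux_open * sub);
            for (int q = 0; q < n; ++q) {
              cax.push_back(inj(r, 0)); cay.push_back(inj(r, 1)); caz.push_back(inj(r, 2));
            }
            injected += n;
          }
        }
      }
      // untagged free ions: move then maybe bind
      for (size_t i = 0; i < cax.size();) {
        cax[i] += sig_ca * rng.norm_fast(); reflect(cax[i], Lx);
        cay[i] += sig_ca * rng.norm_fast(); reflect(cay[i], Ly);
        caz[i] += sig_ca * rng.norm_fast(); reflect(caz[i], Lz);
        int c = g.idx(cax[i], cay[i], caz[i]);
        double rate = (khp * SH[c] + kmp * SM[c]) * uM_per_site;
        if (rate > 0.0 && rng.unif() < -std::expm1(-rate * sub)) {
          bool high = rng.unif() * (khp * SH[c] + kmp * SM[c]) < khp * SH[c];
          // pick a molecule in this cell holding a free site of that type
          double tot = high ? SH[c] : SM[c];
          double u = rng.unif() * tot;
          int chosen = -1;
          for (int q2 = cell_start[c]; q2 < cell_start[c + 1]; ++q2) {
            int mi = mol_sorted[q2];
            double wfree = high ? (sites_h - bh[mi]) : (sites_m - bm[mi]);
            if (u < wfree) { chosen = mi; break; }
            u -= wfree;
          }
          if (chosen >= 0) {
            if (high) { bh[chosen]++; SH[c] -= 1.0; }
            else { bm[chosen]++; SM[c] -= 1.0; }
            cax[i] = cax.back(); cay[i] = cay.back(); caz[i] = caz.back();
            cax.pop_back(); cay.pop_back(); caz.pop_back();
            continue; // do not advance i
          }
        }
        ++i;
      }
      // tagged free ions
      for (int i = 0; i < n_tagged; ++i) {
        if (tstate[i] != 0) continue;
        tx[i] += sig_ca * rng.norm_fast(); reflect(tx[i], Lx);
        ty[i] += sig_ca * rng.norm_fast(); reflect(ty[i], Ly);
        tz[i] += sig_ca * rng.norm_fast(); reflect(tz[i], Lz);
        int c = g.idx(tx[i], ty[i], tz[i]);
        double rate = (khp * SH[c] + kmp * SM[c]) * uM_per_site;
        if (rate > 0.0 && rng.unif() < -std::expm1(-rate * sub)) {
          bool high = rng.unif() * (khp * SH[c] + kmp * SM[c]) < khp * SH[c];
          double tot = high ? SH[c] : SM[c];
          double u = rng.unif() * tot;
          int chosen = -1;
          for (int q2 = cell_start[c]; q2 < cell_start[c + 1]; ++q2) {
            int mi = mol_sorted[q2];
            double wfree = high ? (sites_h - bh[mi]) : (sites_m - bm[mi]);
            if (u < wfree) { chosen = mi; break; }
            u -= wfree;
          }
          if (chosen >= 0) {
            if (high) { bh[chosen]++; th[chosen]++; SH[c] -= 1.0; tstate[i] = 1; }
            else { bm[chosen]++; tm[chosen]++; SM[c] -= 1.0; tstate[i] = 2; }
            tmol[i] = chosen;
          }
        }
      }
    }

    // ---- slower species, once per dt_other -------------------------------
    // calbindin: one fused pass does diffusion, unbinding and the first
    // counting-sort pass of the cell-cache rebuild
    double sig_cb = std::sqrt(2.0 * D_cb * step);
    double p_uh = -std::expm1(-khm * step), p_um = -std::expm1(-kmm * step);
    std::fill(SH.begin(), SH.end(), 0.0);
    std::fill(SM.begin(), SM.end(), 0.0);
    std::fill(cell_start.begin(), cell_start.end(), 0);
    for (int i = 0; i < n_cb; ++i) {
      double x = cbx[i] + sig_cb * rng.norm_fast();
      double y = cby[i] + sig_cb * rng.norm_fast();
      double z = cbz[i] + sig_cb * rng.norm_fast();
      reflect(x, Lx); reflect(y, Ly); reflect(z, Lz);
      cbx[i] = x; cby[i] = y; cbz[i] = z;
      int nh = bh[i] - th[i];
      for (int s = 0; s < nh; ++s)
        if (rng.unif() < p_uh) {
          bh[i]--;
          cax.push_back(x); cay.push_back(y); caz.push_back(z);
        }
      int nm = bm[i] - tm[i];
      for (int s = 0; s < nm; ++s)
        if (rng.unif() < p_um) {
          bm[i]--;
          cax.push_back(x); cay.push_back(y); caz.push_back(z);
        }
      int c = g.idx(x, y, z);
      cb_cell[i] = c;
      cell_start[c + 1]++;
    }
    // tagged unbinding (site counts already settled for this step)
    for (int i = 0; i < n_tagged; ++i) {
      if (tstate[i] == 0) continue;
      double p = tstate[i] == 1 ? p_uh : p_um;
      if (rng.unif() < p) {
        int m = tmol[i];
        if (tstate[i] == 1) { bh[m]--; th[m]--; } else { bm[m]--; tm[m]--; }
        tx[i] = cbx[m]; ty[i] = cby[m]; tz[i] = cbz[m];
        tstate[i] = 0; tmol[i] = -1;
      }
    }
    for (int i = 0; i < n_cb; ++i) {
      int c = cb_cell[i];
      SH[c] += sites_h - bh[i];
      SM[c] += sites_m - bm[i];
    }
    for (int c = 0; c < g.ncell(); ++c) cell_start[c + 1] += cell_start[c];
    {
      std::vector<int>& fill = fill_buf;
      fill.assign(cell_start.begin(), cell_start.end());
      for (int i = 0; i < n_cb; ++i) mol_sorted[fill[cb_cell[i]]++] = i;
    }
    std::fill(ca_count.begin(), ca_count.end(), 0);
    for (size_t i = 0; i < cax.size(); ++i)
      ca_count[g.idx(cax[i], cay[i], caz[i])]++;

    // PMCA pumps
    for (int i = 0; i < n_pump; ++i) {
      int c = pump_cell[i];
      switch (pstate[i]) {
        case 0: {
          double conc = ca_count[c] / conv_cell;
          if (conc > 0.0 && rng.unif() < -std::expm1(-kpm1 * conc * step)) {
            // capture: remove one untagged free ion from this cell
            for (size_t q = 0; q < cax.size(); ++q) {
              if (g.idx(cax[q], cay[q], caz[q]) == c) {
                cax[q] = cax.back(); cay[q] = cay.back(); caz[q] = caz.back();
                cax.pop_back(); cay.pop_back(); caz.pop_back();
                ca_count[c]--;
                pstate[i] = 1;
                break;
              }
            }
          }
          break;
        }
        case 1: {
          double R = kpm2 + kpm3;
          if (rng.unif() < -std::expm1(-R * step)) {
            if (rng.unif() * R < kpm2) {
              cax.push_back(px[i]); cay.push_back(py[i]); caz.push_back(pz[i]);
              pstate[i] = 0;
            } else {
              pstate[i] = 2;
              ++extruded;
            }
          }
          break;
        }
        default:
          if (rng.unif() < -std::expm1(-kpm4 * step)) pstate[i] = 0;
      }
      // leak influx, independent of pump state
      if (leak > 0.0 && rng.unif() < -std::expm1(-leak * step)) {
        cax.push_back(px[i]); cay.push_back(py[i]); caz.push_back(pz[i]);
        ++leaked;
      }
    }

    // clamp slabs at both x-ends
    if (clamp_nm > 0.0) {
      for (size_t i = 0; i < cax.size();) {
        if (cax[i] < clamp_nm || cax[i] > Lx - clamp_nm) {
          cax[i] = cax.back(); cay[i] = cay.back(); caz[i] = caz.back();
          cax.pop_back(); cay.pop_back(); caz.pop_back();
          ++clamp_rm;
        } else ++i;
      }
      double slab_conv = clamp_nm * Ly * Lz * IONS_PER_UM3_PER_UM;
      for (int side = 0; side < 2; ++side) {
        int n = rng.poisson(clamp_uM * slab_conv);
        clamp_add += n;
        for (int q = 0; q < n; ++q) {
          double x = rng.unif() * clamp_nm;
          if (side == 1) x = Lx - x;
          cax.push_back(x); cay.push_back(rng.unif() * Ly); caz.push_back(rng.unif() * Lz);
        }
      }
    }

    now += step;

    // probe sampling (counts free ions, tagged included)
    for (int p = 0; p < n_probe; ++p) {
      double X = probes(p, 0), Y = probes(p, 1), Z = probes(p, 2), r2 = probes(p, 3) * probes(p, 3);
      int cnt = 0;
      for (size_t i = 0; i < cax.size(); ++i) {
        double dx = cax[i] - X, dy = cay[i] - Y, dz = caz[i] - Z;
        if (dx * dx + dy * dy + dz * dz <= r2) ++cnt;
      }
      for (int i = 0; i < n_tagged; ++i) {
        if (tstate[i] != 0) continue;
        double dx = tx[i] - X, dy = ty[i] - Y, dz = tz[i] - Z;
        if (dx * dx + dy * dy + dz * dz <= r2) ++cnt;
      }
      probe_acc[p] += cnt;
    }
    ++acc_n;

    if (n_tagged > 0 && now >= next_tag - 1e-12 && tag_row + n_tagged <= tag_out.nrow()) {
      record_tags(now);
      next_tag += tag_dt;
    }

    if (out_i < n_out && now >= (out_i + 1) * out_dt - 1e-12) {
      for (int p = 0; p < n_probe; ++p) {
        probe_out(out_i, p) = (probe_acc[p] / std::max(1, acc_n)) / probe_conv[p];
        probe_acc[p] = 0.0;
      }
      probe_t[out_i] = (out_i + 1) * out_dt;
      bulk_out[out_i] = cax.size() / conv_box;
      acc_n = 0;
      ++out_i;
    }
  }

  long long n_bound = 0;
  for (int i = 0; i < n_cb; ++i) n_bound += bh[i] + bm[i];
  long long pump_held = 0;
  for (int i = 0; i < n_pump; ++i) if (pstate[i] == 1) ++pump_held;

  return List::create(
      _["time_ms"] = probe_t,
      _["probe_uM"] = probe_out,
      _["bulk_uM"] = bulk_out,
      _["tagged"] = tag_out,
      _["n_tag_rows"] = tag_row,
      _["diag"] = List::create(
          _["injected"] = (double)injected, _["extruded"] = (double)extruded,
          _["leaked"] = (double)leaked, _["clamp_added"] = (double)clamp_add,
          _["clamp_removed"] = (double)clamp_rm,
          _["free_ca"] = (double)cax.size(), _["bound_ca"] = (double)n_bound,
          _["init_free"] = (double)init_free, _["init_bound"] = (double)init_bound,
          _["pump_held"] = (double)pump_held,
          _["init_pump_held"] = (double)init_pump_held,
          _["n_calbindin"] = n_cb, _["n_pumps"] = n_pump));
}

// Brownian step helper (used for unit tests of the displacement kernel).
// [[Rcpp::export]]
NumericMatrix cpp_brownian_steps(NumericMatrix pos, double D, double dt,
                                 NumericVector box, double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  double sig = std::sqrt(2.0 * D * dt);
  NumericMatrix out(pos.nrow(), 3);
  for (int i = 0; i < pos.nrow(); ++i)
    for (int j = 0; j < 3; ++j) {
      double x = pos(i, j) + sig * rng.norm();
      if (box[j] > 0) reflect(x, box[j]);
      out(i, j) = x;
    }
  return out;
}
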