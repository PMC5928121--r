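// Langevin engine for the strings-and-binders tracer model: harmonic
// bead-spring bonds plus truncated (unshifted) Lennard-Jones pairs under
// cubic periodic boundary conditions, integrated with either underdamped
// BAOAB or overdamped Euler-Maruyama dynamics.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <string>
#include "rng.h"
using namespace Rcpp;

namespace {

struct Box {
  double L, hL;
  explicit Box(double L_) : L(L_), hL(0.5 * L_) {}
  inline double mi(double d) const {
    if (d > hL) d -= L;
    else if (d < -hL) d += L;
    return d;
  }
  inline double wrap(double x) const {
    x -= L * std::floor(x / L);
    if (x >= L) x = 0.0;  // guard against floating round-up
    return x;
  }
};

struct System {
  int n;
  std::vector<double> px, py, pz;  // wrapped coordinates
  std::vector<int> sp;             // species code 0..3 (p,a,b,t)
  std::vector<char> mob;
  std::vector<int> b1, b2;         // bonds, 0-based
  Box box;
  double rcut, rcut2, kbond, r0;
  double e24[16], e4[16], xi16[16];

  System(double L) : box(L) {}
};

// Verlet pair list built from a linked-cell grid; pairs where both
// particles are frozen carry no information and are dropped.
struct NeighborList {
  std::vector<int> pi, pj, pc;
  std::vector<double> rx, ry, rz;  // coordinates at last build
  double rlist, rlist2, skin;
  long n_rebuilds = 0;

  void init(double rcut, double skin_) {
    skin = skin_;
    rlist = rcut + skin;
    rlist2 = rlist * rlist;
  }

  bool stale(const System& S) const {
    if (rx.empty()) return true;
    const double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < S.n; ++i) {
      const double dx = S.box.mi(S.px[i] - rx[i]);
      const double dy = S.box.mi(S.py[i] - ry[i]);
      const double dz = S.box.mi(S.pz[i] - rz[i]);
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }

  void build(const System& S) {
    ++n_rebuilds;
    pi.clear(); pj.clear(); pc.clear();
    const double L = S.box.L;
    const int m = (int)std::floor(L / rlist);
    if (m < 4) {
      for (int i = 0; i < S.n; ++i)
        for (int j = i + 1; j < S.n; ++j) add_if_close(S, i, j);
    } else {
      const double edge = L / m;
      const int ncell = m * m * m;
      std::vector<int> head(ncell, -1), nxt(S.n, -1);
      for (int i = 0; i < S.n; ++i) {
        int ix = (int)(S.px[i] / edge); if (ix >= m) ix = m - 1;
        int iy = (int)(S.py[i] / edge); if (iy >= m) iy = m - 1;
        int iz = (int)(S.pz[i] / edge); if (iz >= m) iz = m - 1;
        const int c = (ix * m + iy) * m + iz;
        nxt[i] = head[c];
        head[c] = i;
      }
      static const int off[13][3] = {
        {1, 0, 0}, {0, 1, 0}, {0, 0, 1}, {1, 1, 0}, {1, -1, 0}, {1, 0, 1},
        {1, 0, -1}, {0, 1, 1}, {0, 1, -1}, {1, 1, 1}, {1, 1, -1}, {1, -1, 1},
        {1, -1, -1}};
      for (int ix = 0; ix < m; ++ix)
        for (int iy = 0; iy < m; ++iy)
          for (int iz = 0; iz < m; ++iz) {
            const int c = (ix * m + iy) * m + iz;
            for (int i = head[c]; i >= 0; i = nxt[i])
              for (int j = nxt[i]; j >= 0; j = nxt[j]) add_if_close(S, i, j);
            for (int k = 0; k < 13; ++k) {
              const int jx = (ix + off[k][0] + m) % m;
              const int jy = (iy + off[k][1] + m) % m;
              const int jz = (iz + off[k][2] + m) % m;
              const int c2 = (jx * m + jy) * m + jz;
              for (int i = head[c]; i >= 0; i = nxt[i])
                for (int j = head[c2]; j >= 0; j = nxt[j]) add_if_close(S, i, j);
            }
          }
    }
    rx.assign(S.px.begin(), S.px.end());
    ry.assign(S.py.begin(), S.py.end());
    rz.assign(S.pz.begin(), S.pz.end());
  }

 private:
  inline void add_if_close(const System& S, int i, int j) {
    if (!S.mob[i] && !S.mob[j]) return;
    const double dx = S.box.mi(S.px[i] - S.px[j]);
    const double dy = S.box.mi(S.py[i] - S.py[j]);
    const double dz = S.box.mi(S.pz[i] - S.pz[j]);
    if (dx * dx + dy * dy + dz * dz < rlist2) {
      pi.push_back(i);
      pj.push_back(j);
      pc.push_back(S.sp[i] * 4 + S.sp[j]);
    }
  }
};

const double HARD_FLOOR2 = 0.09;  // (0.3 sigma)^2: below this the run aborts

void compute_forces(const System& S, const NeighborList& nl,
                    std::vector<double>& fx, std::vector<double>& fy,
                    std::vector<double>& fz) {
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  const size_t nb = S.b1.size();
  for (size_t b = 0; b < nb; ++b) {
    const int i = S.b1[b], j = S.b2[b];
    const double dx = S.box.mi(S.px[i] - S.px[j]);
    const double dy = S.box.mi(S.py[i] - S.py[j]);
    const double dz = S.box.mi(S.pz[i] - S.pz[j]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) r = 1e-12;
    const double f = -S.kbond * (r - S.r0) / r;
    fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
    fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
  }
  bool bad = false;
  const size_t np = nl.pi.size();
  for (size_t k = 0; k < np; ++k) {
    const int i = nl.pi[k], j = nl.pj[k];
    const double dx = S.box.mi(S.px[i] - S.px[j]);
    const double dy = S.box.mi(S.py[i] - S.py[j]);
    const double dz = S.box.mi(S.pz[i] - S.pz[j]);
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= S.rcut2) continue;
    const int c = nl.pc[k];
    if (r2 < HARD_FLOOR2 && S.e24[c] != 0.0) { bad = true; continue; }
    if (S.e24[c] == 0.0) continue;
    const double sr2 = 1.0 / r2;
    const double sr6 = sr2 * sr2 * sr2;
    const double f = S.e24[c] * sr6 * (2.0 * sr6 - S.xi16[c]) * sr2;
    fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
    fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
  }
  if (bad)
    throw std::runtime_error(
        "unstable configuration: pair distance fell below 0.3 sigma");
}

double chain_rg(const System& S, const std::vector<int>& chain) {
  const size_t K = chain.size();
  if (K < 2) return 0.0;
  // unwrap by walking the chain with minimum-image steps
  std::vector<double> ux(K), uy(K), uz(K);
  ux[0] = S.px[chain[0]]; uy[0] = S.py[chain[0]]; uz[0] = S.pz[chain[0]];
  for (size_t k = 1; k < K; ++k) {
    ux[k] = ux[k - 1] + S.box.mi(S.px[chain[k]] - S.px[chain[k - 1]]);
    uy[k] = uy[k - 1] + S.box.mi(S.py[chain[k]] - S.py[chain[k - 1]]);
    uz[k] = uz[k - 1] + S.box.mi(S.pz[chain[k]] - S.pz[chain[k - 1]]);
  }
  double mx = 0, my = 0, mz = 0;
  for (size_t k = 0; k < K; ++k) { mx += ux[k]; my += uy[k]; mz += uz[k]; }
  mx /= K; my /= K; mz /= K;
  double s2 = 0;
  for (size_t k = 0; k < K; ++k) {
    const double dx = ux[k] - mx, dy = uy[k] - my, dz = uz[k] - mz;
    s2 += dx * dx + dy * dy + dz * dz;
  }
  return std::sqrt(s2 / K);
}

System make_system(const NumericMatrix& pos, const IntegerVector& species,
                   const IntegerMatrix& bonds, const NumericMatrix& eps,
                   const NumericMatrix& xi, double L, double rcut,
                   double kbond, double r0, const LogicalVector& mobile) {
  System S(L);
  S.n = pos.nrow();
  S.px.resize(S.n); S.py.resize(S.n); S.pz.resize(S.n);
  S.sp.resize(S.n); S.mob.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    S.px[i] = S.box.wrap(pos(i, 0));
    S.py[i] = S.box.wrap(pos(i, 1));
    S.pz[i] = S.box.wrap(pos(i, 2));
    S.sp[i] = species[i];
    if (S.sp[i] < 0 || S.sp[i] > 3) stop("species code out of range 0..3");
    S.mob[i] = mobile.size() ? (char)mobile[i] : 1;
  }
  for (int b = 0; b < bonds.nrow(); ++b) {
    S.b1.push_back(bonds(b, 0));
    S.b2.push_back(bonds(b, 1));
    if (bonds(b, 0) < 0 || bonds(b, 0) >= S.n || bonds(b, 1) < 0 ||
        bonds(b, 1) >= S.n)
      stop("bond index out of range");
  }
  S.rcut = rcut;
  S.rcut2 = rcut * rcut;
  S.kbond = kbond;
  S.r0 = r0;
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) {
      S.e4[a * 4 + b] = 4.0 * eps(a, b);
      S.e24[a * 4 + b] = 24.0 * eps(a, b);
      S.xi16[a * 4 + b] = xi(a, b);
    }
  return S;
}

inline void cap_force(std::vector<double>& fx, std::vector<double>& fy,
                      std::vector<double>& fz, int i, double cap) {
  const double f2 = fx[i] * fx[i] + fy[i] * fy[i] + fz[i] * fz[i];
  if (f2 > cap * cap) {
    const double s = cap / std::sqrt(f2);
    fx[i] *= s; fy[i] *= s; fz[i] *= s;
  }
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".run_engine_cpp")]]
List run_engine_cpp(NumericMatrix pos, IntegerVector species,
                    IntegerMatrix bonds, NumericMatrix eps, NumericMatrix xi,
                    double L, double rcut, double kbond, double r0, double dt,
                    double gamma, double kT, double n_total, double n_equil,
                    double sample_every, LogicalVector mobile, double skin,
                    double seed, std::string scheme, double force_cap,
                    double drift_cap, IntegerVector chain_idx,
                    int diag_every) {
  if (dt <= 0) stop("dt must be positive");
  if (L <= 0) stop("box edge must be positive");
  const long long NT = (long long)n_total;
  const long long NE = (long long)n_equil;
  const long long SE = (long long)sample_every;
  if (NT < NE || SE <= 0) stop("invalid step counts");
  const bool baoab = (scheme == "baoab");
  if (!baoab && scheme != "brownian") stop("unknown integration scheme");
  if (baoab && gamma < 0) stop("gamma must be >= 0 for baoab");
  if (!baoab && gamma <= 0) stop("gamma must be > 0 for brownian");

  System S = make_system(pos, species, bonds, eps, xi, L, rcut, kbond, r0,
                         mobile);
  NeighborList nl;
  nl.init(rcut, skin);

  std::vector<int> chain(chain_idx.begin(), chain_idx.end());
  for (size_t k = 0; k < chain.size(); ++k) chain[k] -= 1;  // to 0-based

  Xoshiro rng((uint64_t)seed);
  const int n = S.n;
  std::vector<double> fx(n), fy(n), fz(n);
  std::vector<double> vx, vy, vz;
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(kT * (1.0 - c1 * c1));
  const double bstep = dt / gamma;                 // brownian drift factor
  const double bnoise = std::sqrt(2.0 * kT * dt / gamma);
  if (baoab) {
    vx.assign(n, 0.0); vy.assign(n, 0.0); vz.assign(n, 0.0);
    const double sv = std::sqrt(kT);
    for (int i = 0; i < n; ++i)
      if (S.mob[i]) {
        vx[i] = sv * rng.norm();
        vy[i] = sv * rng.norm();
        vz[i] = sv * rng.norm();
      }
  }

  const long long n_snap = (NT - NE) / SE;
  NumericVector snaps((R_xlen_t)n * 3 * n_snap);
  IntegerVector snap_steps((R_xlen_t)n_snap);

  std::vector<double> diag_rg, diag_temp;
  std::vector<double> diag_step;

  nl.build(S);
  compute_forces(S, nl, fx, fy, fz);

  long long isnap = 0;
  for (long long step = 1; step <= NT; ++step) {
    if (baoab) {
      for (int i = 0; i < n; ++i) {
        if (!S.mob[i]) continue;
        if (force_cap > 0) cap_force(fx, fy, fz, i, force_cap);
        vx[i] += 0.5 * dt * fx[i];
        vy[i] += 0.5 * dt * fy[i];
        vz[i] += 0.5 * dt * fz[i];
        S.px[i] = S.box.wrap(S.px[i] + 0.5 * dt * vx[i]);
        S.py[i] = S.box.wrap(S.py[i] + 0.5 * dt * vy[i]);
        S.pz[i] = S.box.wrap(S.pz[i] + 0.5 * dt * vz[i]);
        if (gamma > 0) {
          vx[i] = c1 * vx[i] + c2 * rng.norm();
          vy[i] = c1 * vy[i] + c2 * rng.norm();
          vz[i] = c1 * vz[i] + c2 * rng.norm();
        }
        S.px[i] = S.box.wrap(S.px[i] + 0.5 * dt * vx[i]);
        S.py[i] = S.box.wrap(S.py[i] + 0.5 * dt * vy[i]);
        S.pz[i] = S.box.wrap(S.pz[i] + 0.5 * dt * vz[i]);
      }
      if (nl.stale(S)) nl.build(S);
      compute_forces(S, nl, fx, fy, fz);
      for (int i = 0; i < n; ++i) {
        if (!S.mob[i]) continue;
        if (force_cap > 0) cap_force(fx, fy, fz, i, force_cap);
        vx[i] += 0.5 * dt * fx[i];
        vy[i] += 0.5 * dt * fy[i];
        vz[i] += 0.5 * dt * fz[i];
      }
    } else {
      if (nl.stale(S)) nl.build(S);
      compute_forces(S, nl, fx, fy, fz);
      for (int i = 0; i < n; ++i) {
        if (!S.mob[i]) continue;
        if (force_cap > 0) cap_force(fx, fy, fz, i, force_cap);
        double ddx = bstep * fx[i], ddy = bstep * fy[i], ddz = bstep * fz[i];
        if (drift_cap > 0) {
          const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
          if (d2 > drift_cap * drift_cap) {
            const double s = drift_cap / std::sqrt(d2);
            ddx *= s; ddy *= s; ddz *= s;
          }
        }
        S.px[i] = S.box.wrap(S.px[i] + ddx + bnoise * rng.norm());
        S.py[i] = S.box.wrap(S.py[i] + ddy + bnoise * rng.norm());
        S.pz[i] = S.box.wrap(S.pz[i] + ddz + bnoise * rng.norm());
      }
    }

    if (diag_every > 0 && step % diag_every == 0) {
      diag_step.push_back((double)step);
      diag_rg.push_back(chain.empty() ? NA_REAL : chain_rg(S, chain));
      if (baoab) {
        double ke = 0;
        long nm = 0;
        for (int i = 0; i < n; ++i)
          if (S.mob[i]) {
            ke += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
            ++nm;
          }
        diag_temp.push_back(nm ? ke / (3.0 * nm) : NA_REAL);
      } else {
        diag_temp.push_back(NA_REAL);
      }
      for (int i = 0; i < n; ++i)
        if (!R_finite(S.px[i]) || !R_finite(S.py[i]) || !R_finite(S.pz[i]))
          stop("non-finite coordinate at step %lld", step);
    }

    if (step > NE && (step - NE) % SE == 0 && isnap < n_snap) {
      const R_xlen_t base = (R_xlen_t)isnap * n * 3;
      for (int i = 0; i < n; ++i) {
        snaps[base + i] = S.px[i];
        snaps[base + n + i] = S.py[i];
        snaps[base + 2 * n + i] = S.pz[i];
      }
      snap_steps[isnap] = (int)step;
      ++isnap;
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  snaps.attr("dim") = IntegerVector::create(n, 3, (int)n_snap);
  NumericMatrix final_pos(n, 3);
  for (int i = 0; i < n; ++i) {
    final_pos(i, 0) = S.px[i];
    final_pos(i, 1) = S.py[i];
    final_pos(i, 2) = S.pz[i];
  }
  NumericMatrix final_vel(baoab ? n : 0, 3);
  if (baoab) {
    for (int i = 0; i < n; ++i) {
      final_vel(i, 0) = vx[i];
      final_vel(i, 1) = vy[i];
      final_vel(i, 2) = vz[i];
    }
  }
  return List::create(
      _["snapshots"] = snaps, _["snapshot_steps"] = snap_steps,
      _["final_positions"] = final_pos,
      _["final_velocities"] = final_vel,
      _["diagnostics"] = List::create(_["step"] = wrap(diag_step),
                                      _["r_gyr"] = wrap(diag_rg),
                                      _["kinetic_temp"] = wrap(diag_temp)),
      _["n_rebuilds"] = (double)nl.n_rebuilds);
}

//' @noRd
// [[Rcpp::export(name = ".forces_cpp")]]
NumericMatrix forces_cpp(NumericMatrix pos, IntegerVector species,
                         IntegerMatrix bonds, NumericMatrix eps,
                         NumericMatrix xi, double L, double rcut, double kbond,
                         double r0) {
  LogicalVector mob(pos.nrow(), true);
  System S = make_system(pos, species, bonds, eps, xi, L, rcut, kbond, r0, mob);
  NeighborList nl;
  nl.init(rcut, 0.0);
  nl.build(S);
  std::vector<double> fx(S.n), fy(S.n), fz(S.n);
  compute_forces(S, nl, fx, fy, fz);
  NumericMatrix out(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    out(i, 0) = fx[i];
    out(i, 1) = fy[i];
    out(i, 2) = fz[i];
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".energy_cpp")]]
double energy_cpp(NumericMatrix pos, IntegerVector species,
                  IntegerMatrix bonds, NumericMatrix eps, NumericMatrix xi,
                  double L, double rcut, double kbond, double r0) {
  LogicalVector mob(pos.nrow(), true);
  System S = make_system(pos, species, bonds, eps, xi, L, rcut, kbond, r0, mob);
  double e = 0.0;
  for (size_t b = 0; b < S.b1.size(); ++b) {
    const int i = S.b1[b], j = S.b2[b];
    const double dx = S.box.mi(S.px[i] - S.px[j]);
    const double dy = S.box.mi(S.py[i] - S.py[j]);
    const double dz = S.box.mi(S.pz[i] - S.pz[j]);
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    e += 0.5 * S.kbond * (r - S.r0) * (r - S.r0);
  }
  for (int i = 0; i < S.n; ++i)
    for (int j = i + 1; j < S.n; ++j) {
      const double dx = S.box.mi(S.px[i] - S.px[j]);
      const double dy = S.box.mi(S.py[i] - S.py[j]);
      const double dz = S.box.mi(S.pz[i] - S.pz[j]);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= S.rcut2) continue;
      if (r2 <= 0) stop("coincident particles");
      const int c = S.sp[i] * 4 + S.sp[j];
      const double sr2 = 1.0 / r2;
      const double sr6 = sr2 * sr2 * sr2;
      e += S.e4[c] * sr6 * (sr6 - S.xi16[c]);
    }
  return e;
}

//' @noRd
// [[Rcpp::export(name = ".neighbor_pairs_cpp")]]
IntegerMatrix neighbor_pairs_cpp(NumericMatrix pos, double L, double rlist) {
  IntegerVector species(pos.nrow(), 0);
  LogicalVector mob(pos.nrow(), true);
  IntegerMatrix bonds(0, 2);
  NumericMatrix eps(4, 4), xi(4, 4);
  System S = make_system(pos, species, bonds, eps, xi, L, rlist, 0.0, 0.0, mob);
  NeighborList nl;
  nl.init(rlist, 0.0);
  nl.build(S);
  const int np = (int)nl.pi.size();
  IntegerMatrix out(np, 2);
  for (int k = 0; k < np; ++k) {
    out(k, 0) = nl.pi[k] + 1;
    out(k, 1) = nl.pj[k] + 1;
  }
  return out;
}
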