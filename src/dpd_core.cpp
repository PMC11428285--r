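// Core DPD kernels: cell-list pair forces (conservative + dissipative +
// random), harmonic bonds, quadratic wall repulsion, tethers, and the
// Groot-Warren modified velocity-Verlet integrator (lambda = 0.5).
//
// Reduced units throughout: r_c = 1, k_B T = 1, m = 1.  All pair forces are
// applied antisymmetrically with a single random variate shared per pair, so
// total momentum is conserved to round-off in fully periodic systems.

#include <Rcpp.h>
#include <cmath>
#include <functional>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Params {
  double gamma;   // friction
  double sigma;   // noise amplitude, sigma^2 = 2 gamma kT
  double dt;
  double kappa;   // bond spring constant
  double req;     // bond equilibrium length
  double awall;   // wall repulsion magnitude
  double zc;      // wall repulsion range
  bool walled_x;  // x bounded by repulsive walls instead of periodic images
};

struct Forces {
  std::vector<double> fx, fy, fz;            // total
  std::vector<double> cx_, cy_, cz_;         // conservative (breakdown only)
  std::vector<double> dx_, dy_, dz_;         // dissipative
  std::vector<double> rx_, ry_, rz_;         // random
  std::vector<double> bx_, by_, bz_;         // bond
  std::vector<double> wx_, wy_, wz_;         // wall (+ tether)
  bool keep_parts;
  double virial_c;                            // sum r_ij . F^C_ij over pairs
  int wall_clamped;                           // beads found beyond a wall
  void init(int n, bool parts) {
    keep_parts = parts;
    fx.assign(n, 0.0); fy.assign(n, 0.0); fz.assign(n, 0.0);
    if (parts) {
      cx_.assign(n, 0.0); cy_.assign(n, 0.0); cz_.assign(n, 0.0);
      dx_.assign(n, 0.0); dy_.assign(n, 0.0); dz_.assign(n, 0.0);
      rx_.assign(n, 0.0); ry_.assign(n, 0.0); rz_.assign(n, 0.0);
      bx_.assign(n, 0.0); by_.assign(n, 0.0); bz_.assign(n, 0.0);
      wx_.assign(n, 0.0); wy_.assign(n, 0.0); wz_.assign(n, 0.0);
    }
    virial_c = 0.0;
    wall_clamped = 0;
  }
};

class DpdSystem {
public:
  int n;
  std::vector<double> x, y, z, vx, vy, vz;
  std::vector<int> species;   // 0-based
  std::vector<int> frozen;    // 0/1
  int nspec;
  std::vector<double> A;      // nspec x nspec repulsion, row-major
  std::vector<int> b1, b2;    // bonds, 0-based
  double Lx, Ly, Lz;
  Params p;
  // tethers: bead index -> anchor
  std::vector<int> t_idx;
  std::vector<double> t_ax, t_ay, t_az;
  double t_k;

  std::mt19937_64 rng;
  std::normal_distribution<double> gauss;

  // cell list storage
  int ncx, ncy, ncz;
  std::vector<int> head, nxt;
  bool cells_ok;

  DpdSystem() : gauss(0.0, 1.0) {}

  inline double mi(double d, double L, bool periodic) const {
    if (!periodic) return d;
    if (d > 0.5 * L) d -= L;
    else if (d < -0.5 * L) d += L;
    return d;
  }

  void build_cells() {
    ncx = std::max(1, (int)std::floor(Lx));
    ncy = std::max(1, (int)std::floor(Ly));
    ncz = std::max(1, (int)std::floor(Lz));
    // with < 3 cells along a periodic axis the half-stencil double counts
    bool okx = p.walled_x ? (ncx >= 1) : (ncx >= 3);
    cells_ok = okx && ncy >= 3 && ncz >= 3;
    if (!cells_ok) return;
    double lcx = Lx / ncx, lcy = Ly / ncy, lcz = Lz / ncz;
    head.assign((size_t)ncx * ncy * ncz, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int cx = std::min(ncx - 1, std::max(0, (int)std::floor(x[i] / lcx)));
      int cy = std::min(ncy - 1, std::max(0, (int)std::floor(y[i] / lcy)));
      int cz = std::min(ncz - 1, std::max(0, (int)std::floor(z[i] / lcz)));
      int c = (cx * ncy + cy) * ncz + cz;
      nxt[i] = head[c];
      head[c] = i;
    }
  }

  inline void pair_kernel(int i, int j, Forces& F,
                          const std::vector<double>& wx,
                          const std::vector<double>& wy,
                          const std::vector<double>& wz) {
    double dx = mi(x[i] - x[j], Lx, !p.walled_x);
    double dy = mi(y[i] - y[j], Ly, true);
    double dz = mi(z[i] - z[j], Lz, true);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= 1.0) return;
    double Aij = A[species[i] * nspec + species[j]];
    double r = std::sqrt(r2);
    double ex, ey, ez;
    if (r < 1e-12) {
      // exactly overlapping soft beads: push apart along a random direction
      double gx = gauss(rng), gy = gauss(rng), gz = gauss(rng);
      double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
      if (gn < 1e-12) { gx = 1.0; gy = 0.0; gz = 0.0; gn = 1.0; }
      ex = gx / gn; ey = gy / gn; ez = gz / gn;
      double fc = Aij;  // w_C(0) = 1
      F.fx[i] += fc * ex; F.fy[i] += fc * ey; F.fz[i] += fc * ez;
      F.fx[j] -= fc * ex; F.fy[j] -= fc * ey; F.fz[j] -= fc * ez;
      if (F.keep_parts) {
        F.cx_[i] += fc * ex; F.cy_[i] += fc * ey; F.cz_[i] += fc * ez;
        F.cx_[j] -= fc * ex; F.cy_[j] -= fc * ey; F.cz_[j] -= fc * ez;
      }
      return;
    }
    ex = dx / r; ey = dy / r; ez = dz / r;
    double wC = 1.0 - r;              // conservative weight
    double wR = 1.0 - r;              // random weight
    double wD = wR * wR;              // dissipative weight = wR^2
    double fc = Aij * wC;
    double dvx = wx[i] - wx[j], dvy = wy[i] - wy[j], dvz = wz[i] - wz[j];
    double edv = ex * dvx + ey * dvy + ez * dvz;
    double fd = (p.gamma > 0.0) ? -p.gamma * wD * edv : 0.0;
    double fr = 0.0;
    if (p.sigma > 0.0) {
      double zeta = gauss(rng);       // one shared draw per pair per step
      fr = p.sigma * wR * zeta / std::sqrt(p.dt);
    }
    double ft = fc + fd + fr;
    F.fx[i] += ft * ex; F.fy[i] += ft * ey; F.fz[i] += ft * ez;
    F.fx[j] -= ft * ex; F.fy[j] -= ft * ey; F.fz[j] -= ft * ez;
    F.virial_c += r * fc;             // r_ij . F^C_ij = r * A w_C
    if (F.keep_parts) {
      F.cx_[i] += fc * ex; F.cy_[i] += fc * ey; F.cz_[i] += fc * ez;
      F.cx_[j] -= fc * ex; F.cy_[j] -= fc * ey; F.cz_[j] -= fc * ez;
      F.dx_[i] += fd * ex; F.dy_[i] += fd * ey; F.dz_[i] += fd * ez;
      F.dx_[j] -= fd * ex; F.dy_[j] -= fd * ey; F.dz_[j] -= fd * ez;
      F.rx_[i] += fr * ex; F.ry_[i] += fr * ey; F.rz_[i] += fr * ez;
      F.rx_[j] -= fr * ex; F.ry_[j] -= fr * ey; F.rz_[j] -= fr * ez;
    }
  }

  // pair forces using velocities (wx, wy, wz) -- may be the half-step
  // predicted velocities of the modified velocity-Verlet scheme
  void pair_forces(Forces& F, const std::vector<double>& wx,
                   const std::vector<double>& wy,
                   const std::vector<double>& wz) {
    build_cells();
    if (!cells_ok) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) pair_kernel(i, j, F, wx, wy, wz);
      return;
    }
    // half stencil: self cell + 13 neighbours
    static const int off[13][3] = {
        {1, 0, 0},  {0, 1, 0},  {0, 0, 1},  {1, 1, 0},  {1, -1, 0},
        {1, 0, 1},  {1, 0, -1}, {0, 1, 1},  {0, 1, -1}, {1, 1, 1},
        {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};
    for (int cx = 0; cx < ncx; ++cx) {
      for (int cy = 0; cy < ncy; ++cy) {
        for (int cz = 0; cz < ncz; ++cz) {
          int c = (cx * ncy + cy) * ncz + cz;
          // pairs within the cell
          for (int i = head[c]; i >= 0; i = nxt[i])
            for (int j = nxt[i]; j >= 0; j = nxt[j])
              pair_kernel(i, j, F, wx, wy, wz);
          // pairs with half neighbours
          for (int k = 0; k < 13; ++k) {
            int axp = cx + off[k][0];
            if (p.walled_x && (axp < 0 || axp >= ncx)) continue;
            int ax = (axp % ncx + ncx) % ncx;
            int ay = ((cy + off[k][1]) % ncy + ncy) % ncy;
            int az = ((cz + off[k][2]) % ncz + ncz) % ncz;
            int c2 = (ax * ncy + ay) * ncz + az;
            for (int i = head[c]; i >= 0; i = nxt[i])
              for (int j = head[c2]; j >= 0; j = nxt[j])
                pair_kernel(i, j, F, wx, wy, wz);
          }
        }
      }
    }
  }

  void bond_forces(Forces& F) {
    double half_min = 0.5 * std::min(Lx, std::min(Ly, Lz));
    for (size_t k = 0; k < b1.size(); ++k) {
      int i = b1[k], j = b2[k];
      double dx = mi(x[i] - x[j], Lx, !p.walled_x);
      double dy = mi(y[i] - y[j], Ly, true);
      double dz = mi(z[i] - z[j], Lz, true);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r > half_min)
        stop("bond %d-%d stretched to %.3f, beyond half the smallest box "
             "edge (minimum-image ambiguity)", i + 1, j + 1, r);
      if (r < 1e-12) continue;  // force direction undefined, magnitude 0 anyway
      // F = -kappa (r - r_eq) rhat  restores r_eq
      double fm = -p.kappa * (r - p.req);
      double ex = dx / r, ey = dy / r, ez = dz / r;
      F.fx[i] += fm * ex; F.fy[i] += fm * ey; F.fz[i] += fm * ez;
      F.fx[j] -= fm * ex; F.fy[j] -= fm * ey; F.fz[j] -= fm * ez;
      if (F.keep_parts) {
        F.bx_[i] += fm * ex; F.by_[i] += fm * ey; F.bz_[i] += fm * ez;
        F.bx_[j] -= fm * ex; F.by_[j] -= fm * ey; F.bz_[j] -= fm * ez;
      }
    }
  }

  void wall_forces(Forces& F) {
    if (!p.walled_x || p.awall <= 0.0) return;
    double fmax = 2.0 * p.awall / p.zc;
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      double fxi = 0.0;
      double zlo = x[i];          // distance to lower wall plane (x = 0)
      double zhi = Lx - x[i];     // distance to upper wall plane
      if (zlo < p.zc) {
        double f = (zlo <= 0.0) ? fmax : fmax * (1.0 - zlo / p.zc);
        if (zlo <= 0.0) F.wall_clamped++;
        fxi += f;                 // push inward (+x)
      }
      if (zhi < p.zc) {
        double f = (zhi <= 0.0) ? fmax : fmax * (1.0 - zhi / p.zc);
        if (zhi <= 0.0) F.wall_clamped++;
        fxi -= f;                 // push inward (-x)
      }
      if (fxi != 0.0) {
        F.fx[i] += fxi;
        if (F.keep_parts) F.wx_[i] += fxi;
      }
    }
  }

  void tether_forces(Forces& F) {
    for (size_t k = 0; k < t_idx.size(); ++k) {
      int i = t_idx[k];
      double dx = mi(x[i] - t_ax[k], Lx, !p.walled_x);
      double dy = mi(y[i] - t_ay[k], Ly, true);
      double dz = mi(z[i] - t_az[k], Lz, true);
      F.fx[i] -= t_k * dx; F.fy[i] -= t_k * dy; F.fz[i] -= t_k * dz;
      if (F.keep_parts) {
        F.wx_[i] -= t_k * dx; F.wy_[i] -= t_k * dy; F.wz_[i] -= t_k * dz;
      }
    }
  }

  void all_forces(Forces& F, const std::vector<double>& wx,
                  const std::vector<double>& wy,
                  const std::vector<double>& wz, bool parts) {
    F.init(n, parts);
    pair_forces(F, wx, wy, wz);
    bond_forces(F);
    wall_forces(F);
    tether_forces(F);
    // frozen beads are not integrated; zero their net force for bookkeeping
    for (int i = 0; i < n; ++i)
      if (frozen[i]) { F.fx[i] = 0.0; F.fy[i] = 0.0; F.fz[i] = 0.0; }
  }

  inline void wrap(int i) {
    if (!p.walled_x) {
      x[i] -= Lx * std::floor(x[i] / Lx);
      if (x[i] >= Lx) x[i] = 0.0;
    }
    y[i] -= Ly * std::floor(y[i] / Ly);
    if (y[i] >= Ly) y[i] = 0.0;
    z[i] -= Lz * std::floor(z[i] / Lz);
    if (z[i] >= Lz) z[i] = 0.0;
  }
};

void fill_system(DpdSystem& S, const NumericMatrix& pos,
                 const NumericMatrix& vel, const IntegerVector& species,
                 const IntegerVector& frozen, const NumericMatrix& Amat,
                 const IntegerMatrix& bonds, const NumericVector& box,
                 const List& par) {
  int n = pos.nrow();
  S.n = n;
  S.x.resize(n); S.y.resize(n); S.z.resize(n);
  S.vx.resize(n); S.vy.resize(n); S.vz.resize(n);
  S.species.resize(n); S.frozen.resize(n);
  for (int i = 0; i < n; ++i) {
    S.x[i] = pos(i, 0); S.y[i] = pos(i, 1); S.z[i] = pos(i, 2);
    S.vx[i] = vel(i, 0); S.vy[i] = vel(i, 1); S.vz[i] = vel(i, 2);
    S.species[i] = species[i] - 1;
    S.frozen[i] = frozen[i];
  }
  S.nspec = Amat.nrow();
  S.A.resize((size_t)S.nspec * S.nspec);
  for (int a = 0; a < S.nspec; ++a)
    for (int b = 0; b < S.nspec; ++b) S.A[a * S.nspec + b] = Amat(a, b);
  int m = bonds.nrow();
  S.b1.resize(m); S.b2.resize(m);
  for (int k = 0; k < m; ++k) { S.b1[k] = bonds(k, 0) - 1; S.b2[k] = bonds(k, 1) - 1; }
  S.Lx = box[0]; S.Ly = box[1]; S.Lz = box[2];
  S.p.gamma = as<double>(par["gamma"]);
  S.p.sigma = as<double>(par["sigma"]);
  S.p.dt = as<double>(par["dt"]);
  S.p.kappa = as<double>(par["kappa"]);
  S.p.req = as<double>(par["req"]);
  S.p.awall = as<double>(par["awall"]);
  S.p.zc = as<double>(par["zc"]);
  S.p.walled_x = as<bool>(par["walled_x"]);
  S.t_k = 0.0;
}

NumericMatrix pack3(const std::vector<double>& a, const std::vector<double>& b,
                    const std::vector<double>& c) {
  int n = a.size();
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i) { m(i, 0) = a[i]; m(i, 1) = b[i]; m(i, 2) = c[i]; }
  return m;
}

} // namespace

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                IntegerVector frozen, NumericMatrix Amat, IntegerMatrix bonds,
                NumericVector box, List par, int seed) {
  DpdSystem S;
  fill_system(S, pos, vel, species, frozen, Amat, bonds, box, par);
  S.rng.seed((uint64_t)seed);
  Forces F;
  S.all_forces(F, S.vx, S.vy, S.vz, true);
  return List::create(
      _["total"] = pack3(F.fx, F.fy, F.fz),
      _["conservative"] = pack3(F.cx_, F.cy_, F.cz_),
      _["dissipative"] = pack3(F.dx_, F.dy_, F.dz_),
      _["random"] = pack3(F.rx_, F.ry_, F.rz_),
      _["bond"] = pack3(F.bx_, F.by_, F.bz_),
      _["wall"] = pack3(F.wx_, F.wy_, F.wz_),
      _["virial_conservative"] = F.virial_c,
      _["wall_clamped"] = F.wall_clamped);
}

// [[Rcpp::export]]
List cpp_run_dpd(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                 IntegerVector frozen, NumericMatrix Amat, IntegerMatrix bonds,
                 NumericVector box, List par, int nsteps, int stride, int seed,
                 IntegerVector tether_idx, NumericMatrix tether_anchor,
                 double tether_k) {
  DpdSystem S;
  fill_system(S, pos, vel, species, frozen, Amat, bonds, box, par);
  S.rng.seed((uint64_t)seed);
  int nt = tether_idx.size();
  S.t_idx.resize(nt); S.t_ax.resize(nt); S.t_ay.resize(nt); S.t_az.resize(nt);
  for (int k = 0; k < nt; ++k) {
    S.t_idx[k] = tether_idx[k] - 1;
    S.t_ax[k] = tether_anchor(k, 0);
    S.t_ay[k] = tether_anchor(k, 1);
    S.t_az[k] = tether_anchor(k, 2);
  }
  S.t_k = tether_k;

  const double dt = S.p.dt, lambda = 0.5;
  int n = S.n;
  int nfree = 0;
  for (int i = 0; i < n; ++i) if (!S.frozen[i]) nfree++;

  int nsnap = (stride > 0) ? nsteps / stride + 1 : 1;
  List snap_pos(nsnap), snap_vel(nsnap);
  IntegerVector snap_step(nsnap);
  int isnap = 0;
  snap_pos[isnap] = pack3(S.x, S.y, S.z);
  snap_vel[isnap] = pack3(S.vx, S.vy, S.vz);
  snap_step[isnap] = 0;
  isnap++;

  NumericVector temp_series(nsteps), virial_series(nsteps);
  NumericMatrix mom_series(nsteps, 3);

  Forces F;
  std::vector<double> px(n), py(n), pz(n);  // predicted velocities
  S.all_forces(F, S.vx, S.vy, S.vz, false);
  std::vector<double> fx = F.fx, fy = F.fy, fz = F.fz;
  int wall_clamped_total = 0;

  for (int step = 1; step <= nsteps; ++step) {
    double max_d2 = 0.0;
    for (int i = 0; i < n; ++i) {
      if (S.frozen[i]) { px[i] = 0.0; py[i] = 0.0; pz[i] = 0.0; continue; }
      double ddx = dt * S.vx[i] + 0.5 * dt * dt * fx[i];
      double ddy = dt * S.vy[i] + 0.5 * dt * dt * fy[i];
      double ddz = dt * S.vz[i] + 0.5 * dt * dt * fz[i];
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 > max_d2) max_d2 = d2;
      S.x[i] += ddx; S.y[i] += ddy; S.z[i] += ddz;
      S.wrap(i);
      px[i] = S.vx[i] + lambda * dt * fx[i];
      py[i] = S.vy[i] + lambda * dt * fy[i];
      pz[i] = S.vz[i] + lambda * dt * fz[i];
    }
    if (max_d2 > 1.0)
      stop("integration unstable at step %d: displacement %.3f > r_c",
           step, std::sqrt(max_d2));
    S.all_forces(F, px, py, pz, false);
    wall_clamped_total += F.wall_clamped;
    double ke = 0.0, mx = 0.0, my = 0.0, mz = 0.0;
    for (int i = 0; i < n; ++i) {
      if (S.frozen[i]) continue;
      S.vx[i] += 0.5 * dt * (fx[i] + F.fx[i]);
      S.vy[i] += 0.5 * dt * (fy[i] + F.fy[i]);
      S.vz[i] += 0.5 * dt * (fz[i] + F.fz[i]);
      ke += S.vx[i] * S.vx[i] + S.vy[i] * S.vy[i] + S.vz[i] * S.vz[i];
      mx += S.vx[i]; my += S.vy[i]; mz += S.vz[i];
    }
    fx = F.fx; fy = F.fy; fz = F.fz;
    if (std::isnan(ke))
      stop("NaN encountered at step %d; simulation aborted", step);
    temp_series[step - 1] = (nfree > 0) ? ke / (3.0 * nfree) : 0.0;
    virial_series[step - 1] = F.virial_c;
    mom_series(step - 1, 0) = mx;
    mom_series(step - 1, 1) = my;
    mom_series(step - 1, 2) = mz;
    if (stride > 0 && step % stride == 0) {
      snap_pos[isnap] = pack3(S.x, S.y, S.z);
      snap_vel[isnap] = pack3(S.vx, S.vy, S.vz);
      snap_step[isnap] = step;
      isnap++;
    }
  }

  return List::create(
      _["positions"] = pack3(S.x, S.y, S.z),
      _["velocities"] = pack3(S.vx, S.vy, S.vz),
      _["snap_pos"] = snap_pos, _["snap_vel"] = snap_vel,
      _["snap_step"] = snap_step,
      _["temperature"] = temp_series,
      _["virial_conservative"] = virial_series,
      _["momentum"] = mom_series,
      _["wall_clamped"] = wall_clamped_total);
}

// Single-linkage clustering of chains by hydrophobic-bead proximity.
// Positions are the hydrophobic beads only; chain_id maps each bead to its
// chain (1-based, contiguous).  Returns a cluster label per chain (1-based).
// [[Rcpp::export]]
IntegerVector cpp_link_chains(NumericMatrix pos, IntegerVector chain_id,
                              int nchain, NumericVector box,
                              LogicalVector periodic, double cutoff) {
  int n = pos.nrow();
  double L[3] = {box[0], box[1], box[2]};
  bool per[3] = {(bool)periodic[0], (bool)periodic[1], (bool)periodic[2]};
  // union-find over chains
  std::vector<int> parent(nchain);
  for (int i = 0; i < nchain; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  double c2 = cutoff * cutoff;
  // cell binning on the beads
  int nc[3];
  for (int d = 0; d < 3; ++d) nc[d] = std::max(1, (int)std::floor(L[d] / cutoff));
  bool brute = false;
  for (int d = 0; d < 3; ++d) if (per[d] && nc[d] < 3) brute = true;
  if (brute) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (chain_id[i] == chain_id[j]) continue;
        double dd = 0.0;
        double del[3] = {pos(i, 0) - pos(j, 0), pos(i, 1) - pos(j, 1),
                         pos(i, 2) - pos(j, 2)};
        for (int d = 0; d < 3; ++d) {
          if (per[d]) {
            if (del[d] > 0.5 * L[d]) del[d] -= L[d];
            else if (del[d] < -0.5 * L[d]) del[d] += L[d];
          }
          dd += del[d] * del[d];
        }
        if (dd <= c2) unite(chain_id[i] - 1, chain_id[j] - 1);
      }
  } else {
    std::vector<int> head((size_t)nc[0] * nc[1] * nc[2], -1), nxt(n, -1);
    auto cell_of = [&](int i) {
      int c[3];
      for (int d = 0; d < 3; ++d) {
        double v = pos(i, d);
        int k = (int)std::floor(v / (L[d] / nc[d]));
        c[d] = std::min(nc[d] - 1, std::max(0, k));
      }
      return (c[0] * nc[1] + c[1]) * nc[2] + c[2];
    };
    for (int i = 0; i < n; ++i) { int c = cell_of(i); nxt[i] = head[c]; head[c] = i; }
    for (int cx = 0; cx < nc[0]; ++cx)
      for (int cy = 0; cy < nc[1]; ++cy)
        for (int cz = 0; cz < nc[2]; ++cz) {
          int c = (cx * nc[1] + cy) * nc[2] + cz;
          for (int ox = -1; ox <= 1; ++ox)
            for (int oy = -1; oy <= 1; ++oy)
              for (int oz = -1; oz <= 1; ++oz) {
                int ax = cx + ox, ay = cy + oy, az = cz + oz;
                if (per[0]) ax = (ax % nc[0] + nc[0]) % nc[0];
                else if (ax < 0 || ax >= nc[0]) continue;
                if (per[1]) ay = (ay % nc[1] + nc[1]) % nc[1];
                else if (ay < 0 || ay >= nc[1]) continue;
                if (per[2]) az = (az % nc[2] + nc[2]) % nc[2];
                else if (az < 0 || az >= nc[2]) continue;
                int c2i = (ax * nc[1] + ay) * nc[2] + az;
                if (c2i < c) continue;  // visit each cell pair once
                for (int i = head[c]; i >= 0; i = nxt[i])
                  for (int j = (c2i == c ? nxt[i] : head[c2i]); j >= 0; j = nxt[j]) {
                    if (chain_id[i] == chain_id[j]) continue;
                    double dd = 0.0;
                    double del[3] = {pos(i, 0) - pos(j, 0),
                                     pos(i, 1) - pos(j, 1),
                                     pos(i, 2) - pos(j, 2)};
                    for (int d = 0; d < 3; ++d) {
                      if (per[d]) {
                        if (del[d] > 0.5 * L[d]) del[d] -= L[d];
                        else if (del[d] < -0.5 * L[d]) del[d] += L[d];
                      }
                      dd += del[d] * del[d];
                    }
                    if (dd <= c2) unite(chain_id[i] - 1, chain_id[j] - 1);
                  }
              }
        }
  }
  IntegerVector out(nchain);
  // relabel roots consecutively
  std::vector<int> relabel(nchain, 0);
  int next_lab = 0;
  for (int i = 0; i < nchain; ++i) {
    int r = find(i);
    if (relabel[r] == 0) relabel[r] = ++next_lab;
    out[i] = relabel[r];
  }
  return out;
}
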