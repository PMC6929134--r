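// Force/torque kernels and Langevin integrator for the coarse-grained
// magnetosensitive polymersome model.  All quantities are in reduced units
// (length h, energy kBT).  Shell beads carry translational DOF only; the
// magnetic nanoparticles (MNPs) additionally carry a unit moment vector and
// an angular velocity.  Shell bead-bead sterics are intentionally absent:
// mesh springs and intershell bonds maintain the membrane geometry.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// splitmix64: turns (seed, stream) into a well-mixed 64-bit state
static inline uint64_t splitmix64(uint64_t& x) {
  x += 0x9e3779b97f4a7c15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d4a7c2ca79b8f5ULL ^ 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // Box-Muller normals (cached second draw) -- platform independent
  bool has_spare = false;
  double spare = 0.0;
  double gauss() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925287 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// system topology + force evaluation

struct EnergyTerms {
  double stretch = 0, area = 0, bend = 0, bond = 0, wca = 0, dipolar = 0,
         zeeman = 0;
  double total() const {
    return stretch + area + bend + bond + wca + dipolar + zeeman;
  }
};

// dihedral angle of the quad (k, i, j, l): triangles (k,i,j) and (i,j,l)
// share edge i-j; returns the torsion angle of the chain k-i-j-l.
static inline double dihedral_angle(const double* xk, const double* xi,
                                    const double* xj, const double* xl) {
  double b1[3], b2[3], b3[3], c1[3], c2[3], cc[3];
  for (int c = 0; c < 3; ++c) {
    b1[c] = xi[c] - xk[c];
    b2[c] = xj[c] - xi[c];
    b3[c] = xl[c] - xj[c];
  }
  cross3(b1, b2, c1);
  cross3(b2, b3, c2);
  cross3(c1, c2, cc);
  double nb2 = std::sqrt(dot3(b2, b2));
  return std::atan2(dot3(cc, b2) / nb2, dot3(c1, c2));
}

struct MpsSystem {
  int n_total = 0, n_beads = 0, n_mnp = 0;
  std::vector<int> e0, e1;          // stretch springs
  std::vector<double> erest;
  double k_stretch = 0;
  std::vector<int> t0, t1, t2;      // mesh triangles
  std::vector<double> tref;
  double k_area = 0;
  std::vector<int> dk, di, dj, dl;  // bending dihedrals (k,i,j,l)
  std::vector<double> phi0;
  double k_bend = 0;
  std::vector<int> b0, b1;          // intershell bonds
  double bond_rest = 1.0, k_bond = 0;
  std::vector<double> diam;         // per particle
  double wca_eps = 1.0;
  double dip_pref = 0.0;            // lambda * kBT * dp^3
  double xi_kBT = 0.0;              // Zeeman torque scale
  double hdir[3] = {0, 0, 1};
  long wca_caps = 0;                // capped-overlap counter
  long bend_caps = 0;               // clamped degenerate dihedrals

  int mnp0() const { return n_beads; }

  void stretch_forces(const double* x, double* F, EnergyTerms& E) {
    for (size_t k = 0; k < e0.size(); ++k) {
      const int i = e0[k], j = e1[k];
      double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2]};
      double l = std::sqrt(dot3(d, d));
      if (l < 1e-12) stop("degenerate mesh edge (zero length)");
      double f = -k_stretch * (l - erest[k]) / l;
      for (int c = 0; c < 3; ++c) { F[3*i+c] += f * d[c]; F[3*j+c] -= f * d[c]; }
      double dl = l - erest[k];
      E.stretch += 0.5 * k_stretch * dl * dl;
    }
  }

  // per-triangle energy (k_area/2) * (A - A0)^2 / A0
  void area_forces(const double* x, double* F, EnergyTerms& E) {
    for (size_t k = 0; k < t0.size(); ++k) {
      const int a = t0[k], b = t1[k], c = t2[k];
      double u[3] = {x[3*b] - x[3*a], x[3*b+1] - x[3*a+1], x[3*b+2] - x[3*a+2]};
      double w[3] = {x[3*c] - x[3*a], x[3*c+1] - x[3*a+1], x[3*c+2] - x[3*a+2]};
      double nrm[3];
      cross3(u, w, nrm);
      double n2 = dot3(nrm, nrm);
      if (n2 < 1e-24) stop("degenerate mesh triangle (zero area)");
      double A = 0.5 * std::sqrt(n2);
      double nh[3] = {nrm[0] / (2 * A), nrm[1] / (2 * A), nrm[2] / (2 * A)};
      double coef = -k_area * (A - tref[k]) / tref[k];
      // dA/dp = 0.5 * (opposite edge) x n_hat  (cyclic)
      double bc[3] = {x[3*b] - x[3*c], x[3*b+1] - x[3*c+1], x[3*b+2] - x[3*c+2]};
      double ca[3] = {x[3*c] - x[3*a], x[3*c+1] - x[3*a+1], x[3*c+2] - x[3*a+2]};
      double ab[3] = {x[3*a] - x[3*b], x[3*a+1] - x[3*b+1], x[3*a+2] - x[3*b+2]};
      double g[3];
      cross3(bc, nh, g);
      for (int d = 0; d < 3; ++d) F[3*a+d] += coef * 0.5 * g[d];
      cross3(ca, nh, g);
      for (int d = 0; d < 3; ++d) F[3*b+d] += coef * 0.5 * g[d];
      cross3(ab, nh, g);
      for (int d = 0; d < 3; ++d) F[3*c+d] += coef * 0.5 * g[d];
      double dA = A - tref[k];
      E.area += 0.5 * k_area * dA * dA / tref[k];
    }
  }

  // harmonic dihedral springs about the built angles: shape-memory bending
  void bending_forces(const double* x, double* F, EnergyTerms& E) {
    for (size_t m = 0; m < dk.size(); ++m) {
      const int k = dk[m], i = di[m], j = dj[m], l = dl[m];
      double b1[3], b2[3], b3[3], c1[3], c2[3], cc[3];
      for (int c = 0; c < 3; ++c) {
        b1[c] = x[3*i+c] - x[3*k+c];
        b2[c] = x[3*j+c] - x[3*i+c];
        b3[c] = x[3*l+c] - x[3*j+c];
      }
      cross3(b1, b2, c1);
      cross3(b2, b3, c2);
      cross3(c1, c2, cc);
      double n1 = dot3(c1, c1), n2 = dot3(c2, c2);
      if (n1 < 1e-24 || n2 < 1e-24) stop("degenerate bending dihedral");
      double nb2 = std::sqrt(dot3(b2, b2));
      double phi = std::atan2(dot3(cc, b2) / nb2, dot3(c1, c2));
      double dphi = phi - phi0[m];
      // wrap into (-pi, pi]
      while (dphi > M_PI) dphi -= 2 * M_PI;
      while (dphi <= -M_PI) dphi += 2 * M_PI;
      E.bend += 0.5 * k_bend * dphi * dphi;
      double dV = k_bend * dphi;
      // the exact gradient carries a 1/area factor that diverges for
      // degenerate triangles; clamp its norm (numerical safeguard, the
      // energy is untouched)
      const double gcap = 20.0;
      double sk = nb2 / std::sqrt(n1), sl = nb2 / std::sqrt(n2);
      if (sk > gcap) { sk = gcap; ++bend_caps; }
      if (sl > gcap) { sl = gcap; ++bend_caps; }
      double gk[3], gl[3];
      for (int c = 0; c < 3; ++c) {
        gk[c] = -sk / std::sqrt(n1) * c1[c];   // dphi/dx_k
        gl[c] =  sl / std::sqrt(n2) * c2[c];   // dphi/dx_l
      }
      double p = dot3(b1, b2) / (nb2 * nb2);
      double q = dot3(b3, b2) / (nb2 * nb2);
      for (int c = 0; c < 3; ++c) {
        double gi = -(1.0 + p) * gk[c] + q * gl[c];
        double gj = p * gk[c] - (1.0 + q) * gl[c];
        F[3*k+c] -= dV * gk[c];
        F[3*i+c] -= dV * gi;
        F[3*j+c] -= dV * gj;
        F[3*l+c] -= dV * gl[c];
      }
    }
  }

  void bond_forces(const double* x, double* F, EnergyTerms& E) {
    for (size_t k = 0; k < b0.size(); ++k) {
      const int i = b0[k], j = b1[k];
      double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2]};
      double l = std::sqrt(dot3(d, d));
      if (l < 1e-12) stop("degenerate intershell bond (zero length)");
      double f = -k_bond * (l - bond_rest) / l;
      for (int c = 0; c < 3; ++c) { F[3*i+c] += f * d[c]; F[3*j+c] -= f * d[c]; }
      double dl = l - bond_rest;
      E.bond += 0.5 * k_bond * dl * dl;
    }
  }

  // WCA between particles i and j; r capped below cap_frac*sigma for
  // integrator safety (counted)
  inline void wca_pair(const double* x, int i, int j, double* F,
                       EnergyTerms& E) {
    double sigma = 0.5 * (diam[i] + diam[j]);
    double rc2 = std::cbrt(2.0) * sigma * sigma;  // (2^{1/6} sigma)^2
    double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2]};
    double r2 = dot3(d, d);
    if (r2 >= rc2) return;
    double rmin = 0.3 * sigma;
    double r2eff = r2;
    if (r2 < rmin * rmin) { r2eff = rmin * rmin; ++wca_caps; }
    double s2 = sigma * sigma / r2eff;
    double s6 = s2 * s2 * s2;
    double fr = 24.0 * wca_eps * (2.0 * s6 * s6 - s6) / r2eff;  // F = fr * d
    for (int c = 0; c < 3; ++c) { F[3*i+c] += fr * d[c]; F[3*j+c] -= fr * d[c]; }
    E.wca += 4.0 * wca_eps * (s6 * s6 - s6) + wca_eps;
  }

  // all MNP-MNP and MNP-bead pairs, brute force
  void wca_forces_brute(const double* x, double* F, EnergyTerms& E) {
    const int m0 = mnp0();
    for (int i = m0; i < n_total; ++i) {
      for (int j = 0; j < m0; ++j) wca_pair(x, i, j, F, E);
      for (int j = i + 1; j < n_total; ++j) wca_pair(x, i, j, F, E);
    }
  }

  void wca_forces_list(const double* x, const std::vector<int>& pi,
                       const std::vector<int>& pj, double* F, EnergyTerms& E) {
    for (size_t k = 0; k < pi.size(); ++k) wca_pair(x, pi[k], pj[k], F, E);
  }

  // point-dipole pair forces and torques, all pairs, open boundaries
  void dipolar_forces(const double* x, const double* e, double* F, double* T,
                      EnergyTerms& E) {
    const int m0 = mnp0();
    for (int a = 0; a < n_mnp; ++a) {
      const int i = m0 + a;
      for (int b = a + 1; b < n_mnp; ++b) {
        const int j = m0 + b;
        double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1],
                       x[3*i+2] - x[3*j+2]};
        double r2 = dot3(d, d);
        if (r2 < 1e-20) stop("coincident dipole centres");
        double r = std::sqrt(r2);
        double rh[3] = {d[0] / r, d[1] / r, d[2] / r};
        const double* ei = e + 3 * a;
        const double* ej = e + 3 * b;
        double ee = dot3(ei, ej);
        double eir = dot3(ei, rh), ejr = dot3(ej, rh);
        double c3 = dip_pref / (r2 * r);
        E.dipolar += c3 * (ee - 3.0 * eir * ejr);
        double cf = 3.0 * c3 / r;
        for (int c = 0; c < 3; ++c) {
          double f = cf * ((ee - 5.0 * eir * ejr) * rh[c] +
                           ejr * ei[c] + eir * ej[c]);
          F[3*i+c] += f;
          F[3*j+c] -= f;
        }
        // torque_i = pref * ei x (3 rh (ej.rh) - ej) / r^3, and i<->j
        double Bi[3], Bj[3], tq[3];
        for (int c = 0; c < 3; ++c) {
          Bi[c] = c3 * (3.0 * rh[c] * ejr - ej[c]);
          Bj[c] = c3 * (3.0 * rh[c] * eir - ei[c]);
        }
        cross3(ei, Bi, tq);
        for (int c = 0; c < 3; ++c) T[3*a+c] += tq[c];
        cross3(ej, Bj, tq);
        for (int c = 0; c < 3; ++c) T[3*b+c] += tq[c];
      }
    }
  }

  void zeeman_torques(const double* e, double* T, EnergyTerms& E) {
    if (xi_kBT == 0.0) return;
    for (int a = 0; a < n_mnp; ++a) {
      const double* ea = e + 3 * a;
      double tq[3];
      cross3(ea, hdir, tq);
      for (int c = 0; c < 3; ++c) T[3*a+c] += xi_kBT * tq[c];
      E.zeeman -= xi_kBT * dot3(ea, hdir);
    }
  }

  void compute(const double* x, const double* e, double* F, double* T,
               EnergyTerms& E, const std::vector<int>* pair_i = nullptr,
               const std::vector<int>* pair_j = nullptr) {
    std::fill(F, F + 3 * n_total, 0.0);
    if (n_mnp > 0) std::fill(T, T + 3 * n_mnp, 0.0);
    E = EnergyTerms();
    stretch_forces(x, F, E);
    area_forces(x, F, E);
    bending_forces(x, F, E);
    bond_forces(x, F, E);
    if (n_mnp > 0) {
      if (wca_eps != 0.0) {
        if (pair_i) wca_forces_list(x, *pair_i, *pair_j, F, E);
        else wca_forces_brute(x, F, E);
      }
      if (dip_pref != 0.0) dipolar_forces(x, e, F, T, E);
      zeeman_torques(e, T, E);
    }
  }
};

static MpsSystem make_system(List topo) {
  MpsSystem s;
  s.n_beads = as<int>(topo["n_beads"]);
  s.n_mnp = as<int>(topo["n_mnp"]);
  s.n_total = s.n_beads + s.n_mnp;
  IntegerMatrix ed = topo["edges"];            // 1-based
  NumericVector er = topo["edge_rest"];
  for (int k = 0; k < ed.nrow(); ++k) {
    s.e0.push_back(ed(k, 0) - 1);
    s.e1.push_back(ed(k, 1) - 1);
    s.erest.push_back(er[k]);
  }
  s.k_stretch = as<double>(topo["k_stretch"]);
  IntegerMatrix tr = topo["triangles"];
  NumericVector ta = topo["tri_ref"];
  for (int k = 0; k < tr.nrow(); ++k) {
    s.t0.push_back(tr(k, 0) - 1);
    s.t1.push_back(tr(k, 1) - 1);
    s.t2.push_back(tr(k, 2) - 1);
    s.tref.push_back(ta[k]);
  }
  s.k_area = as<double>(topo["k_area"]);
  IntegerMatrix dh = topo["dihedrals"];      // columns k, i, j, l (1-based)
  NumericVector p0 = topo["phi0"];
  for (int k = 0; k < dh.nrow(); ++k) {
    s.dk.push_back(dh(k, 0) - 1);
    s.di.push_back(dh(k, 1) - 1);
    s.dj.push_back(dh(k, 2) - 1);
    s.dl.push_back(dh(k, 3) - 1);
    s.phi0.push_back(p0[k]);
  }
  s.k_bend = as<double>(topo["k_bend"]);
  IntegerMatrix bd = topo["bonds"];
  for (int k = 0; k < bd.nrow(); ++k) {
    s.b0.push_back(bd(k, 0) - 1);
    s.b1.push_back(bd(k, 1) - 1);
  }
  s.bond_rest = as<double>(topo["bond_rest"]);
  s.k_bond = as<double>(topo["k_bond"]);
  NumericVector dm = topo["diam"];
  s.diam.assign(dm.begin(), dm.end());
  s.wca_eps = as<double>(topo["wca_eps"]);
  s.dip_pref = as<double>(topo["dip_pref"]);
  s.xi_kBT = as<double>(topo["xi_kBT"]);
  NumericVector hd = topo["field_dir"];
  double hn = std::sqrt(hd[0]*hd[0] + hd[1]*hd[1] + hd[2]*hd[2]);
  for (int c = 0; c < 3; ++c) s.hdir[c] = hd[c] / hn;
  return s;
}

static NumericMatrix to_mat(const std::vector<double>& v, int n) {
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) m(i, c) = v[3 * i + c];
  return m;
}
static std::vector<double> from_mat(NumericMatrix m) {
  std::vector<double> v(3 * m.nrow());
  for (int i = 0; i < m.nrow(); ++i)
    for (int c = 0; c < 3; ++c) v[3 * i + c] = m(i, c);
  return v;
}

// [[Rcpp::export(name = ".cpp_forces")]]
List cpp_forces(List topo, NumericMatrix pos, NumericMatrix orient) {
  MpsSystem s = make_system(topo);
  if (pos.nrow() != s.n_total) stop("position count mismatch");
  std::vector<double> x = from_mat(pos), e = from_mat(orient);
  std::vector<double> F(3 * s.n_total, 0.0), T(3 * std::max(s.n_mnp, 1), 0.0);
  EnergyTerms E;
  s.compute(x.data(), e.data(), F.data(), T.data(), E);
  return List::create(
    _["forces"] = to_mat(F, s.n_total),
    _["torques"] = to_mat(T, std::max(s.n_mnp, 1)),
    _["energy"] = NumericVector::create(
      _["stretch"] = E.stretch, _["area"] = E.area, _["bend"] = E.bend,
      _["bond"] = E.bond, _["wca"] = E.wca, _["dipolar"] = E.dipolar,
      _["zeeman"] = E.zeeman),
    _["wca_caps"] = (double) s.wca_caps);
}

// ---------------------------------------------------------------------------
// stand-alone kernels for unit testing individual interaction types

// [[Rcpp::export(name = ".cpp_springs")]]
List cpp_springs(NumericMatrix pos, IntegerMatrix pairs, NumericVector rest,
                 double k) {
  MpsSystem s;
  s.n_total = pos.nrow();
  for (int i = 0; i < pairs.nrow(); ++i) {
    s.e0.push_back(pairs(i, 0) - 1);
    s.e1.push_back(pairs(i, 1) - 1);
    s.erest.push_back(rest[i]);
  }
  s.k_stretch = k;
  std::vector<double> x = from_mat(pos), F(3 * s.n_total, 0.0);
  EnergyTerms E;
  s.stretch_forces(x.data(), F.data(), E);
  return List::create(_["forces"] = to_mat(F, s.n_total),
                      _["energy"] = E.stretch);
}

// [[Rcpp::export(name = ".cpp_area")]]
List cpp_area(NumericMatrix pos, IntegerMatrix tris, NumericVector ref,
              double k) {
  MpsSystem s;
  s.n_total = pos.nrow();
  for (int i = 0; i < tris.nrow(); ++i) {
    s.t0.push_back(tris(i, 0) - 1);
    s.t1.push_back(tris(i, 1) - 1);
    s.t2.push_back(tris(i, 2) - 1);
    s.tref.push_back(ref[i]);
  }
  s.k_area = k;
  std::vector<double> x = from_mat(pos), F(3 * s.n_total, 0.0);
  EnergyTerms E;
  s.area_forces(x.data(), F.data(), E);
  return List::create(_["forces"] = to_mat(F, s.n_total),
                      _["energy"] = E.area);
}

// [[Rcpp::export(name = ".cpp_dihedral_angles")]]
NumericVector cpp_dihedral_angles(NumericMatrix pos, IntegerMatrix quads) {
  NumericVector out(quads.nrow());
  std::vector<double> x = from_mat(pos);
  for (int m = 0; m < quads.nrow(); ++m)
    out[m] = dihedral_angle(&x[3 * (quads(m, 0) - 1)],
                            &x[3 * (quads(m, 1) - 1)],
                            &x[3 * (quads(m, 2) - 1)],
                            &x[3 * (quads(m, 3) - 1)]);
  return out;
}

// [[Rcpp::export(name = ".cpp_bending")]]
List cpp_bending(NumericMatrix pos, IntegerMatrix quads, NumericVector phi0,
                 double k) {
  MpsSystem s;
  s.n_total = pos.nrow();
  for (int m = 0; m < quads.nrow(); ++m) {
    s.dk.push_back(quads(m, 0) - 1);
    s.di.push_back(quads(m, 1) - 1);
    s.dj.push_back(quads(m, 2) - 1);
    s.dl.push_back(quads(m, 3) - 1);
    s.phi0.push_back(phi0[m]);
  }
  s.k_bend = k;
  std::vector<double> x = from_mat(pos), F(3 * s.n_total, 0.0);
  EnergyTerms E;
  s.bending_forces(x.data(), F.data(), E);
  return List::create(_["forces"] = to_mat(F, s.n_total),
                      _["energy"] = E.bend);
}

// [[Rcpp::export(name = ".cpp_wca")]]
List cpp_wca(NumericMatrix pos, NumericVector diam, IntegerMatrix pairs,
             double eps) {
  MpsSystem s;
  s.n_total = pos.nrow();
  s.diam.assign(diam.begin(), diam.end());
  s.wca_eps = eps;
  std::vector<double> x = from_mat(pos), F(3 * s.n_total, 0.0);
  EnergyTerms E;
  for (int k = 0; k < pairs.nrow(); ++k)
    s.wca_pair(x.data(), pairs(k, 0) - 1, pairs(k, 1) - 1, F.data(), E);
  return List::create(_["forces"] = to_mat(F, s.n_total),
                      _["energy"] = E.wca,
                      _["wca_caps"] = (double) s.wca_caps);
}

// [[Rcpp::export(name = ".cpp_dipolar")]]
List cpp_dipolar(NumericMatrix pos, NumericMatrix orient, double pref) {
  MpsSystem s;
  s.n_mnp = pos.nrow();
  s.n_total = pos.nrow();
  s.n_beads = 0;
  s.dip_pref = pref;
  std::vector<double> x = from_mat(pos), e = from_mat(orient);
  std::vector<double> F(3 * s.n_total, 0.0), T(3 * s.n_mnp, 0.0);
  EnergyTerms E;
  s.dipolar_forces(x.data(), e.data(), F.data(), T.data(), E);
  return List::create(_["forces"] = to_mat(F, s.n_total),
                      _["torques"] = to_mat(T, s.n_mnp),
                      _["energy"] = E.dipolar);
}

// [[Rcpp::export(name = ".cpp_zeeman")]]
List cpp_zeeman(NumericMatrix orient, double xi_kBT, NumericVector field_dir) {
  MpsSystem s;
  s.n_mnp = orient.nrow();
  s.n_total = orient.nrow();
  s.n_beads = 0;
  s.xi_kBT = xi_kBT;
  double hn = std::sqrt(field_dir[0]*field_dir[0] + field_dir[1]*field_dir[1] +
                        field_dir[2]*field_dir[2]);
  for (int c = 0; c < 3; ++c) s.hdir[c] = field_dir[c] / hn;
  std::vector<double> e = from_mat(orient), T(3 * s.n_mnp, 0.0);
  EnergyTerms E;
  s.zeeman_torques(e.data(), T.data(), E);
  return List::create(_["torques"] = to_mat(T, s.n_mnp),
                      _["energy"] = E.zeeman);
}

// ---------------------------------------------------------------------------
// Verlet neighbour list over a uniform cell grid (WCA partners of MNPs only)

struct NeighbourList {
  std::vector<int> pi, pj;
  std::vector<double> ref;  // positions at build
  double r_list = 0.0;

  void build(const MpsSystem& s, const double* x) {
    pi.clear(); pj.clear();
    const int n = s.n_total, m0 = s.mnp0();
    double maxd_bead = 0, maxd_mnp = 0;
    for (int i = 0; i < m0; ++i) maxd_bead = std::max(maxd_bead, s.diam[i]);
    for (int i = m0; i < n; ++i) maxd_mnp = std::max(maxd_mnp, s.diam[i]);
    double cut = std::pow(2.0, 1.0 / 6.0) * 0.5 * (maxd_bead + maxd_mnp);
    double skin = 0.3 * maxd_mnp;
    r_list = cut + skin;
    double lo[3] = {1e30, 1e30, 1e30}, hi[3] = {-1e30, -1e30, -1e30};
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) {
        lo[c] = std::min(lo[c], x[3*i+c]);
        hi[c] = std::max(hi[c], x[3*i+c]);
      }
    int nc[3];
    for (int c = 0; c < 3; ++c)
      nc[c] = std::max(1, (int) std::floor((hi[c] - lo[c]) / r_list));
    double cw[3];
    for (int c = 0; c < 3; ++c) cw[c] = (hi[c] - lo[c]) / nc[c] + 1e-12;
    auto cell_of = [&](int i, int* cc) {
      for (int c = 0; c < 3; ++c) {
        cc[c] = (int) ((x[3*i+c] - lo[c]) / cw[c]);
        cc[c] = std::min(std::max(cc[c], 0), nc[c] - 1);
      }
    };
    std::vector<std::vector<int>> cells(nc[0] * nc[1] * nc[2]);
    for (int i = 0; i < n; ++i) {
      int cc[3];
      cell_of(i, cc);
      cells[(cc[0] * nc[1] + cc[1]) * nc[2] + cc[2]].push_back(i);
    }
    const double rl2 = r_list * r_list;
    for (int i = m0; i < n; ++i) {
      int cc[3];
      cell_of(i, cc);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int a = cc[0] + dx, b = cc[1] + dy, g = cc[2] + dz;
            if (a < 0 || b < 0 || g < 0 || a >= nc[0] || b >= nc[1] ||
                g >= nc[2]) continue;
            for (int j : cells[(a * nc[1] + b) * nc[2] + g]) {
              if (j >= m0 && j <= i) continue;  // MNP pairs once
              double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1],
                             x[3*i+2] - x[3*j+2]};
              if (dot3(d, d) < rl2) { pi.push_back(i); pj.push_back(j); }
            }
          }
    }
    ref.assign(x, x + 3 * n);
  }

  bool stale(const MpsSystem& s, const double* x) const {
    double maxd_mnp = 0;
    for (int i = s.mnp0(); i < s.n_total; ++i)
      maxd_mnp = std::max(maxd_mnp, s.diam[i]);
    double lim = 0.5 * 0.3 * maxd_mnp;
    double lim2 = lim * lim;
    for (int i = 0; i < s.n_total; ++i) {
      double d[3] = {x[3*i] - ref[3*i], x[3*i+1] - ref[3*i+1],
                     x[3*i+2] - ref[3*i+2]};
      if (dot3(d, d) > lim2) return true;
    }
    return false;
  }
};

// ---------------------------------------------------------------------------
// BAOAB Langevin integrator with rotational dynamics of the MNP moments.
// Orientations evolve by e <- e + (omega x e) dt with renormalisation.

// [[Rcpp::export(name = ".cpp_run_langevin")]]
List cpp_run_langevin(List topo, NumericMatrix pos, NumericMatrix vel,
                      NumericMatrix orient, NumericMatrix angvel,
                      List dyn, int n_steps, double seed_hi, double seed_lo) {
  MpsSystem s = make_system(topo);
  const int n = s.n_total, nm = s.n_mnp, m0 = s.mnp0();
  std::vector<double> x = from_mat(pos), v = from_mat(vel);
  std::vector<double> e = from_mat(orient), w = from_mat(angvel);
  if (e.size() < 3) e.assign(3, 0.0);   // dummy row when no dipoles
  if (w.size() < 3) w.assign(3, 0.0);
  const double dt = as<double>(dyn["dt"]);
  const double kBT = as<double>(dyn["kBT"]);
  const double mass = as<double>(dyn["mass"]);
  const double mass_mnp = dyn.containsElementNamed("mass_mnp")
    ? as<double>(dyn["mass_mnp"]) : mass;
  const double inertia = as<double>(dyn["inertia"]);
  const double zeta_t = as<double>(dyn["zeta_t"]);
  const double zeta_r = as<double>(dyn["zeta_r"]);
  const bool thermo = as<bool>(dyn["thermostat"]);
  const int energy_interval = as<int>(dyn["energy_interval"]);
  const int sample_interval = as<int>(dyn["sample_interval"]);
  const double max_disp = as<double>(dyn["max_disp"]);  // per-step abort

  uint64_t seed = ((uint64_t) seed_hi << 21) ^ (uint64_t) seed_lo;
  Xoshiro rng(seed);

  const double c1b = thermo ? std::exp(-zeta_t * dt / mass) : 1.0;
  const double c2b = thermo ? std::sqrt((1.0 - c1b * c1b) * kBT / mass) : 0.0;
  const double c1m = thermo ? std::exp(-zeta_t * dt / mass_mnp) : 1.0;
  const double c2m = thermo ? std::sqrt((1.0 - c1m * c1m) * kBT / mass_mnp)
                            : 0.0;
  const double c1r = thermo ? std::exp(-zeta_r * dt / inertia) : 1.0;
  const double c2r = thermo ? std::sqrt((1.0 - c1r * c1r) * kBT / inertia)
                            : 0.0;

  std::vector<double> F(3 * n, 0.0), T(3 * std::max(nm, 1), 0.0);
  EnergyTerms E;
  NeighbourList nl;
  bool use_list = nm > 0 && s.n_beads > 0;
  if (use_list) nl.build(s, x.data());
  s.compute(x.data(), e.data(), F.data(), T.data(), E,
            use_list ? &nl.pi : nullptr, use_list ? &nl.pj : nullptr);

  int n_rec = energy_interval > 0 ? n_steps / energy_interval : 0;
  NumericMatrix trace(n_rec, 11);
  colnames(trace) = CharacterVector::create(
    "step", "E_pot", "E_kin_t", "E_kin_r", "stretch", "area", "bend",
    "bond", "wca", "dipolar", "zeeman");
  int rec = 0;
  List frames;
  std::vector<double> xprev(3 * n);
  bool aborted = false;
  std::string abort_msg;

  for (int step = 1; step <= n_steps; ++step) {
    std::copy(x.begin(), x.end(), xprev.begin());
    // B: half kick
    const double hdt_b = 0.5 * dt / mass, hdt_m = 0.5 * dt / mass_mnp;
    const double hdt_I = 0.5 * dt / inertia;
    for (int i = 0; i < 3 * m0; ++i) v[i] += hdt_b * F[i];
    for (int i = 3 * m0; i < 3 * n; ++i) v[i] += hdt_m * F[i];
    for (int i = 0; i < 3 * nm; ++i) w[i] += hdt_I * T[i];
    // A: half drift
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    for (int a = 0; a < nm; ++a) {
      double de[3];
      cross3(&w[3*a], &e[3*a], de);
      for (int c = 0; c < 3; ++c) e[3*a+c] += 0.5 * dt * de[c];
      double nn = std::sqrt(dot3(&e[3*a], &e[3*a]));
      for (int c = 0; c < 3; ++c) e[3*a+c] /= nn;
    }
    // O: thermostat
    if (thermo) {
      for (int i = 0; i < 3 * m0; ++i) v[i] = c1b * v[i] + c2b * rng.gauss();
      for (int i = 3 * m0; i < 3 * n; ++i)
        v[i] = c1m * v[i] + c2m * rng.gauss();
      for (int i = 0; i < 3 * nm; ++i) w[i] = c1r * w[i] + c2r * rng.gauss();
    }
    // A: half drift
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    for (int a = 0; a < nm; ++a) {
      double de[3];
      cross3(&w[3*a], &e[3*a], de);
      for (int c = 0; c < 3; ++c) e[3*a+c] += 0.5 * dt * de[c];
      double nn = std::sqrt(dot3(&e[3*a], &e[3*a]));
      for (int c = 0; c < 3; ++c) e[3*a+c] /= nn;
    }
    // displacement guard
    double md2 = 0;
    int mi = -1;
    for (int i = 0; i < n; ++i) {
      double d[3] = {x[3*i] - xprev[3*i], x[3*i+1] - xprev[3*i+1],
                     x[3*i+2] - xprev[3*i+2]};
      double dd = dot3(d, d);
      if (dd > md2) { md2 = dd; mi = i; }
    }
    if (md2 > max_disp * max_disp) {
      double fmax = 0;
      for (int c = 0; c < 3; ++c) fmax += F[3*mi+c] * F[3*mi+c];
      aborted = true;
      abort_msg = "timestep too large: per-step displacement " +
        std::to_string(std::sqrt(md2)) + " exceeds limit " +
        std::to_string(max_disp) + " (particle " + std::to_string(mi + 1) +
        (mi >= m0 ? " [MNP]" : " [bead]") + ", step " +
        std::to_string(step) + ", |F| " + std::to_string(std::sqrt(fmax)) +
        ")";
      break;
    }
    if (use_list && nl.stale(s, x.data())) nl.build(s, x.data());
    // force update + B: half kick
    s.compute(x.data(), e.data(), F.data(), T.data(), E,
              use_list ? &nl.pi : nullptr, use_list ? &nl.pj : nullptr);
    for (int i = 0; i < 3 * m0; ++i) v[i] += hdt_b * F[i];
    for (int i = 3 * m0; i < 3 * n; ++i) v[i] += hdt_m * F[i];
    for (int i = 0; i < 3 * nm; ++i) w[i] += hdt_I * T[i];

    if (energy_interval > 0 && step % energy_interval == 0 && rec < n_rec) {
      double ekt = 0, ekr = 0;
      for (int i = 0; i < 3 * m0; ++i) ekt += mass * v[i] * v[i];
      for (int i = 3 * m0; i < 3 * n; ++i) ekt += mass_mnp * v[i] * v[i];
      for (int i = 0; i < 3 * nm; ++i) ekr += w[i] * w[i];
      ekt *= 0.5;
      ekr *= 0.5 * inertia;
      trace(rec, 0) = step;
      trace(rec, 1) = E.total();
      trace(rec, 2) = ekt;
      trace(rec, 3) = ekr;
      trace(rec, 4) = E.stretch; trace(rec, 5) = E.area;
      trace(rec, 6) = E.bend; trace(rec, 7) = E.bond;
      trace(rec, 8) = E.wca; trace(rec, 9) = E.dipolar;
      trace(rec, 10) = E.zeeman;
      ++rec;
    }
    if (sample_interval > 0 && step % sample_interval == 0) {
      frames.push_back(List::create(_["step"] = step,
                                    _["positions"] = to_mat(x, n),
                                    _["orientations"] = to_mat(e,
                                                               std::max(nm, 1))));
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["positions"] = to_mat(x, n), _["velocities"] = to_mat(v, n),
    _["orientations"] = to_mat(e, std::max(nm, 1)),
    _["ang_velocities"] = to_mat(w, std::max(nm, 1)),
    _["trace"] = trace, _["frames"] = frames,
    _["wca_caps"] = (double) s.wca_caps,
    _["aborted"] = aborted, _["abort_msg"] = abort_msg);
}
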