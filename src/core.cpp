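// Compiled core: force-field evaluation, BAOAB Langevin propagation and the
// discrete Gauss linking-number double sum.  Units: kcal/mol, Angstrom, Da,
// ps.  Masses are converted internally so that 1 kcal/mol = 418.4 Da A^2/ps^2.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double MASS_CONV = 418.4;      // Da A^2/ps^2 per kcal/mol
static const double KBOLTZ = 0.0019872041;  // kcal/mol/K

struct Vec3 {
  double x, y, z;
};
static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline double vdot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double vnorm(const Vec3 &a) { return std::sqrt(vdot(a, a)); }

// 12-10-6 pair potential eps*(13 s^12 - 18 s^10 + 4 s^6), s = R/r.
// Returns energy; dEdr receives dE/dr.
static inline double e12106(double r, double eps, double R, double &dEdr) {
  double s2 = (R / r) * (R / r);
  double s6 = s2 * s2 * s2, s10 = s6 * s2 * s2, s12 = s10 * s2;
  double e = eps * (13.0 * s12 - 18.0 * s10 + 4.0 * s6);
  dEdr = eps * (-12.0 * 13.0 * s12 + 10.0 * 18.0 * s10 - 6.0 * 4.0 * s6) / r;
  return e;
}

// 12-6 pair potential eps*(s^12 - 2 s^6).
static inline double e126(double r, double eps, double R, double &dEdr) {
  double s2 = (R / r) * (R / r);
  double s6 = s2 * s2 * s2, s12 = s6 * s6;
  double e = eps * (s12 - 2.0 * s6);
  dEdr = eps * (-12.0 * s12 + 12.0 * s6) / r;
  return e;
}

// C1 cubic switch: 1 for r <= rc - w, 0 for r >= rc.
static inline double switchf(double r, double rc, double w, double &dSdr) {
  if (r >= rc) { dSdr = 0.0; return 0.0; }
  if (r <= rc - w || w <= 0.0) { dSdr = 0.0; return 1.0; }
  double t = (r - (rc - w)) / w;
  dSdr = (-6.0 * t + 6.0 * t * t) / w;
  return 1.0 - 3.0 * t * t + 2.0 * t * t * t;
}

struct WallSpec {
  bool active = false;
  double x_wall = 160.0, r_tunnel = 7.5, k_rep = 50.0;
  std::vector<int> prot_idx;            // 0-based
  std::vector<double> prot_radius;
  std::vector<int> lig_idx;
  std::vector<double> lig_eps, lig_R;
};

struct RestraintSpec {
  int mode = 0;  // 0 none, 1 per-site to fixed point, 2 COM-COM
  double K = 0.1, d0 = 100.0;
  double cx = 160.0, cy = 0.0, cz = 0.0;
  std::vector<int> sites;               // mode 1 (0-based)
  std::vector<int> groupA, groupB;      // mode 2
};

struct System {
  int n = 0;
  std::vector<double> bonds;      // i j b0 K (stride 4, indices 0-based)
  std::vector<double> angles;     // i j k th0 K (stride 5)
  std::vector<double> dihedrals;  // i j k l phi0 K1 K3 (stride 7)
  std::vector<double> p1210;      // i j eps R use_cutoff (stride 5)
  std::vector<double> p126;       // i j eps R (stride 4)
  std::vector<double> anchors;    // i x y z K (stride 5)
  double cutoff = 20.0, switch_width = 2.0;
  WallSpec wall;
  RestraintSpec restr;
  std::vector<double> massesDa;

  // returns potential energy; f (length 3n) receives forces
  double forces(const std::vector<double> &x, std::vector<double> &f,
                double *comp = nullptr) const {
    std::fill(f.begin(), f.end(), 0.0);
    double e_bond = 0, e_angle = 0, e_dih = 0, e_pair = 0, e_bind = 0,
           e_wall = 0, e_restr = 0, e_anchor = 0;
    // bonds
    for (size_t b = 0; b < bonds.size(); b += 4) {
      int i = (int)bonds[b], j = (int)bonds[b + 1];
      double b0 = bonds[b + 2], K = bonds[b + 3];
      Vec3 d = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                x[3 * i + 2] - x[3 * j + 2]};
      double r = vnorm(d);
      if (r < 1e-12) return R_PosInf;
      double dr = r - b0;
      e_bond += K * dr * dr;
      double c = -2.0 * K * dr / r;
      f[3 * i] += c * d.x; f[3 * i + 1] += c * d.y; f[3 * i + 2] += c * d.z;
      f[3 * j] -= c * d.x; f[3 * j + 1] -= c * d.y; f[3 * j + 2] -= c * d.z;
    }
    // angles: V = K (theta - th0)^2
    for (size_t b = 0; b < angles.size(); b += 5) {
      int i = (int)angles[b], j = (int)angles[b + 1], k = (int)angles[b + 2];
      double th0 = angles[b + 3], K = angles[b + 4];
      Vec3 a = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                x[3 * i + 2] - x[3 * j + 2]};
      Vec3 c = {x[3 * k] - x[3 * j], x[3 * k + 1] - x[3 * j + 1],
                x[3 * k + 2] - x[3 * j + 2]};
      double la = vnorm(a), lc = vnorm(c);
      if (la < 1e-12 || lc < 1e-12) return R_PosInf;
      double cth = vdot(a, c) / (la * lc);
      cth = std::max(-1.0, std::min(1.0, cth));
      double th = std::acos(cth);
      double sth = std::sqrt(std::max(1.0 - cth * cth, 1e-12));
      double dth = th - th0;
      e_angle += K * dth * dth;
      double coef = 2.0 * K * dth / sth;  // = -dV/dth * d(cos)/... sign below
      // d(cos th)/d a_i = c/(la lc) - cth a/la^2 ; F = -dV/dth * dth/dp,
      // dth/dp = -1/sth * dcos/dp  =>  F_i = -coef_? ... assembled directly:
      Vec3 fi = {coef * (c.x / (la * lc) - cth * a.x / (la * la)),
                 coef * (c.y / (la * lc) - cth * a.y / (la * la)),
                 coef * (c.z / (la * lc) - cth * a.z / (la * la))};
      Vec3 fk = {coef * (a.x / (la * lc) - cth * c.x / (lc * lc)),
                 coef * (a.y / (la * lc) - cth * c.y / (lc * lc)),
                 coef * (a.z / (la * lc) - cth * c.z / (lc * lc))};
      f[3 * i] += fi.x; f[3 * i + 1] += fi.y; f[3 * i + 2] += fi.z;
      f[3 * k] += fk.x; f[3 * k + 1] += fk.y; f[3 * k + 2] += fk.z;
      f[3 * j] -= fi.x + fk.x; f[3 * j + 1] -= fi.y + fk.y;
      f[3 * j + 2] -= fi.z + fk.z;
    }
    // dihedrals: V = K1 (1 - cos(phi - phi0)) + K3 (1 - cos(3 (phi - phi0)))
    for (size_t b = 0; b < dihedrals.size(); b += 7) {
      int i = (int)dihedrals[b], j = (int)dihedrals[b + 1],
          k = (int)dihedrals[b + 2], l = (int)dihedrals[b + 3];
      double phi0 = dihedrals[b + 4], K1 = dihedrals[b + 5],
             K3 = dihedrals[b + 6];
      Vec3 b1 = {x[3 * j] - x[3 * i], x[3 * j + 1] - x[3 * i + 1],
                 x[3 * j + 2] - x[3 * i + 2]};
      Vec3 b2 = {x[3 * k] - x[3 * j], x[3 * k + 1] - x[3 * j + 1],
                 x[3 * k + 2] - x[3 * j + 2]};
      Vec3 b3 = {x[3 * l] - x[3 * k], x[3 * l + 1] - x[3 * k + 1],
                 x[3 * l + 2] - x[3 * k + 2]};
      Vec3 n1 = vcross(b1, b2), n2 = vcross(b2, b3);
      double ln1 = vdot(n1, n1), ln2 = vdot(n2, n2), lb2 = vnorm(b2);
      if (ln1 < 1e-12 || ln2 < 1e-12 || lb2 < 1e-12) continue;  // degenerate
      double phi = std::atan2(vdot(vcross(n1, n2), b2) / lb2, vdot(n1, n2));
      double dphi = phi - phi0;
      e_dih += K1 * (1.0 - std::cos(dphi)) + K3 * (1.0 - std::cos(3.0 * dphi));
      double dV = K1 * std::sin(dphi) + 3.0 * K3 * std::sin(3.0 * dphi);
      // F = -dV/dphi * dphi/dr with dphi/dr1 = -|b2|/|n1|^2 n1,
      // dphi/dr4 = |b2|/|n2|^2 n2 and the Blondel-Karplus middle terms
      Vec3 fi = {dV * lb2 / ln1 * n1.x, dV * lb2 / ln1 * n1.y,
                 dV * lb2 / ln1 * n1.z};
      Vec3 fl = {-dV * lb2 / ln2 * n2.x, -dV * lb2 / ln2 * n2.y,
                 -dV * lb2 / ln2 * n2.z};
      double t1 = vdot(b1, b2) / (lb2 * lb2), t2 = vdot(b3, b2) / (lb2 * lb2);
      Vec3 fj = {-(1.0 + t1) * fi.x + t2 * fl.x,
                 -(1.0 + t1) * fi.y + t2 * fl.y,
                 -(1.0 + t1) * fi.z + t2 * fl.z};
      Vec3 fk = {t1 * fi.x - (1.0 + t2) * fl.x,
                 t1 * fi.y - (1.0 + t2) * fl.y,
                 t1 * fi.z - (1.0 + t2) * fl.z};
      f[3 * i] += fi.x; f[3 * i + 1] += fi.y; f[3 * i + 2] += fi.z;
      f[3 * j] += fj.x; f[3 * j + 1] += fj.y; f[3 * j + 2] += fj.z;
      f[3 * k] += fk.x; f[3 * k + 1] += fk.y; f[3 * k + 2] += fk.z;
      f[3 * l] += fl.x; f[3 * l + 1] += fl.y; f[3 * l + 2] += fl.z;
    }
    // 12-10-6 pairs (native contacts, non-native repulsion, ligand internal)
    for (size_t b = 0; b < p1210.size(); b += 5) {
      int i = (int)p1210[b], j = (int)p1210[b + 1];
      double eps = p1210[b + 2], R = p1210[b + 3];
      bool use_cut = p1210[b + 4] > 0.5;
      Vec3 d = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                x[3 * i + 2] - x[3 * j + 2]};
      double r = vnorm(d);
      if (use_cut && r >= cutoff) continue;
      if (r < 1e-12) return R_PosInf;
      double dEdr, e = e12106(r, eps, R, dEdr);
      if (use_cut) {
        double dSdr, S = switchf(r, cutoff, switch_width, dSdr);
        dEdr = dEdr * S + e * dSdr;
        e *= S;
      }
      e_pair += e;
      double c = -dEdr / r;
      f[3 * i] += c * d.x; f[3 * i + 1] += c * d.y; f[3 * i + 2] += c * d.z;
      f[3 * j] -= c * d.x; f[3 * j + 1] -= c * d.y; f[3 * j + 2] -= c * d.z;
    }
    // 12-6 binding pairs (no cutoff)
    for (size_t b = 0; b < p126.size(); b += 4) {
      int i = (int)p126[b], j = (int)p126[b + 1];
      double eps = p126[b + 2], R = p126[b + 3];
      Vec3 d = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                x[3 * i + 2] - x[3 * j + 2]};
      double r = vnorm(d);
      if (r < 1e-12) return R_PosInf;
      double dEdr, e = e126(r, eps, R, dEdr);
      e_bind += e;
      double c = -dEdr / r;
      f[3 * i] += c * d.x; f[3 * i + 1] += c * d.y; f[3 * i + 2] += c * d.z;
      f[3 * j] -= c * d.x; f[3 * j + 1] -= c * d.y; f[3 * j + 2] -= c * d.z;
    }
    // harmonic position anchors
    for (size_t b = 0; b < anchors.size(); b += 5) {
      int i = (int)anchors[b];
      double dx = x[3 * i] - anchors[b + 1], dy = x[3 * i + 1] - anchors[b + 2],
             dz = x[3 * i + 2] - anchors[b + 3], K = anchors[b + 4];
      e_anchor += K * (dx * dx + dy * dy + dz * dz);
      f[3 * i] -= 2.0 * K * dx;
      f[3 * i + 1] -= 2.0 * K * dy;
      f[3 * i + 2] -= 2.0 * K * dz;
    }
    // simplified ribosome wall: the solid region {x >= x_wall} minus the
    // cylindrical exit tunnel {rho < r_tunnel} about the x axis.  Both the
    // protein penalty and the ligand 12-10-6 term act on the continuous
    // signed distance to the solid's surface (positive outside).
    if (wall.active) {
      // signed distance and its gradient (dsd_dx, dsd_drho)
      auto signed_dist = [&](double px, double rho, double &gx,
                             double &grho) {
        double a = wall.x_wall - px;       // >0 outside the plane
        double b = wall.r_tunnel - rho;    // >0 inside the tunnel radius
        if (a > 0.0 && b <= 0.0) { gx = -1.0; grho = 0.0; return a; }
        if (a > 0.0 && b > 0.0) {
          double sd = std::sqrt(a * a + b * b);
          gx = -a / sd; grho = -b / sd;
          return sd;
        }
        if (a <= 0.0 && b > 0.0) { gx = 0.0; grho = -1.0; return b; }
        // inside the solid: negative distance to the nearest face
        if (-a < -b) { gx = -1.0; grho = 0.0; return a; }
        gx = 0.0; grho = -1.0; return b;
      };
      for (size_t b = 0; b < wall.prot_idx.size(); ++b) {
        int i = wall.prot_idx[b];
        double Ri = wall.prot_radius[b];
        double py = x[3 * i + 1], pz = x[3 * i + 2];
        double rho = std::sqrt(py * py + pz * pz);
        double gx, grho;
        double sd = signed_dist(x[3 * i], rho, gx, grho);
        if (sd < Ri) {
          double d = Ri - sd;
          e_wall += wall.k_rep * d * d;
          double c = 2.0 * wall.k_rep * d;  // F = +dE/d(sd) * dsd/dpos...
          f[3 * i] += c * gx;
          if (rho > 1e-9) {
            f[3 * i + 1] += c * grho * py / rho;
            f[3 * i + 2] += c * grho * pz / rho;
          }
        }
      }
      for (size_t b = 0; b < wall.lig_idx.size(); ++b) {
        int i = wall.lig_idx[b];
        double py = x[3 * i + 1], pz = x[3 * i + 2];
        double rho = std::sqrt(py * py + pz * pz);
        double gx, grho;
        double sd = signed_dist(x[3 * i], rho, gx, grho);
        if (sd >= cutoff) continue;
        double r = sd < 0.05 ? 0.05 : sd;  // clamp deep in the wall
        double dEdr, e = e12106(r, wall.lig_eps[b], wall.lig_R[b], dEdr);
        double dSdr, S = switchf(r, cutoff, switch_width, dSdr);
        e_wall += e * S;
        double dEdsd = (sd < 0.05) ? 0.0 : (dEdr * S + e * dSdr);
        f[3 * i] -= dEdsd * gx;
        if (rho > 1e-9) {
          f[3 * i + 1] -= dEdsd * grho * py / rho;
          f[3 * i + 2] -= dEdsd * grho * pz / rho;
        }
      }
    }
    // spherical restraint (Eq-6 form)
    if (restr.mode == 1) {
      for (size_t b = 0; b < restr.sites.size(); ++b) {
        int i = restr.sites[b];
        Vec3 d = {x[3 * i] - restr.cx, x[3 * i + 1] - restr.cy,
                  x[3 * i + 2] - restr.cz};
        double r = vnorm(d);
        if (r > restr.d0) {
          double dr = r - restr.d0;
          e_restr += restr.K * dr * dr;
          double c = -2.0 * restr.K * dr / r;
          f[3 * i] += c * d.x; f[3 * i + 1] += c * d.y; f[3 * i + 2] += c * d.z;
        }
      }
    } else if (restr.mode == 2) {
      double mA = 0, mB = 0;
      Vec3 cA = {0, 0, 0}, cB = {0, 0, 0};
      for (int i : restr.groupA) {
        double m = massesDa[i];
        mA += m;
        cA.x += m * x[3 * i]; cA.y += m * x[3 * i + 1]; cA.z += m * x[3 * i + 2];
      }
      for (int i : restr.groupB) {
        double m = massesDa[i];
        mB += m;
        cB.x += m * x[3 * i]; cB.y += m * x[3 * i + 1]; cB.z += m * x[3 * i + 2];
      }
      cA.x /= mA; cA.y /= mA; cA.z /= mA;
      cB.x /= mB; cB.y /= mB; cB.z /= mB;
      Vec3 d = vsub(cA, cB);
      double r = vnorm(d);
      if (r > restr.d0 && r > 1e-12) {
        double dr = r - restr.d0;
        e_restr += restr.K * dr * dr;
        double g = 2.0 * restr.K * dr / r;  // dE/dr * unit vector factor
        for (int i : restr.groupA) {
          double w = massesDa[i] / mA;
          f[3 * i] -= g * w * d.x; f[3 * i + 1] -= g * w * d.y;
          f[3 * i + 2] -= g * w * d.z;
        }
        for (int i : restr.groupB) {
          double w = massesDa[i] / mB;
          f[3 * i] += g * w * d.x; f[3 * i + 1] += g * w * d.y;
          f[3 * i + 2] += g * w * d.z;
        }
      }
    }
    if (comp) {
      comp[0] = e_bond; comp[1] = e_angle; comp[2] = e_dih; comp[3] = e_pair;
      comp[4] = e_bind; comp[5] = e_wall; comp[6] = e_restr; comp[7] = e_anchor;
    }
    return e_bond + e_angle + e_dih + e_pair + e_bind + e_wall + e_restr +
           e_anchor;
  }
};

static std::vector<double> flatmat(SEXP m) {
  if (Rf_isNull(m)) return {};
  NumericMatrix M(m);
  std::vector<double> out(M.nrow() * M.ncol());
  for (int r = 0; r < M.nrow(); ++r)
    for (int c = 0; c < M.ncol(); ++c) out[r * M.ncol() + c] = M(r, c);
  return out;
}

static System parse_system(List par) {
  System s;
  s.n = as<int>(par["n_beads"]);
  s.bonds = flatmat(par["bonds"]);
  s.angles = flatmat(par["angles"]);
  s.dihedrals = flatmat(par["dihedrals"]);
  s.p1210 = flatmat(par["pairs_12_10_6"]);
  s.p126 = flatmat(par["pairs_12_6"]);
  s.anchors = flatmat(par["anchors"]);
  s.cutoff = as<double>(par["cutoff"]);
  s.switch_width = as<double>(par["switch_width"]);
  s.massesDa = as<std::vector<double> >(par["masses"]);
  // convert 1-based indices from R
  auto fix = [](std::vector<double> &v, size_t stride, size_t nidx) {
    for (size_t b = 0; b < v.size(); b += stride)
      for (size_t k = 0; k < nidx; ++k) v[b + k] -= 1.0;
  };
  fix(s.bonds, 4, 2);
  fix(s.angles, 5, 3);
  fix(s.dihedrals, 7, 4);
  fix(s.p1210, 5, 2);
  fix(s.p126, 4, 2);
  fix(s.anchors, 5, 1);
  if (par.containsElementNamed("wall") && !Rf_isNull(par["wall"])) {
    List w(par["wall"]);
    s.wall.active = as<bool>(w["active"]);
    if (s.wall.active) {
      s.wall.x_wall = as<double>(w["x_wall"]);
      s.wall.r_tunnel = as<double>(w["r_tunnel"]);
      s.wall.k_rep = as<double>(w["k_rep"]);
      IntegerVector pi(w["protein_idx"]);
      NumericVector pr(w["protein_radius"]);
      for (int i = 0; i < pi.size(); ++i) {
        s.wall.prot_idx.push_back(pi[i] - 1);
        s.wall.prot_radius.push_back(pr[i]);
      }
      IntegerVector li(w["ligand_idx"]);
      NumericVector le(w["ligand_eps"]), lr(w["ligand_R"]);
      for (int i = 0; i < li.size(); ++i) {
        s.wall.lig_idx.push_back(li[i] - 1);
        s.wall.lig_eps.push_back(le[i]);
        s.wall.lig_R.push_back(lr[i]);
      }
    }
  }
  if (par.containsElementNamed("restraint") && !Rf_isNull(par["restraint"])) {
    List r(par["restraint"]);
    s.restr.mode = as<int>(r["mode"]);
    if (s.restr.mode > 0) {
      s.restr.K = as<double>(r["K"]);
      s.restr.d0 = as<double>(r["d0"]);
      if (s.restr.mode == 1) {
        NumericVector ctr(r["center"]);
        s.restr.cx = ctr[0]; s.restr.cy = ctr[1]; s.restr.cz = ctr[2];
        IntegerVector si(r["sites"]);
        for (int i = 0; i < si.size(); ++i) s.restr.sites.push_back(si[i] - 1);
      } else {
        IntegerVector ga(r["group_a"]), gb(r["group_b"]);
        for (int i = 0; i < ga.size(); ++i) s.restr.groupA.push_back(ga[i] - 1);
        for (int i = 0; i < gb.size(); ++i) s.restr.groupB.push_back(gb[i] - 1);
      }
    }
  }
  return s;
}

// [[Rcpp::export]]
List eval_energy_forces_cpp(NumericMatrix pos, List par) {
  System s = parse_system(par);
  int n = pos.nrow();
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i) {
    x[3 * i] = pos(i, 0); x[3 * i + 1] = pos(i, 1); x[3 * i + 2] = pos(i, 2);
  }
  double comp[8];
  double e = s.forces(x, f, comp);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) {
    F(i, 0) = f[3 * i]; F(i, 1) = f[3 * i + 1]; F(i, 2) = f[3 * i + 2];
  }
  return List::create(
      _["energy"] = e, _["forces"] = F,
      _["components"] = NumericVector::create(
          _["bond"] = comp[0], _["angle"] = comp[1], _["dihedral"] = comp[2],
          _["pair_12_10_6"] = comp[3], _["pair_12_6"] = comp[4],
          _["wall"] = comp[5], _["restraint"] = comp[6],
          _["anchor"] = comp[7]));
}

// BAOAB Langevin propagation.  Draws Gaussian noise from R's RNG so that a
// set.seed() call on the R side makes trajectories reproducible.
// [[Rcpp::export]]
List run_langevin_cpp(NumericMatrix pos, NumericMatrix vel, List par,
                      double dt, double gamma, double temperature,
                      int n_steps, int save_every) {
  System s = parse_system(par);
  int n = pos.nrow();
  std::vector<double> x(3 * n), v(3 * n), f(3 * n), minv(n), sig(n);
  for (int i = 0; i < n; ++i) {
    x[3 * i] = pos(i, 0); x[3 * i + 1] = pos(i, 1); x[3 * i + 2] = pos(i, 2);
    v[3 * i] = vel(i, 0); v[3 * i + 1] = vel(i, 1); v[3 * i + 2] = vel(i, 2);
    double m = s.massesDa[i] / MASS_CONV;  // energy-consistent mass
    minv[i] = 1.0 / m;
    sig[i] = std::sqrt(KBOLTZ * temperature / m);
  }
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  bool noise = (c2 > 0.0 && temperature > 0.0);

  int n_saved = n_steps / save_every + 1;
  NumericVector times(n_saved), epot_out(n_saved), ekin_out(n_saved),
      ekin_mid_out(n_saved);
  NumericVector frames(static_cast<R_xlen_t>(n_saved) * n * 3);
  int isave = 0;
  int err_step = -1;

  auto kinetic = [&]() {
    double ke = 0;
    for (int i = 0; i < n; ++i)
      ke += 0.5 / minv[i] *
            (v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
             v[3 * i + 2] * v[3 * i + 2]);
    return ke;
  };
  double ke_mid = 0.0;  // KE at the thermostat (O) midpoint of the step
  auto save_frame = [&](int step, double epot) {
    times[isave] = step * dt;
    epot_out[isave] = epot;
    ekin_out[isave] = kinetic();
    ekin_mid_out[isave] = (step == 0) ? ekin_out[isave] : ke_mid;
    R_xlen_t off = static_cast<R_xlen_t>(isave) * n * 3;
    for (int i = 0; i < 3 * n; ++i) frames[off + i] = x[i];
    ++isave;
  };

  double epot = s.forces(x, f);
  if (!std::isfinite(epot) || epot > 1e12) {
    return List::create(_["error_step"] = 0, _["frames"] = R_NilValue);
  }
  save_frame(0, epot);
  double half = 0.5 * dt;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      v[3 * i] += half * f[3 * i] * minv[i];
      v[3 * i + 1] += half * f[3 * i + 1] * minv[i];
      v[3 * i + 2] += half * f[3 * i + 2] * minv[i];
    }
    for (int i = 0; i < 3 * n; ++i) x[i] += half * v[i];
    double ke_before = kinetic();
    if (noise) {
      for (int i = 0; i < n; ++i) {
        v[3 * i] = c1 * v[3 * i] + c2 * sig[i] * norm_rand();
        v[3 * i + 1] = c1 * v[3 * i + 1] + c2 * sig[i] * norm_rand();
        v[3 * i + 2] = c1 * v[3 * i + 2] + c2 * sig[i] * norm_rand();
      }
    } else if (c1 < 1.0) {
      for (int i = 0; i < 3 * n; ++i) v[i] *= c1;
    }
    ke_mid = 0.5 * (ke_before + kinetic());
    for (int i = 0; i < 3 * n; ++i) x[i] += half * v[i];
    epot = s.forces(x, f);
    // non-finite or absurdly large energies mean the integration diverged
    if (!std::isfinite(epot) || epot > 1e12) { err_step = step; break; }
    for (int i = 0; i < n; ++i) {
      v[3 * i] += half * f[3 * i] * minv[i];
      v[3 * i + 1] += half * f[3 * i + 1] * minv[i];
      v[3 * i + 2] += half * f[3 * i + 2] * minv[i];
    }
    if (step % save_every == 0) save_frame(step, epot);
  }
  NumericMatrix P(n, 3), V(n, 3);
  for (int i = 0; i < n; ++i) {
    P(i, 0) = x[3 * i]; P(i, 1) = x[3 * i + 1]; P(i, 2) = x[3 * i + 2];
    V(i, 0) = v[3 * i]; V(i, 1) = v[3 * i + 1]; V(i, 2) = v[3 * i + 2];
  }
  frames.attr("dim") = IntegerVector::create(3, n, n_saved);
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["epot"] = epot_out, _["ekin"] = ekin_out,
                      _["ekin_mid"] = ekin_mid_out,
                      _["final_positions"] = P, _["final_velocities"] = V,
                      _["n_saved"] = isave, _["error_step"] = err_step);
}

// Discrete Gauss linking double sum over segment midpoints:
//   g = (1/4pi) sum_a sum_b (m_a - m_b) . (t_a x t_b) / |m_a - m_b|^3
// [[Rcpp::export]]
double gauss_linking_cpp(NumericMatrix A, NumericMatrix B, bool closed_a,
                         bool closed_b) {
  int na = A.nrow(), nb = B.nrow();
  int sa = closed_a ? na : na - 1;
  int sb = closed_b ? nb : nb - 1;
  std::vector<Vec3> ma(sa), ta(sa), mb(sb), tb(sb);
  for (int i = 0; i < sa; ++i) {
    int j = (i + 1) % na;
    ta[i] = {A(j, 0) - A(i, 0), A(j, 1) - A(i, 1), A(j, 2) - A(i, 2)};
    ma[i] = {0.5 * (A(j, 0) + A(i, 0)), 0.5 * (A(j, 1) + A(i, 1)),
             0.5 * (A(j, 2) + A(i, 2))};
    if (vnorm(ta[i]) < 1e-9) stop("degenerate (zero-length) segment in curve A");
  }
  for (int i = 0; i < sb; ++i) {
    int j = (i + 1) % nb;
    tb[i] = {B(j, 0) - B(i, 0), B(j, 1) - B(i, 1), B(j, 2) - B(i, 2)};
    mb[i] = {0.5 * (B(j, 0) + B(i, 0)), 0.5 * (B(j, 1) + B(i, 1)),
             0.5 * (B(j, 2) + B(i, 2))};
    if (vnorm(tb[i]) < 1e-9) stop("degenerate (zero-length) segment in curve B");
  }
  double g = 0.0;
  for (int i = 0; i < sa; ++i) {
    for (int j = 0; j < sb; ++j) {
      Vec3 d = vsub(ma[i], mb[j]);
      double r = vnorm(d);
      if (r < 1e-9) continue;  // coincident midpoints contribute nothing
      Vec3 c = vcross(ta[i], tb[j]);
      g += vdot(d, c) / (r * r * r);
    }
  }
  return g / (4.0 * M_PI);
}
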