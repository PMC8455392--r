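// Axisymmetric biphasic (u-p) finite-element core for the FRPE model.
// Taylor-Hood Q9 (biquadratic displacement) / Q4 (bilinear pressure)
// quadrilaterals, finite-strain kinematics (small-strain mode available for
// linear verification problems), backward-Euler time integration of the
// fluid mass balance, Newton iteration with finite-difference element
// tangents and time-step bisection on non-convergence.
//
// Units: mm, MPa, s, N. Permeability passed in mm^2/(MPa s).

#include <RcppArmadillo.h>
using namespace arma;

struct Material {
  double Ef0, EfEps, Enf, nu, k0, M;
  bool fibrils;
  bool finite_strain;
};

static const int NGP = 9;
// 3-point Gauss in 1D
static const double GX[3] = {-0.774596669241483, 0.0, 0.774596669241483};
static const double GW[3] = {5.0 / 9.0, 8.0 / 9.0, 5.0 / 9.0};

// Precomputed shape tables at the 9 Gauss points
struct ShapeTables {
  double N9[NGP][9], dN9[NGP][9][2];
  double N4[NGP][4], dN4[NGP][4][2];
  double w[NGP];
};

static ShapeTables g_shape;
static bool g_shape_init = false;

static void init_shape_tables() {
  if (g_shape_init) return;
  for (int gj = 0; gj < 3; ++gj) {
    for (int gi = 0; gi < 3; ++gi) {
      int g = gj * 3 + gi;
      double xi = GX[gi], eta = GX[gj];
      g_shape.w[g] = GW[gi] * GW[gj];
      // 1D quadratic Lagrange at nodes -1, 0, 1
      double L[3]  = {xi * (xi - 1) / 2, 1 - xi * xi, xi * (xi + 1) / 2};
      double dL[3] = {xi - 0.5, -2 * xi, xi + 0.5};
      double Me[3]  = {eta * (eta - 1) / 2, 1 - eta * eta, eta * (eta + 1) / 2};
      double dMe[3] = {eta - 0.5, -2 * eta, eta + 0.5};
      for (int j = 0; j < 3; ++j)
        for (int i = 0; i < 3; ++i) {
          int k = j * 3 + i;
          g_shape.N9[g][k] = L[i] * Me[j];
          g_shape.dN9[g][k][0] = dL[i] * Me[j];
          g_shape.dN9[g][k][1] = L[i] * dMe[j];
        }
      double P[2] = {(1 - xi) / 2, (1 + xi) / 2};
      double dP[2] = {-0.5, 0.5};
      double Q[2] = {(1 - eta) / 2, (1 + eta) / 2};
      double dQ[2] = {-0.5, 0.5};
      for (int j = 0; j < 2; ++j)
        for (int i = 0; i < 2; ++i) {
          int k = j * 2 + i;
          g_shape.N4[g][k] = P[i] * Q[j];
          g_shape.dN4[g][k][0] = dP[i] * Q[j];
          g_shape.dN4[g][k][1] = P[i] * dQ[j];
        }
    }
  }
  g_shape_init = true;
}

// Cauchy stress of the solid skeleton (non-fibrillar + fibrils), axisymmetric
// Voigt order rr, zz, tt, rz. F2 is the in-plane deformation gradient, Fth
// the hoop stretch. Returns false on degenerate deformation (J <= 0).
static bool solid_stress(const Material& m, const double F2[2][2], double Fth,
                         double sig[4], double* Jout) {
  double mu = m.Enf / (2.0 * (1.0 + m.nu));
  double lam = m.Enf * m.nu / ((1.0 + m.nu) * (1.0 - 2.0 * m.nu));
  if (m.finite_strain) {
    double det2 = F2[0][0] * F2[1][1] - F2[0][1] * F2[1][0];
    double J = Fth * det2;
    if (!(J > 0.0) || !std::isfinite(J)) return false;
    *Jout = J;
    double Brr = F2[0][0] * F2[0][0] + F2[0][1] * F2[0][1];
    double Bzz = F2[1][0] * F2[1][0] + F2[1][1] * F2[1][1];
    double Brz = F2[0][0] * F2[1][0] + F2[0][1] * F2[1][1];
    double Btt = Fth * Fth;
    double c = lam * std::log(J) / J;
    sig[0] = mu / J * (Brr - 1.0) + c;
    sig[1] = mu / J * (Bzz - 1.0) + c;
    sig[2] = mu / J * (Btt - 1.0) + c;
    sig[3] = mu / J * Brz;
    if (m.fibrils) {
      // radial family: reference direction e_R, deformed to column 1 of F
      double a0 = F2[0][0], a1 = F2[1][0];
      double lr = std::sqrt(a0 * a0 + a1 * a1);
      double ef = lr - 1.0;
      if (ef > 0.0) {
        double s = (m.Ef0 + m.EfEps * ef) * ef;
        double ar = a0 / lr, az = a1 / lr;
        sig[0] += s * ar * ar;
        sig[1] += s * az * az;
        sig[3] += s * ar * az;
      }
      double eh = Fth - 1.0;
      if (eh > 0.0) sig[2] += (m.Ef0 + m.EfEps * eh) * eh;
    }
  } else {
    double err = F2[0][0] - 1.0, ezz = F2[1][1] - 1.0;
    double erz = 0.5 * (F2[0][1] + F2[1][0]);
    double ett = Fth - 1.0;
    double tr = err + ezz + ett;
    *Jout = 1.0 + tr;
    sig[0] = 2.0 * mu * err + lam * tr;
    sig[1] = 2.0 * mu * ezz + lam * tr;
    sig[2] = 2.0 * mu * ett + lam * tr;
    sig[3] = 2.0 * mu * erz;
    if (m.fibrils) {
      if (err > 0.0) sig[0] += (m.Ef0 + m.EfEps * err) * err;
      if (ett > 0.0) sig[2] += (m.Ef0 + m.EfEps * ett) * ett;
    }
  }
  return true;
}

// Element residual. Xe: 9x2 reference coords (column-major double[18]),
// ue/ue_n: 18 displacement dofs (r,z interleaved per node), pe: 4 pressures.
// Adds nothing; writes Ru[18], Rp[4]. Returns false on degenerate state.
static bool elem_residual(const double* Xr, const double* Xz,
                          const double* ue, const double* ue_n,
                          const double* pe, const Material& m,
                          double dt, bool transient,
                          double Ru[18], double Rp[4]) {
  for (int i = 0; i < 18; ++i) Ru[i] = 0.0;
  for (int i = 0; i < 4; ++i) Rp[i] = 0.0;
  const bool fin = m.finite_strain;
  for (int g = 0; g < NGP; ++g) {
    const double* N = g_shape.N9[g];
    // geometry (reference)
    double Jr[2][2] = {{0, 0}, {0, 0}};
    double Rg = 0.0;
    for (int a = 0; a < 9; ++a) {
      const double dNx = g_shape.dN9[g][a][0], dNe = g_shape.dN9[g][a][1];
      Jr[0][0] += Xr[a] * dNx; Jr[0][1] += Xr[a] * dNe;
      Jr[1][0] += Xz[a] * dNx; Jr[1][1] += Xz[a] * dNe;
      Rg += Xr[a] * N[a];
    }
    double detJr = Jr[0][0] * Jr[1][1] - Jr[0][1] * Jr[1][0];
    if (!(detJr > 0.0)) return false;
    double Ji[2][2] = {{ Jr[1][1] / detJr, -Jr[0][1] / detJr},
                       {-Jr[1][0] / detJr,  Jr[0][0] / detJr}};
    // dN/dX and interpolated u, grad u
    double dNdX[9][2];
    double ur = 0.0, H[2][2] = {{0, 0}, {0, 0}};
    double ur_n = 0.0, Hn[2][2] = {{0, 0}, {0, 0}};
    for (int a = 0; a < 9; ++a) {
      double dx = g_shape.dN9[g][a][0] * Ji[0][0] + g_shape.dN9[g][a][1] * Ji[1][0];
      double dz = g_shape.dN9[g][a][0] * Ji[0][1] + g_shape.dN9[g][a][1] * Ji[1][1];
      dNdX[a][0] = dx; dNdX[a][1] = dz;
      double uar = ue[2 * a], uaz = ue[2 * a + 1];
      ur += N[a] * uar;
      H[0][0] += uar * dx; H[0][1] += uar * dz;
      H[1][0] += uaz * dx; H[1][1] += uaz * dz;
      if (transient) {
        double unr = ue_n[2 * a], unz = ue_n[2 * a + 1];
        ur_n += N[a] * unr;
        Hn[0][0] += unr * dx; Hn[0][1] += unr * dz;
        Hn[1][0] += unz * dx; Hn[1][1] += unz * dz;
      }
    }
    double F2[2][2] = {{1.0 + H[0][0], H[0][1]}, {H[1][0], 1.0 + H[1][1]}};
    double Fth = 1.0 + ur / Rg;
    double sig[4], J;
    if (!solid_stress(m, F2, Fth, sig, &J)) return false;
    double p = 0.0;
    const double* N4 = g_shape.N4[g];
    for (int b = 0; b < 4; ++b) p += N4[b] * pe[b];
    sig[0] -= p; sig[1] -= p; sig[2] -= p;

    // current configuration for spatial gradients (finite strain); reference
    // configuration in the small-strain mode
    double dNdx[9][2], r_cur, detJc;
    if (fin) {
      double Jc[2][2] = {{0, 0}, {0, 0}};
      r_cur = 0.0;
      for (int a = 0; a < 9; ++a) {
        double xr = Xr[a] + ue[2 * a], xz = Xz[a] + ue[2 * a + 1];
        const double dNx = g_shape.dN9[g][a][0], dNe = g_shape.dN9[g][a][1];
        Jc[0][0] += xr * dNx; Jc[0][1] += xr * dNe;
        Jc[1][0] += xz * dNx; Jc[1][1] += xz * dNe;
        r_cur += xr * N[a];
      }
      detJc = Jc[0][0] * Jc[1][1] - Jc[0][1] * Jc[1][0];
      if (!(detJc > 0.0) || !(r_cur > 0.0)) return false;
      double Jci[2][2] = {{ Jc[1][1] / detJc, -Jc[0][1] / detJc},
                          {-Jc[1][0] / detJc,  Jc[0][0] / detJc}};
      for (int a = 0; a < 9; ++a) {
        dNdx[a][0] = g_shape.dN9[g][a][0] * Jci[0][0] + g_shape.dN9[g][a][1] * Jci[1][0];
        dNdx[a][1] = g_shape.dN9[g][a][0] * Jci[0][1] + g_shape.dN9[g][a][1] * Jci[1][1];
      }
    } else {
      for (int a = 0; a < 9; ++a) { dNdx[a][0] = dNdX[a][0]; dNdx[a][1] = dNdX[a][1]; }
      r_cur = Rg; detJc = detJr;
    }
    double wv = g_shape.w[g] * 2.0 * M_PI * r_cur * detJc;

    for (int a = 0; a < 9; ++a) {
      Ru[2 * a]     += wv * (dNdx[a][0] * sig[0] + dNdx[a][1] * sig[3] +
                             N[a] / r_cur * sig[2]);
      Ru[2 * a + 1] += wv * (dNdx[a][0] * sig[3] + dNdx[a][1] * sig[1]);
    }

    if (transient) {
      // volumetric rate (J - J_n) / (J dt); small strain: tr(eps) rate
      double Jn;
      if (fin) {
        double F2n[2][2] = {{1.0 + Hn[0][0], Hn[0][1]},
                            {Hn[1][0], 1.0 + Hn[1][1]}};
        double det2n = F2n[0][0] * F2n[1][1] - F2n[0][1] * F2n[1][0];
        Jn = (1.0 + ur_n / Rg) * det2n;
      } else {
        Jn = 1.0 + Hn[0][0] + Hn[1][1] + ur_n / Rg;
      }
      double vol_rate = fin ? (J - Jn) / (J * dt) : (J - Jn) / dt;
      double k = m.k0 * std::pow(J, m.M);  // (1+e)/(1+e0) = J
      // pressure shape gradients through the same isoparametric map as the
      // displacement (spatial in finite strain, reference in small strain)
      double dN4dx[4][2], gpr = 0.0, gpz = 0.0;
      {
        double Jm[2][2] = {{0, 0}, {0, 0}};
        if (fin) {
          for (int a = 0; a < 9; ++a) {
            double xr = Xr[a] + ue[2 * a], xz = Xz[a] + ue[2 * a + 1];
            const double dNx = g_shape.dN9[g][a][0], dNe = g_shape.dN9[g][a][1];
            Jm[0][0] += xr * dNx; Jm[0][1] += xr * dNe;
            Jm[1][0] += xz * dNx; Jm[1][1] += xz * dNe;
          }
        } else {
          Jm[0][0] = Jr[0][0]; Jm[0][1] = Jr[0][1];
          Jm[1][0] = Jr[1][0]; Jm[1][1] = Jr[1][1];
        }
        double dJ = Jm[0][0] * Jm[1][1] - Jm[0][1] * Jm[1][0];
        double Jmi[2][2] = {{ Jm[1][1] / dJ, -Jm[0][1] / dJ},
                            {-Jm[1][0] / dJ,  Jm[0][0] / dJ}};
        for (int b = 0; b < 4; ++b) {
          dN4dx[b][0] = g_shape.dN4[g][b][0] * Jmi[0][0] + g_shape.dN4[g][b][1] * Jmi[1][0];
          dN4dx[b][1] = g_shape.dN4[g][b][0] * Jmi[0][1] + g_shape.dN4[g][b][1] * Jmi[1][1];
          gpr += dN4dx[b][0] * pe[b];
          gpz += dN4dx[b][1] * pe[b];
        }
      }
      for (int b = 0; b < 4; ++b) {
        Rp[b] += wv * (N4[b] * vol_rate +
                       k * (dN4dx[b][0] * gpr + dN4dx[b][1] * gpz));
      }
    }
  }
  return true;
}

struct Problem {
  mat nodes;        // nn x 2
  imat elems;       // ne x 9, 0-based
  imat pelems;      // ne x 4, 0-based
  int nn, np, ne, ndof;
  Material m;
  uvec free_idx;
  std::vector<int> drive;     // u-dofs driven by w(t)
  std::vector<bool> is_fixed; // all constrained dofs
};

// assemble global residual; returns false on degenerate element state
static bool assemble_residual(const Problem& pb, const vec& d, const vec& dn,
                              double dt, bool transient, vec& R) {
  R.zeros(pb.ndof);
  double Ru[18], Rp[4], Xr[9], Xz[9], ue[18], uen[18], pe[4];
  for (int e = 0; e < pb.ne; ++e) {
    for (int a = 0; a < 9; ++a) {
      int n = pb.elems(e, a);
      Xr[a] = pb.nodes(n, 0); Xz[a] = pb.nodes(n, 1);
      ue[2 * a] = d(2 * n); ue[2 * a + 1] = d(2 * n + 1);
      uen[2 * a] = dn(2 * n); uen[2 * a + 1] = dn(2 * n + 1);
    }
    for (int b = 0; b < 4; ++b) pe[b] = d(2 * pb.nn + pb.pelems(e, b));
    if (!elem_residual(Xr, Xz, ue, uen, pe, pb.m, dt, transient, Ru, Rp))
      return false;
    for (int a = 0; a < 9; ++a) {
      int n = pb.elems(e, a);
      R(2 * n) += Ru[2 * a];
      R(2 * n + 1) += Ru[2 * a + 1];
    }
    for (int b = 0; b < 4; ++b) R(2 * pb.nn + pb.pelems(e, b)) += Rp[b];
  }
  return true;
}

// assemble residual and dense tangent by element-level forward differences
static bool assemble_system(const Problem& pb, const vec& d, const vec& dn,
                            double dt, bool transient, vec& R, mat& K) {
  R.zeros(pb.ndof);
  K.zeros(pb.ndof, pb.ndof);
  double Ru0[18], Rp0[4], Ru1[18], Rp1[4];
  double Xr[9], Xz[9], ue[18], uen[18], pe[4];
  int gdof[22];
  for (int e = 0; e < pb.ne; ++e) {
    for (int a = 0; a < 9; ++a) {
      int n = pb.elems(e, a);
      Xr[a] = pb.nodes(n, 0); Xz[a] = pb.nodes(n, 1);
      ue[2 * a] = d(2 * n); ue[2 * a + 1] = d(2 * n + 1);
      uen[2 * a] = dn(2 * n); uen[2 * a + 1] = dn(2 * n + 1);
      gdof[2 * a] = 2 * n; gdof[2 * a + 1] = 2 * n + 1;
    }
    for (int b = 0; b < 4; ++b) {
      pe[b] = d(2 * pb.nn + pb.pelems(e, b));
      gdof[18 + b] = 2 * pb.nn + pb.pelems(e, b);
    }
    if (!elem_residual(Xr, Xz, ue, uen, pe, pb.m, dt, transient, Ru0, Rp0))
      return false;
    for (int a = 0; a < 9; ++a) {
      R(gdof[2 * a]) += Ru0[2 * a];
      R(gdof[2 * a + 1]) += Ru0[2 * a + 1];
    }
    for (int b = 0; b < 4; ++b) R(gdof[18 + b]) += Rp0[b];

    for (int j = 0; j < 22; ++j) {
      if (pb.is_fixed[gdof[j]]) continue;  // columns of fixed dofs not needed
      double* slot = (j < 18) ? &ue[j] : &pe[j - 18];
      double old = *slot;
      double hstep = 1e-7 * (1.0 + std::abs(old));
      *slot = old + hstep;
      bool ok = elem_residual(Xr, Xz, ue, uen, pe, pb.m, dt, transient, Ru1, Rp1);
      *slot = old;
      if (!ok) return false;
      double inv_h = 1.0 / hstep;
      int cj = gdof[j];
      for (int a = 0; a < 18; ++a)
        K(gdof[a], cj) += (Ru1[a] - Ru0[a]) * inv_h;
      for (int b = 0; b < 4; ++b)
        K(gdof[18 + b], cj) += (Rp1[b] - Rp0[b]) * inv_h;
    }
  }
  return true;
}

// Newton solve of one time increment; d holds BCs already applied.
// Returns 0 ok, 1 no convergence, 2 degenerate/singular.
static int newton_increment(const Problem& pb, vec& d, const vec& dn,
                            double dt, bool transient,
                            double tol, int max_iter) {
  vec R;
  mat K;
  double uscale = std::max(1e-3, arma::abs(d.subvec(0, 2 * pb.nn - 1)).max());
  for (int it = 0; it < max_iter; ++it) {
    if (!assemble_system(pb, d, dn, dt, transient, R, K)) return 2;
    mat Kff = K.submat(pb.free_idx, pb.free_idx);
    vec Rf = R.elem(pb.free_idx);
    vec delta;
    bool ok = solve(delta, Kff, Rf, solve_opts::no_approx);
    if (!ok || !delta.is_finite()) return 2;
    d.elem(pb.free_idx) -= delta;
    double du = 0.0, dp = 0.0;
    for (uword i = 0; i < pb.free_idx.n_elem; ++i) {
      double v = std::abs(delta(i));
      if ((int)pb.free_idx(i) < 2 * pb.nn) du = std::max(du, v);
      else dp = std::max(dp, v);
    }
    double pscale = std::max(1e-3,
        pb.np > 0 ? arma::abs(d.subvec(2 * pb.nn, pb.ndof - 1)).max() : 0.0);
    if (du < tol * uscale && dp < tol * pscale) return 0;
  }
  return 1;
}

static Material material_from_list(const Rcpp::List& ml) {
  Material m;
  m.Ef0 = ml["Ef0"]; m.EfEps = ml["EfEps"]; m.Enf = ml["Enf"];
  m.nu = ml["nu_nf"]; m.k0 = ml["k0_int"]; m.M = ml["M"];
  m.fibrils = ml["fibrils"];
  m.finite_strain = ml["finite_strain"];
  return m;
}

// [[Rcpp::export]]
Rcpp::List cpp_simulate_path(const arma::mat& nodes, const arma::imat& elems,
                             const arma::imat& pelems, int np,
                             const arma::ivec& fix_dof,
                             const arma::ivec& drive_dof,
                             const Rcpp::List& material,
                             const arma::vec& times, const arma::vec& wvals,
                             const arma::vec& d0, bool transient,
                             double tol, int max_iter, int max_bisect) {
  init_shape_tables();
  Problem pb;
  pb.nodes = nodes; pb.elems = elems; pb.pelems = pelems;
  pb.nn = nodes.n_rows; pb.np = np; pb.ne = elems.n_rows;
  pb.ndof = 2 * pb.nn + np;
  pb.m = material_from_list(material);
  pb.is_fixed.assign(pb.ndof, false);
  for (uword i = 0; i < fix_dof.n_elem; ++i) pb.is_fixed[fix_dof(i)] = true;
  pb.drive.clear();
  for (uword i = 0; i < drive_dof.n_elem; ++i) {
    pb.is_fixed[drive_dof(i)] = true;
    pb.drive.push_back(drive_dof(i));
  }
  std::vector<uword> fr;
  for (int i = 0; i < pb.ndof; ++i) if (!pb.is_fixed[i]) fr.push_back(i);
  pb.free_idx = uvec(fr);

  int nT = times.n_elem;
  vec d = d0;
  if ((int)d.n_elem != pb.ndof) Rcpp::stop("bad initial state length");
  vec force(nT, fill::zeros);
  vec R;

  // force at the initial state
  if (!assemble_residual(pb, d, d, 1.0, false, R))
    Rcpp::stop("degenerate initial state");
  double f0 = 0.0;
  for (int dof : pb.drive) f0 -= R(dof);
  force(0) = f0;

  double tc = times(0), wc = wvals(0);
  vec dn = d;
  for (int s = 1; s < nT; ++s) {
    double tt = times(s), wt = wvals(s);
    // bisection stack of pending targets
    std::vector<std::pair<double, double>> stack;
    stack.push_back({tt, wt});
    int inserted = 0;
    while (!stack.empty()) {
      Rcpp::checkUserInterrupt();
      double t_try = stack.back().first, w_try = stack.back().second;
      double dt = t_try - tc;
      if (dt <= 0) Rcpp::stop("non-increasing time grid");
      vec d_try = dn;
      for (int dof : pb.drive) d_try(dof) = w_try;
      int status = newton_increment(pb, d_try, dn, dt, transient, tol, max_iter);
      if (status == 0) {
        stack.pop_back();
        tc = t_try; wc = w_try; dn = d_try;
      } else {
        if (++inserted > (1 << max_bisect))
          Rcpp::stop("Newton failed to converge at t = %g (step %d)", t_try, s);
        stack.push_back({tc + dt / 2.0, wc + (w_try - wc) / 2.0});
      }
    }
    if (!assemble_residual(pb, dn, dn, 1.0, false, R))
      Rcpp::stop("degenerate state after convergence");
    double f = 0.0;
    for (int dof : pb.drive) f -= R(dof);
    force(s) = f;
  }

  return Rcpp::List::create(Rcpp::Named("force") = force,
                            Rcpp::Named("state") = dn);
}

// Direct material-point evaluation for cross-checks against the R-level
// constitutive functions. Returns total Cauchy stress (rr, zz, tt, rz).
// [[Rcpp::export]]
arma::vec cpp_point_stress(const arma::mat& F2, double Fth, double p,
                           const Rcpp::List& material) {
  Material m = material_from_list(material);
  double F[2][2] = {{F2(0, 0), F2(0, 1)}, {F2(1, 0), F2(1, 1)}};
  double sig[4], J;
  if (!solid_stress(m, F, Fth, sig, &J))
    Rcpp::stop("degenerate deformation");
  sig[0] -= p; sig[1] -= p; sig[2] -= p;
  return arma::vec({sig[0], sig[1], sig[2], sig[3]});
}
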