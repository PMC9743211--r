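// Toy force field and Langevin integrator for desk-scale bead-spring
// systems.  Units: length A, energy kJ/mol, time ps, mass amu.
// 1 kJ/mol = 100 amu A^2/ps^2, hence the factor KJU when converting
// forces to accelerations and kT to velocity variance.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KJU = 100.0; // (amu A^2/ps^2) per (kJ/mol)

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// Accumulate energy and (optionally) forces for one configuration.
// X is N x 3 (column-major from R).  F, if non-null, is N x 3.
static double ff_eval(const NumericMatrix& X, const List& ff,
                      NumericMatrix* F) {
  const int N = X.nrow();
  double U = 0.0;
  auto xat = [&](int i, double* out) {
    out[0] = X(i, 0); out[1] = X(i, 1); out[2] = X(i, 2);
  };
  auto addf = [&](int i, const double* f, double w) {
    if (F) { (*F)(i, 0) += w * f[0]; (*F)(i, 1) += w * f[1]; (*F)(i, 2) += w * f[2]; }
  };

  if (ff.containsElementNamed("bonds") && !Rf_isNull(ff["bonds"])) {
    NumericMatrix B = ff["bonds"];
    for (int b = 0; b < B.nrow(); ++b) {
      int i = (int)B(b, 0) - 1, j = (int)B(b, 1) - 1;
      double kb = B(b, 2), r0 = B(b, 3);
      if (i < 0 || j < 0 || i >= N || j >= N)
        stop("bond %d references an atom outside the frame", b + 1);
      double d[3] = {X(i,0) - X(j,0), X(i,1) - X(j,1), X(i,2) - X(j,2)};
      double r = std::sqrt(dot3(d, d));
      U += 0.5 * kb * (r - r0) * (r - r0);
      if (F && r > 1e-12) {
        double c = -kb * (r - r0) / r; // force on i = -dU/dxi
        double f[3] = {c * d[0], c * d[1], c * d[2]};
        addf(i, f, 1.0); addf(j, f, -1.0);
      }
    }
  }

  if (ff.containsElementNamed("angles") && !Rf_isNull(ff["angles"])) {
    NumericMatrix A = ff["angles"];
    for (int a = 0; a < A.nrow(); ++a) {
      int i = (int)A(a, 0) - 1, j = (int)A(a, 1) - 1, k = (int)A(a, 2) - 1;
      double ka = A(a, 3), th0 = A(a, 4);
      if (i < 0 || j < 0 || k < 0 || i >= N || j >= N || k >= N)
        stop("angle %d references an atom outside the frame", a + 1);
      double u[3] = {X(i,0) - X(j,0), X(i,1) - X(j,1), X(i,2) - X(j,2)};
      double v[3] = {X(k,0) - X(j,0), X(k,1) - X(j,1), X(k,2) - X(j,2)};
      double nu = std::sqrt(dot3(u, u)), nv = std::sqrt(dot3(v, v));
      double c = dot3(u, v) / (nu * nv);
      c = std::max(-1.0, std::min(1.0, c));
      double th = std::acos(c);
      U += 0.5 * ka * (th - th0) * (th - th0);
      if (F) {
        double s = std::sqrt(std::max(1.0 - c * c, 1e-14));
        double pref = -ka * (th - th0); // = -dU/dtheta
        // dtheta/dxi = (c*u/nu^2 - v/(nu*nv)) / s
        double gi[3], gk[3];
        for (int d = 0; d < 3; ++d) {
          gi[d] = (c * u[d] / (nu * nu) - v[d] / (nu * nv)) / s;
          gk[d] = (c * v[d] / (nv * nv) - u[d] / (nu * nv)) / s;
        }
        double fi[3] = {pref * gi[0], pref * gi[1], pref * gi[2]};
        double fk[3] = {pref * gk[0], pref * gk[1], pref * gk[2]};
        double fj[3] = {-(fi[0] + fk[0]), -(fi[1] + fk[1]), -(fi[2] + fk[2])};
        addf(i, fi, 1.0); addf(k, fk, 1.0); addf(j, fj, 1.0);
      }
    }
  }

  if (ff.containsElementNamed("dihedrals") && !Rf_isNull(ff["dihedrals"])) {
    NumericMatrix D = ff["dihedrals"];
    for (int t = 0; t < D.nrow(); ++t) {
      int i1 = (int)D(t, 0) - 1, i2 = (int)D(t, 1) - 1,
          i3 = (int)D(t, 2) - 1, i4 = (int)D(t, 3) - 1;
      double bar = D(t, 4);
      if (i1 < 0 || i4 >= N || i2 < 0 || i3 < 0 || i2 >= N || i3 >= N || i1 >= N || i4 < 0)
        stop("dihedral %d references an atom outside the frame", t + 1);
      double p1[3], p2[3], p3[3], p4[3];
      xat(i1, p1); xat(i2, p2); xat(i3, p3); xat(i4, p4);
      double b1[3] = {p2[0]-p1[0], p2[1]-p1[1], p2[2]-p1[2]};
      double b2[3] = {p3[0]-p2[0], p3[1]-p2[1], p3[2]-p2[2]};
      double b3[3] = {p4[0]-p3[0], p4[1]-p3[1], p4[2]-p3[2]};
      double n1[3], n2[3], m1[3];
      cross3(b1, b2, n1); cross3(b2, b3, n2);
      double lb2 = std::sqrt(dot3(b2, b2));
      cross3(n1, n2, m1);
      double phi = std::atan2(dot3(m1, b2) / lb2, dot3(n1, n2));
      // double well: U = 0.5 * barrier * (1 - cos(2 phi)); minima at 0, pi
      U += 0.5 * bar * (1.0 - std::cos(2.0 * phi));
      if (F) {
        double dU = bar * std::sin(2.0 * phi); // dU/dphi
        double ln1 = dot3(n1, n1), ln2 = dot3(n2, n2);
        if (ln1 < 1e-14 || ln2 < 1e-14) continue; // collinear: zero torque
        double g1[3], g4[3], g2[3], g3[3];
        double a12 = dot3(b1, b2) / (lb2 * lb2);
        double a32 = dot3(b3, b2) / (lb2 * lb2);
        for (int d = 0; d < 3; ++d) {
          g1[d] = -lb2 / ln1 * n1[d];
          g4[d] =  lb2 / ln2 * n2[d];
          g2[d] = -(1.0 + a12) * g1[d] + a32 * g4[d];
          g3[d] = a12 * g1[d] - (1.0 + a32) * g4[d];
        }
        double f1[3], f2[3], f3[3], f4[3];
        for (int d = 0; d < 3; ++d) {
          f1[d] = -dU * g1[d]; f2[d] = -dU * g2[d];
          f3[d] = -dU * g3[d]; f4[d] = -dU * g4[d];
        }
        addf(i1, f1, 1.0); addf(i2, f2, 1.0);
        addf(i3, f3, 1.0); addf(i4, f4, 1.0);
      }
    }
  }

  if (ff.containsElementNamed("lj") && !Rf_isNull(ff["lj"])) {
    NumericMatrix L = ff["lj"];
    for (int p = 0; p < L.nrow(); ++p) {
      int i = (int)L(p, 0) - 1, j = (int)L(p, 1) - 1;
      double eps = L(p, 2), sig = L(p, 3);
      if (i < 0 || j < 0 || i >= N || j >= N)
        stop("LJ pair %d references an atom outside the frame", p + 1);
      double d[3] = {X(i,0) - X(j,0), X(i,1) - X(j,1), X(i,2) - X(j,2)};
      double r2 = dot3(d, d);
      if (r2 < 1e-12)
        stop("singular geometry: coincident LJ pair (%d, %d)", i + 1, j + 1);
      double sr2 = sig * sig / r2;
      double sr6 = sr2 * sr2 * sr2;
      U += 4.0 * eps * (sr6 * sr6 - sr6);
      if (F) {
        // force on i = 24 eps (2 sr12 - sr6) / r2 * d
        double c = 24.0 * eps * (2.0 * sr6 * sr6 - sr6) / r2;
        double f[3] = {c * d[0], c * d[1], c * d[2]};
        addf(i, f, 1.0); addf(j, f, -1.0);
      }
    }
  }
  return U;
}

// [[Rcpp::export(name = ".ff_energy_cpp")]]
double ff_energy_cpp(NumericMatrix X, List ff) {
  return ff_eval(X, ff, nullptr);
}

// [[Rcpp::export(name = ".ff_forces_cpp")]]
NumericMatrix ff_forces_cpp(NumericMatrix X, List ff) {
  NumericMatrix F(X.nrow(), 3);
  ff_eval(X, ff, &F);
  return F;
}

// BAOAB splitting of underdamped Langevin dynamics.  Records every
// `stride` integration steps; uses R's RNG so set.seed() makes runs
// bit-reproducible.  Returns coordinates (nrec x N x 3), final
// positions and velocities.
// [[Rcpp::export(name = ".langevin_cpp")]]
List langevin_cpp(NumericMatrix X0, NumericMatrix V0, List ff,
                  NumericVector mass, double kT, double gamma,
                  double dt, int nsteps, int stride, double guard) {
  const int N = X0.nrow();
  NumericMatrix X(clone(X0)), V(clone(V0));
  const int nrec = nsteps / stride;
  NumericVector out(Dimension(nrec, N, 3));
  NumericMatrix F(N, 3);
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);
  std::vector<double> sdv(N), half_a(N);
  for (int i = 0; i < N; ++i) {
    sdv[i] = std::sqrt(KJU * kT / mass[i]);
    half_a[i] = 0.5 * dt * KJU / mass[i];
  }
  RNGScope scope;
  std::fill(F.begin(), F.end(), 0.0);
  ff_eval(X, ff, &F);
  int rec = 0;
  for (int s = 0; s < nsteps; ++s) {
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d)
        V(i, d) += half_a[i] * F(i, d);
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d)
        X(i, d) += 0.5 * dt * V(i, d);
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d)
        V(i, d) = c1 * V(i, d) + c2 * sdv[i] * R::norm_rand();
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d)
        X(i, d) += 0.5 * dt * V(i, d);
    std::fill(F.begin(), F.end(), 0.0);
    ff_eval(X, ff, &F);
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d)
        V(i, d) += half_a[i] * F(i, d);
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d)
        if (!std::isfinite(X(i, d)) || std::fabs(X(i, d)) > guard)
          stop("Langevin integration diverged at step %d (atom %d)",
               s + 1, i + 1);
    if ((s + 1) % stride == 0 && rec < nrec) {
      for (int i = 0; i < N; ++i)
        for (int d = 0; d < 3; ++d)
          out[rec + nrec * (i + N * d)] = X(i, d);
      ++rec;
    }
  }
  return List::create(_["coords"] = out, _["x_final"] = X,
                      _["v_final"] = V);
}
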