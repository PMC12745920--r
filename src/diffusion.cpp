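// Forward diffusion solver for allele-frequency densities in one and two
// populations. Time is measured in units of 2*N_ref generations; population
// sizes are relative to N_ref; migration rates are 2*N_ref*m. The density
// phi(x[,y]) is advanced by operator splitting: each axis is integrated
// implicitly (tridiagonal solve of a flux-conservative finite-volume
// discretisation), with the cross-population migration advection folded into
// the axis sweep it acts on. Mutations enter at the lowest-frequency interior
// cell at rate theta/2 (theta = 1 throughout; spectra are per unit theta).
//
// Boundary treatment: the scheme is zero-flux, so density lost or fixed in a
// population pools at the degenerate boundary nodes (x = 0, 1) where it
// correctly feeds the "absent/fixed in one population" spectrum entries.
// When migration points away from a boundary the local steady profile is the
// integrable power law x^(kappa-1), kappa = 2*nu*a (a the advection speed at
// the boundary); the advective weighting of the two boundary interfaces is
// chosen so the discrete zero-flux state reproduces the cell-averaged mass of
// that profile (a Chang-Cooper-style exactness condition). When advection
// points toward a boundary, the interface is upwinded on the interior node:
// the pooled delta sits at the boundary itself, where the advection speed
// vanishes, and must not be coupled into the advective flux.
//
// The per-axis implicit systems are tridiagonal; their LU factors depend on
// time only through the population sizes, so for constant-size epochs they
// are factorised once and reused across all time steps.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// pool/adjacent density ratio of the zero-flux power-law profile x^(kappa-1)
// averaged over the half-width boundary cell
static inline double pool_ratio(double kappa) {
  return std::pow(2.0, 1.0 - kappa) / kappa;
}

struct SweepFactors {
  // factorised (I/dt - L) systems, one tridiagonal system per grid line;
  // with no migration all lines coincide and a single system is shared
  int G;
  bool shared;
  std::vector<double> w;   // G x nline elimination multipliers
  std::vector<double> bp;  // G x nline modified diagonals
  std::vector<double> c;   // G x nline super-diagonals
};

// build advective interface weightings for one grid line
static void interface_deltas(const std::vector<double> &xx,
                             const std::vector<double> &V,
                             const std::vector<double> &Mh,
                             double nu, std::vector<double> &delta) {
  const int G = (int)xx.size();
  for (int i = 0; i < G - 1; ++i) delta[i] = 0.5;
  double dx0 = xx[1] - xx[0];
  if (Mh[0] < 0) delta[0] = 0.0;
  if (Mh[G - 2] > 0) delta[G - 2] = 1.0;
  if (Mh[0] > 0) {
    double kappa = 2.0 * nu * Mh[0];
    if (kappa < 500) {
      double R = pool_ratio(kappa);
      double num = V[1] / (2.0 * dx0 * Mh[0]) - 1.0;
      double d = (std::fabs(R - 1.0) < 1e-9) ? 1.0 / (1.0 + M_LN2)
                                             : num / (R - 1.0);
      delta[0] = std::min(1.0, std::max(0.0, d));
    } else {
      delta[0] = 1.0;
    }
  }
  double dxl = xx[G - 1] - xx[G - 2];
  if (Mh[G - 2] < 0) {
    double a = -Mh[G - 2];
    double kappa = 2.0 * nu * a;
    if (kappa < 500) {
      double R = pool_ratio(kappa);
      double num = V[G - 2] / (2.0 * dxl * a) - R;
      double d = (std::fabs(R - 1.0) < 1e-9) ? M_LN2 / (1.0 + M_LN2)
                                             : num / (1.0 - R);
      delta[G - 2] = std::min(1.0, std::max(0.0, d));
    } else {
      delta[G - 2] = 0.0;
    }
  }
}

// factorise the implicit system for every line of one sweep direction:
// line j has advection Mh_i = m * (z_j - xh_i) along the sweep axis
static void build_factors(const std::vector<double> &xx,
                          const std::vector<double> &dx,
                          const std::vector<double> &Del,
                          const std::vector<double> &xh,
                          double nu, double m, double dt,
                          SweepFactors &F) {
  const int G = (int)xx.size();
  std::vector<double> V(G), Mh(G - 1), delta(G - 1);
  std::vector<double> a(G), b(G), c(G);
  for (int i = 0; i < G; ++i) V[i] = xx[i] * (1.0 - xx[i]) / nu;
  F.shared = (m == 0.0);
  const int nline = F.shared ? 1 : G;
  for (int j = 0; j < nline; ++j) {
    double z = xx[j];
    for (int i = 0; i < G - 1; ++i) Mh[i] = m * (z - xh[i]);
    interface_deltas(xx, V, Mh, nu, delta);
    for (int i = 0; i < G; ++i) {
      double Lll = 0.0, Ldd = 0.0, Luu = 0.0;
      if (i > 0) {
        Lll = (Mh[i - 1] * delta[i - 1] + V[i - 1] / (2.0 * dx[i - 1])) / Del[i];
        Ldd = (Mh[i - 1] * (1.0 - delta[i - 1]) - V[i] / (2.0 * dx[i - 1])) / Del[i];
      }
      if (i < G - 1) {
        Ldd -= (Mh[i] * delta[i] + V[i] / (2.0 * dx[i])) / Del[i];
        Luu = -(Mh[i] * (1.0 - delta[i]) - V[i + 1] / (2.0 * dx[i])) / Del[i];
      }
      a[i] = -dt * Lll;
      b[i] = 1.0 - dt * Ldd;
      c[i] = -dt * Luu;
    }
    // Thomas forward elimination, stored for reuse
    double *w = &F.w[(size_t)j * G];
    double *bp = &F.bp[(size_t)j * G];
    double *cc = &F.c[(size_t)j * G];
    bp[0] = b[0];
    cc[0] = c[0];
    w[0] = 0.0;
    for (int i = 1; i < G; ++i) {
      w[i] = a[i] / bp[i - 1];
      bp[i] = b[i] - w[i] * c[i - 1];
      cc[i] = c[i];
    }
  }
}

// solve one factorised system in place (rhs r of length G)
static inline void solve_line(const SweepFactors &F, int j, double *r) {
  const int G = F.G;
  if (F.shared) j = 0;
  const double *w = &F.w[(size_t)j * G];
  const double *bp = &F.bp[(size_t)j * G];
  const double *cc = &F.c[(size_t)j * G];
  for (int i = 1; i < G; ++i) r[i] -= w[i] * r[i - 1];
  r[G - 1] /= bp[G - 1];
  for (int i = G - 2; i >= 0; --i) r[i] = (r[i] - cc[i] * r[i + 1]) / bp[i];
}

// Exponential interpolation of a relative size across an epoch.
static inline double nu_at(double nu_start, double nu_end, double frac) {
  if (nu_start == nu_end) return nu_start;
  return nu_start * std::pow(nu_end / nu_start, frac);
}

// [[Rcpp::export]]
NumericVector diff_integrate_1d(NumericVector phi_in, NumericVector xx_in, double T,
                                double nu_start, double nu_end, double dt_max,
                                bool inject) {
  const int G = xx_in.size();
  std::vector<double> xx(xx_in.begin(), xx_in.end());
  std::vector<double> phi(phi_in.begin(), phi_in.end());
  if (T <= 0) return phi_in;
  int nsteps = (int)std::ceil(T / dt_max);
  if (nsteps < 1) nsteps = 1;
  if (nsteps > 600) nsteps = 600;  // long runs approach equilibrium
  double dt = T / nsteps;

  std::vector<double> dx(G - 1), Del(G), xh(G - 1);
  for (int i = 0; i < G - 1; ++i) {
    dx[i] = xx[i + 1] - xx[i];
    xh[i] = 0.5 * (xx[i] + xx[i + 1]);
  }
  Del[0] = dx[0] / 2.0;
  Del[G - 1] = dx[G - 2] / 2.0;
  for (int i = 1; i < G - 1; ++i) Del[i] = (dx[i] + dx[i - 1]) / 2.0;

  SweepFactors F;
  F.G = G;
  F.w.resize((size_t)G * G);
  F.bp.resize((size_t)G * G);
  F.c.resize((size_t)G * G);
  bool constant = (nu_start == nu_end);
  if (constant) build_factors(xx, dx, Del, xh, nu_start, 0.0, dt, F);

  double inj = 0.5 * 2.0 / (xx[2] - xx[0]) / xx[1];
  for (int k = 0; k < nsteps; ++k) {
    if (!constant) {
      build_factors(xx, dx, Del, xh, nu_at(nu_start, nu_end, (k + 0.5) / nsteps),
                    0.0, dt, F);
    }
    if (inject) phi[1] += dt * inj;
    solve_line(F, 0, phi.data());
  }
  return NumericVector(phi.begin(), phi.end());
}

// [[Rcpp::export]]
NumericMatrix diff_integrate_2d(NumericMatrix phi_in, NumericVector xx_in, double T,
                                double nu1_start, double nu1_end, double nu2_start,
                                double nu2_end, double m12, double m21, double dt_max,
                                bool inject = true) {
  const int G = xx_in.size();
  std::vector<double> xx(xx_in.begin(), xx_in.end());
  NumericMatrix phi = clone(phi_in);
  double *P = REAL(phi);
  if (T <= 0) return phi;
  int nsteps = (int)std::ceil(T / dt_max);
  if (nsteps < 1) nsteps = 1;
  if (nsteps > 600) nsteps = 600;  // long runs approach equilibrium
  double dt = T / nsteps;

  std::vector<double> dx(G - 1), Del(G), xh(G - 1), buf(G);
  for (int i = 0; i < G - 1; ++i) {
    dx[i] = xx[i + 1] - xx[i];
    xh[i] = 0.5 * (xx[i] + xx[i + 1]);
  }
  Del[0] = dx[0] / 2.0;
  Del[G - 1] = dx[G - 2] / 2.0;
  for (int i = 1; i < G - 1; ++i) Del[i] = (dx[i] + dx[i - 1]) / 2.0;

  SweepFactors Fx, Fy;
  for (SweepFactors *F : {&Fx, &Fy}) {
    F->G = G;
    F->w.resize((size_t)G * G);
    F->bp.resize((size_t)G * G);
    F->c.resize((size_t)G * G);
  }
  bool const1 = (nu1_start == nu1_end);
  bool const2 = (nu2_start == nu2_end);
  if (const1) build_factors(xx, dx, Del, xh, nu1_start, m12, dt, Fx);
  if (const2) build_factors(xx, dx, Del, xh, nu2_start, m21, dt, Fy);

  double inj = 0.5 * 4.0 / ((xx[2] - xx[0]) * xx[1]) / xx[1];

  for (int k = 0; k < nsteps; ++k) {
    double frac = (k + 0.5) / nsteps;
    if (!const1) build_factors(xx, dx, Del, xh, nu_at(nu1_start, nu1_end, frac),
                               m12, dt, Fx);
    if (!const2) build_factors(xx, dx, Del, xh, nu_at(nu2_start, nu2_end, frac),
                               m21, dt, Fy);

    // new mutations arise private to one population
    if (inject) {
      P[1] += dt * inj;          // phi(1, 0)
      P[(size_t)G] += dt * inj;  // phi(0, 1)
    }

    // x sweep (population 1): columns are contiguous
    for (int j = 0; j < G; ++j) solve_line(Fx, j, P + (size_t)j * G);

    // y sweep (population 2): gather strided rows
    for (int i = 0; i < G; ++i) {
      for (int j = 0; j < G; ++j) buf[j] = P[(size_t)j * G + i];
      solve_line(Fy, i, buf.data());
      for (int j = 0; j < G; ++j) P[(size_t)j * G + i] = buf[j];
    }
  }
  return phi;
}
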