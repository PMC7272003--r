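// Core propagators: overdamped Langevin dynamics on piecewise-cubic
// one-dimensional potentials, dividing-surface shooting segments with
// crossing bookkeeping, and rigid-rod Brownian dynamics of a two-helix
// toy dimer confined to a membrane plane.
//
// All randomness comes from R's RNG (norm_rand/unif_rand), so set.seed()
// on the R side makes every trajectory reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Piecewise-cubic potential
//
// Knots are alternating extrema (zero slope at every knot); between knots
// V interpolates with the cubic smoothstep 3t^2 - 2t^3, so the stated knot
// positions are exact stationary points. Beyond the outer knots a harmonic
// confinement of stiffness kconf (slope-continuous) keeps the walker in the
// domain. An empty knot vector means a flat (free-diffusion) potential.
// ---------------------------------------------------------------------------

static inline double pw_value(double x, const double* kn, const double* va,
                              int nk, double kconf) {
  if (nk == 0) return 0.0;
  if (x <= kn[0]) {
    double d = x - kn[0];
    return va[0] + 0.5 * kconf * d * d;
  }
  if (x >= kn[nk - 1]) {
    double d = x - kn[nk - 1];
    return va[nk - 1] + 0.5 * kconf * d * d;
  }
  int lo = 0, hi = nk - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (kn[mid] <= x) lo = mid; else hi = mid;
  }
  double t = (x - kn[lo]) / (kn[lo + 1] - kn[lo]);
  double h = t * t * (3.0 - 2.0 * t);
  return va[lo] + (va[lo + 1] - va[lo]) * h;
}

static inline double pw_grad(double x, const double* kn, const double* va,
                             int nk, double kconf) {
  if (nk == 0) return 0.0;
  if (x <= kn[0]) return kconf * (x - kn[0]);
  if (x >= kn[nk - 1]) return kconf * (x - kn[nk - 1]);
  int lo = 0, hi = nk - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (kn[mid] <= x) lo = mid; else hi = mid;
  }
  double w = kn[lo + 1] - kn[lo];
  double t = (x - kn[lo]) / w;
  return (va[lo + 1] - va[lo]) * 6.0 * t * (1.0 - t) / w;
}

// [[Rcpp::export]]
NumericVector piecewise_value_cpp(NumericVector x, NumericVector knots,
                                  NumericVector vals, double kconf) {
  int n = x.size(), nk = knots.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = pw_value(x[i], knots.begin(), vals.begin(), nk, kconf);
  return out;
}

// [[Rcpp::export]]
NumericVector piecewise_grad_cpp(NumericVector x, NumericVector knots,
                                 NumericVector vals, double kconf) {
  int n = x.size(), nk = knots.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = pw_grad(x[i], knots.begin(), vals.begin(), nk, kconf);
  return out;
}

// ---------------------------------------------------------------------------
// Overdamped Euler-Maruyama propagator, optional harmonic umbrella bias.
// Returns the trajectory thinned by `thin` (frame 0 = initial point).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector sim_overdamped_cpp(NumericVector knots, NumericVector vals,
                                 double kconf, double D, double kT, double dt,
                                 double nsteps, double x0, int thin,
                                 double bias_center, double bias_k) {
  long long ns = (long long) nsteps;
  int nk = knots.size();
  const double* kn = knots.begin();
  const double* va = vals.begin();
  double lo_b = 0, hi_b = 0;
  bool check = nk > 0;
  if (check) {
    double W = std::max(kn[nk - 1] - kn[0], 1.0);
    lo_b = kn[0] - 10.0 * W;
    hi_b = kn[nk - 1] + 10.0 * W;
  }
  long long nrec = ns / thin + 1;
  NumericVector out(nrec);
  double x = x0;
  out[0] = x;
  double pref = -D / kT * dt;
  double noise = std::sqrt(2.0 * D * dt);
  long long irec = 1;
  for (long long s = 1; s <= ns; ++s) {
    double g = pw_grad(x, kn, va, nk, kconf);
    if (bias_k > 0) g += bias_k * (x - bias_center);
    x += pref * g + noise * norm_rand();
    if (check && (x < lo_b || x > hi_b))
      stop("trajectory diverged at step %lld (x = %g): time step too large "
           "for this potential", s, x);
    if (s % thin == 0) out[irec++] = x;
  }
  return out;
}

// ---------------------------------------------------------------------------
// One shooting segment on a 1D model: run until X enters basin A
// (x <= a_hi) or basin B (x >= b_lo), or until max_steps.  Records every
// crossing of `level` with its finite-difference speed, the sign of the
// first displacement from the level, and the (linearly interpolated)
// time of basin entry.
// Label codes: 0 = timeout, 1 = basin A, 2 = basin B.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List shoot_segment_cpp(NumericVector knots, NumericVector vals, double kconf,
                       double D, double kT, double dt, double x0, double level,
                       double a_hi, double b_lo, double max_steps, int thin,
                       double band_h) {
  long long ms = (long long) max_steps;
  int nk = knots.size();
  const double* kn = knots.begin();
  const double* va = vals.begin();
  double pref = -D / kT * dt;
  double noise = std::sqrt(2.0 * D * dt);
  std::vector<double> speeds;
  std::vector<double> path;
  path.push_back(x0);
  double x = x0;
  double occ = 0.0;
  double d0 = x0 - level;
  int last_sign = d0 > 0 ? 1 : (d0 < 0 ? -1 : 0);
  int first_sign = 0;
  int label = 0;
  double t_entry = NA_REAL;
  long long s;
  for (s = 1; s <= ms; ++s) {
    double xp = x;
    double g = pw_grad(x, kn, va, nk, kconf);
    x += pref * g + noise * norm_rand();
    double d = x - level;
    if (std::fabs(d) < band_h) occ += dt;
    if (d != 0.0) {
      int sg = d > 0 ? 1 : -1;
      if (first_sign == 0) first_sign = sg;
      if (last_sign != 0 && sg != last_sign)
        speeds.push_back(std::fabs(x - xp) / dt);
      last_sign = sg;
    }
    if (s % thin == 0) path.push_back(x);
    if (x <= a_hi) {
      label = 1;
      double frac = (xp > a_hi) ? (xp - a_hi) / (xp - x) : 0.0;
      t_entry = ((double)(s - 1) + frac) * dt;
      break;
    }
    if (x >= b_lo) {
      label = 2;
      double frac = (xp < b_lo) ? (b_lo - xp) / (x - xp) : 0.0;
      t_entry = ((double)(s - 1) + frac) * dt;
      break;
    }
  }
  if (label != 0 && (s % thin != 0)) path.push_back(x);
  return List::create(_["label"] = label,
                      _["time"] = t_entry,
                      _["steps"] = (double) std::min(s, ms),
                      _["cross_speeds"] = NumericVector(speeds.begin(), speeds.end()),
                      _["first_sign"] = first_sign,
                      _["occupation"] = occ,
                      _["path"] = NumericVector(path.begin(), path.end()));
}

// ---------------------------------------------------------------------------
// Toy dimer: two rigid rods of n beads each, centers in the membrane plane
// (z = 0), one in-plane rotation phi and one tilt psi per rod.  Periodic
// box (minimum image in x, y).  Interactions act between beads of
// different rods only:
//   - harmonic core repulsion below sig_rep,
//   - Gaussian attraction of per-pair amplitude amp[i][j] centred at r_att,
//   - harmonic tilt restraint 0.5 k_tilt psi^2 per rod (the membrane).
// State vector: (xA, yA, phiA, psiA, xB, yB, phiB, psiB).
// ---------------------------------------------------------------------------

struct DimerPar {
  int n;
  double spacing, L, k_rep, sig_rep, r_att, w_att, w_att_nat, k_tilt;
  double Dt, Dr, kT, dt, d_min;
  const double* amp;        // n x n nonspecific amplitudes ([i + n*j])
  const double* amp_nat;    // n x n native-bonus amplitudes
  int n_drms;
  const int* di; const int* dj; const double* dr0;  // drms reference pairs
  int a_lo, a_hi;           // anchor bead indices (0-based) for the dihedral
};

static DimerPar unpack_par(const List& par) {
  DimerPar p;
  p.n = as<int>(par["n_beads"]);
  p.spacing = as<double>(par["spacing"]);
  p.L = as<double>(par["box"]);
  p.k_rep = as<double>(par["k_rep"]);
  p.sig_rep = as<double>(par["sig_rep"]);
  p.r_att = as<double>(par["r_att"]);
  p.w_att = as<double>(par["w_att"]);
  p.w_att_nat = as<double>(par["w_att_nat"]);
  p.k_tilt = as<double>(par["k_tilt"]);
  p.Dt = as<double>(par["D_trans"]);
  p.Dr = as<double>(par["D_rot"]);
  p.kT = as<double>(par["kT"]);
  p.dt = as<double>(par["dt"]);
  p.d_min = as<double>(par["d_min"]);
  p.amp = REAL(as<NumericMatrix>(par["amp"]));
  p.amp_nat = REAL(as<NumericMatrix>(par["amp_nat"]));
  IntegerVector di = par["drms_i"], dj = par["drms_j"];
  NumericVector dr0 = par["drms_r0"];
  p.n_drms = di.size();
  p.di = INTEGER(di); p.dj = INTEGER(dj); p.dr0 = REAL(dr0);
  p.a_lo = as<int>(par["anchor_lo"]) - 1;
  p.a_hi = as<int>(par["anchor_hi"]) - 1;
  return p;
}

// bead positions of one rod; out is 3*n doubles (x,y,z per bead)
static inline void rod_beads(const double* s, int n, double spacing,
                             double* out) {
  double cph = std::cos(s[2]), sph = std::sin(s[2]);
  double cps = std::cos(s[3]), sps = std::sin(s[3]);
  double ax = cps * cph, ay = cps * sph, az = sps;
  double mid = 0.5 * (n - 1);
  for (int k = 0; k < n; ++k) {
    double o = (k - mid) * spacing;
    out[3 * k] = s[0] + o * ax;
    out[3 * k + 1] = s[1] + o * ay;
    out[3 * k + 2] = o * az;
  }
}

// Periodicity convention: chain B as a whole is translated to the image
// whose centre is nearest chain A's centre; all pair distances are then
// direct. (Rods are short relative to the box, so cross-image bead pairs
// are far outside every interaction range.) The same convention is used
// when exporting coordinates, so R-side CV code agrees bit-for-bit.
static inline void chain_shift(const double* s, double L, double* sh) {
  sh[0] = -L * std::round((s[4] - s[0]) / L);
  sh[1] = -L * std::round((s[5] - s[1]) / L);
}

// beads of chain B after the whole-chain image shift
static inline void rod_beads_B(const double* s, int n, double spacing,
                               double L, double* out) {
  double sh[2];
  chain_shift(s, L, sh);
  double sB[4] = {s[4] + sh[0], s[5] + sh[1], s[6], s[7]};
  // rod_beads defined below on generic 4-vector
  double cph = std::cos(sB[2]), sph = std::sin(sB[2]);
  double cps = std::cos(sB[3]), sps = std::sin(sB[3]);
  double ax = cps * cph, ay = cps * sph, az = sps;
  double mid = 0.5 * (n - 1);
  for (int k = 0; k < n; ++k) {
    double o = (k - mid) * spacing;
    out[3 * k] = sB[0] + o * ax;
    out[3 * k + 1] = sB[1] + o * ay;
    out[3 * k + 2] = o * az;
  }
}

// signed dihedral (IUPAC convention) of points p1..p4
static double dihedral4(const double* p1, const double* p2,
                        const double* p3, const double* p4) {
  double b1[3], b2[3], b3[3];
  for (int k = 0; k < 3; ++k) {
    b1[k] = p2[k] - p1[k];
    b2[k] = p3[k] - p2[k];
    b3[k] = p4[k] - p3[k];
  }
  double n1[3] = {b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                  b1[0]*b2[1]-b1[1]*b2[0]};
  double n2[3] = {b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                  b2[0]*b3[1]-b2[1]*b3[0]};
  double nb2 = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
  double m1[3] = {n1[1]*b2[2]-n1[2]*b2[1], n1[2]*b2[0]-n1[0]*b2[2],
                  n1[0]*b2[1]-n1[1]*b2[0]};
  double xx = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
  double yy = (m1[0]*n2[0]+m1[1]*n2[1]+m1[2]*n2[2]) / nb2;
  return std::atan2(yy, xx);
}

// energy, generalized forces (dU/ds), drms and theta for a dimer state.
// grad may be NULL. Umbrella bias on drms: 0.5*bk*(drms-bc)^2.
static double dimer_energy(const double* s, const DimerPar& p, double* grad,
                           double* drms_out, double* theta_out,
                           double bias_c, double bias_k) {
  int n = p.n;
  std::vector<double> A(3 * n), B(3 * n);
  rod_beads(s, n, p.spacing, A.data());
  rod_beads_B(s, n, p.spacing, p.L, B.data());
  double U = 0.0;
  if (grad) for (int k = 0; k < 8; ++k) grad[k] = 0.0;

  // tilt restraints
  U += 0.5 * p.k_tilt * (s[3] * s[3] + s[7] * s[7]);
  if (grad) { grad[3] += p.k_tilt * s[3]; grad[7] += p.k_tilt * s[7]; }

  // derivative helpers for chain A and B orientations
  double cphA = std::cos(s[2]), sphA = std::sin(s[2]);
  double cpsA = std::cos(s[3]), spsA = std::sin(s[3]);
  double cphB = std::cos(s[6]), sphB = std::sin(s[6]);
  double cpsB = std::cos(s[7]), spsB = std::sin(s[7]);
  double mid = 0.5 * (n - 1);

  // drms needs all reference-pair distances first
  std::vector<double> ddist(p.n_drms);
  double drms = 0.0;
  for (int q = 0; q < p.n_drms; ++q) {
    int i = p.di[q] - 1, j = p.dj[q] - 1;
    double dx = A[3*i] - B[3*j];
    double dy = A[3*i+1] - B[3*j+1];
    double dz = A[3*i+2] - B[3*j+2];
    double d = std::sqrt(dx*dx + dy*dy + dz*dz);
    ddist[q] = d;
    drms += (d - p.dr0[q]) * (d - p.dr0[q]);
  }
  drms = std::sqrt(drms / p.n_drms);
  if (drms_out) *drms_out = drms;
  if (theta_out) {
    *theta_out = dihedral4(&A[3*p.a_lo], &A[3*p.a_hi], &B[3*p.a_hi],
                           &B[3*p.a_lo]);
  }
  double bias_pref = 0.0;
  if (bias_k > 0) {
    U += 0.5 * bias_k * (drms - bias_c) * (drms - bias_c);
    if (drms > 1e-8)
      bias_pref = bias_k * (drms - bias_c) / (p.n_drms * drms);
  }

  // pairs beyond the attraction range contribute nothing: skip on the
  // squared distance before taking any square root
  double wmax = p.w_att > p.w_att_nat ? p.w_att : p.w_att_nat;
  double cut = p.r_att + 6.0 * wmax;
  if (p.sig_rep > cut) cut = p.sig_rep;
  double cut2 = cut * cut;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dx = A[3*i] - B[3*j];
      double dy = A[3*i+1] - B[3*j+1];
      double dz = A[3*i+2] - B[3*j+2];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > cut2) continue;
      double d = std::sqrt(d2);
      double dudd = 0.0;
      if (d < p.sig_rep) {
        double ov = p.sig_rep - d;
        U += 0.5 * p.k_rep * ov * ov;
        dudd -= p.k_rep * ov;
      }
      double a = p.amp[i + n * j];
      double dev = d - p.r_att;
      if (a != 0.0) {
        double e = std::exp(-dev * dev / (2.0 * p.w_att * p.w_att));
        U -= a * e;
        dudd += a * e * dev / (p.w_att * p.w_att);
      }
      double an = p.amp_nat[i + n * j];
      if (an != 0.0) {
        double en = std::exp(-dev * dev / (2.0 * p.w_att_nat * p.w_att_nat));
        U -= an * en;
        dudd += an * en * dev / (p.w_att_nat * p.w_att_nat);
      }
      if (!grad || dudd == 0.0 || d < 1e-12) continue;
      double ux = dx / d, uy = dy / d, uz = dz / d;
      double oi = (i - mid) * p.spacing, oj = (j - mid) * p.spacing;
      // chain A translations
      grad[0] += dudd * ux;
      grad[1] += dudd * uy;
      // chain A phi: d rA/d phi = oi * (-cpsA*sphA, cpsA*cphA, 0)
      grad[2] += dudd * oi * (-cpsA * sphA * ux + cpsA * cphA * uy);
      // chain A psi: d rA/d psi = oi * (-spsA*cphA, -spsA*sphA, cpsA)
      grad[3] += dudd * oi * (-spsA * cphA * ux - spsA * sphA * uy + cpsA * uz);
      // chain B (displacement enters with minus sign)
      grad[4] -= dudd * ux;
      grad[5] -= dudd * uy;
      grad[6] -= dudd * oj * (-cpsB * sphB * ux + cpsB * cphB * uy);
      grad[7] -= dudd * oj * (-spsB * cphB * ux - spsB * sphB * uy + cpsB * uz);
    }
  }

  // bias gradient handled exactly through the reference pairs
  if (grad && bias_pref != 0.0) {
    for (int q = 0; q < p.n_drms; ++q) {
      int i = p.di[q] - 1, j = p.dj[q] - 1;
      double dx = A[3*i] - B[3*j];
      double dy = A[3*i+1] - B[3*j+1];
      double dz = A[3*i+2] - B[3*j+2];
      double d = ddist[q];
      if (d < 1e-12) continue;
      double dudd = bias_pref * (d - p.dr0[q]);
      double ux = dx / d, uy = dy / d, uz = dz / d;
      double oi = (i - mid) * p.spacing, oj = (j - mid) * p.spacing;
      grad[0] += dudd * ux;
      grad[1] += dudd * uy;
      grad[2] += dudd * oi * (-cpsA * sphA * ux + cpsA * cphA * uy);
      grad[3] += dudd * oi * (-spsA * cphA * ux - spsA * sphA * uy + cpsA * uz);
      grad[4] -= dudd * ux;
      grad[5] -= dudd * uy;
      grad[6] -= dudd * oj * (-cpsB * sphB * ux + cpsB * cphB * uy);
      grad[7] -= dudd * oj * (-spsB * cphB * ux - spsB * sphB * uy + cpsB * uz);
    }
  }
  return U;
}

static bool dimer_overlap(const double* s, const DimerPar& p) {
  int n = p.n;
  std::vector<double> A(3 * n), B(3 * n);
  rod_beads(s, n, p.spacing, A.data());
  rod_beads_B(s, n, p.spacing, p.L, B.data());
  double dmin2 = p.d_min * p.d_min;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double dx = A[3*i] - B[3*j];
      double dy = A[3*i+1] - B[3*j+1];
      double dz = A[3*i+2] - B[3*j+2];
      if (dx*dx + dy*dy + dz*dz < dmin2) return true;
    }
  return false;
}

// one BD step with retry-on-overlap; returns false if retries exhausted
static bool dimer_step(double* s, const DimerPar& p) {
  double grad[8];
  dimer_energy(s, p, grad, nullptr, nullptr, 0.0, 0.0);
  double trial[8];
  double nt = std::sqrt(2.0 * p.Dt * p.dt), nr = std::sqrt(2.0 * p.Dr * p.dt);
  for (int attempt = 0; attempt < 100; ++attempt) {
    for (int c = 0; c < 8; ++c) {
      double D = (c % 4 < 2) ? p.Dt : p.Dr;
      double nn = (c % 4 < 2) ? nt : nr;
      trial[c] = s[c] - D / p.kT * grad[c] * p.dt + nn * norm_rand();
    }
    if (!dimer_overlap(trial, p)) {
      for (int c = 0; c < 8; ++c) s[c] = trial[c];
      return true;
    }
  }
  return false;
}

static bool dimer_step_biased(double* s, const DimerPar& p, double bias_c,
                              double bias_k) {
  double grad[8];
  dimer_energy(s, p, grad, nullptr, nullptr, bias_c, bias_k);
  double trial[8];
  double nt = std::sqrt(2.0 * p.Dt * p.dt), nr = std::sqrt(2.0 * p.Dr * p.dt);
  for (int attempt = 0; attempt < 100; ++attempt) {
    for (int c = 0; c < 8; ++c) {
      double D = (c % 4 < 2) ? p.Dt : p.Dr;
      double nn = (c % 4 < 2) ? nt : nr;
      trial[c] = s[c] - D / p.kT * grad[c] * p.dt + nn * norm_rand();
    }
    if (!dimer_overlap(trial, p)) {
      for (int c = 0; c < 8; ++c) s[c] = trial[c];
      return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
List sim_dimer_cpp(List par, NumericVector state0, double nsteps, int thin,
                   double bias_center, double bias_k) {
  DimerPar p = unpack_par(par);
  long long ns = (long long) nsteps;
  long long nrec = ns / thin + 1;
  NumericMatrix states(nrec, 8);
  NumericVector drms(nrec), theta(nrec);
  double s[8];
  for (int c = 0; c < 8; ++c) s[c] = state0[c];
  double dr, th;
  dimer_energy(s, p, nullptr, &dr, &th, 0.0, 0.0);
  for (int c = 0; c < 8; ++c) states(0, c) = s[c];
  drms[0] = dr; theta[0] = th;
  long long irec = 1;
  for (long long st = 1; st <= ns; ++st) {
    bool ok = (bias_k > 0) ? dimer_step_biased(s, p, bias_center, bias_k)
                           : dimer_step(s, p);
    if (!ok) stop("bead overlap persisted after 100 retries at step %lld", st);
    if (st % thin == 0) {
      dimer_energy(s, p, nullptr, &dr, &th, 0.0, 0.0);
      for (int c = 0; c < 8; ++c) states(irec, c) = s[c];
      drms[irec] = dr; theta[irec] = th;
      ++irec;
    }
  }
  return List::create(_["states"] = states, _["drms"] = drms,
                      _["theta"] = theta);
}

// [[Rcpp::export]]
List shoot_dimer_cpp(List par, NumericVector state0, double mu, double level,
                     double a_hi, double b_lo, double max_steps, int thin,
                     double band_h) {
  DimerPar p = unpack_par(par);
  long long ms = (long long) max_steps;
  std::vector<double> speeds, xs;
  std::vector<double> st_store;
  double s[8];
  for (int c = 0; c < 8; ++c) s[c] = state0[c];
  double dr, th;
  dimer_energy(s, p, nullptr, &dr, &th, 0.0, 0.0);
  double X = dr + mu * th;
  xs.push_back(X);
  for (int c = 0; c < 8; ++c) st_store.push_back(s[c]);
  double occ = 0.0;
  double d0 = X - level;
  int last_sign = d0 > 0 ? 1 : (d0 < 0 ? -1 : 0);
  int first_sign = 0, label = 0;
  double t_entry = NA_REAL;
  long long st;
  for (st = 1; st <= ms; ++st) {
    double Xp = X;
    if (!dimer_step(s, p))
      stop("bead overlap persisted after 100 retries at step %lld", st);
    dimer_energy(s, p, nullptr, &dr, &th, 0.0, 0.0);
    X = dr + mu * th;
    double d = X - level;
    if (std::fabs(d) < band_h) occ += p.dt;
    if (d != 0.0) {
      int sg = d > 0 ? 1 : -1;
      if (first_sign == 0) first_sign = sg;
      if (last_sign != 0 && sg != last_sign)
        speeds.push_back(std::fabs(X - Xp) / p.dt);
      last_sign = sg;
    }
    bool rec = (st % thin == 0);
    if (X <= a_hi) {
      label = 1;
      double frac = (Xp > a_hi) ? (Xp - a_hi) / (Xp - X) : 0.0;
      t_entry = ((double)(st - 1) + frac) * p.dt;
      rec = true;
    } else if (X >= b_lo) {
      label = 2;
      double frac = (Xp < b_lo) ? (b_lo - Xp) / (X - Xp) : 0.0;
      t_entry = ((double)(st - 1) + frac) * p.dt;
      rec = true;
    }
    if (rec) {
      xs.push_back(X);
      for (int c = 0; c < 8; ++c) st_store.push_back(s[c]);
    }
    if (label != 0) break;
  }
  long long nrec = (long long) xs.size();
  NumericMatrix states(nrec, 8);
  for (long long r = 0; r < nrec; ++r)
    for (int c = 0; c < 8; ++c) states(r, c) = st_store[8 * r + c];
  return List::create(_["label"] = label,
                      _["time"] = t_entry,
                      _["steps"] = (double) std::min(st, ms),
                      _["cross_speeds"] = NumericVector(speeds.begin(), speeds.end()),
                      _["first_sign"] = first_sign,
                      _["occupation"] = occ,
                      _["x"] = NumericVector(xs.begin(), xs.end()),
                      _["states"] = states);
}

// [[Rcpp::export]]
List dimer_cv_cpp(List par, NumericMatrix states) {
  DimerPar p = unpack_par(par);
  int nf = states.nrow();
  NumericVector drms(nf), theta(nf);
  double s[8], dr, th;
  for (int f = 0; f < nf; ++f) {
    for (int c = 0; c < 8; ++c) s[c] = states(f, c);
    dimer_energy(s, p, nullptr, &dr, &th, 0.0, 0.0);
    drms[f] = dr; theta[f] = th;
  }
  return List::create(_["drms"] = drms, _["theta"] = theta);
}

// [[Rcpp::export]]
double dimer_energy_cpp(List par, NumericVector state, double bias_center,
                        double bias_k) {
  DimerPar p = unpack_par(par);
  return dimer_energy(state.begin(), p, nullptr, nullptr, nullptr,
                      bias_center, bias_k);
}

// [[Rcpp::export]]
NumericVector dimer_grad_cpp(List par, NumericVector state) {
  DimerPar p = unpack_par(par);
  NumericVector g(8);
  dimer_energy(state.begin(), p, g.begin(), nullptr, nullptr, 0.0, 0.0);
  return g;
}

// [[Rcpp::export]]
NumericMatrix dimer_coords_cpp(List par, NumericVector state) {
  DimerPar p = unpack_par(par);
  NumericMatrix out(2 * p.n, 3);
  std::vector<double> A(3 * p.n), B(3 * p.n);
  rod_beads(state.begin(), p.n, p.spacing, A.data());
  rod_beads_B(state.begin(), p.n, p.spacing, p.L, B.data());
  for (int k = 0; k < p.n; ++k)
    for (int c = 0; c < 3; ++c) {
      out(k, c) = A[3 * k + c];
      out(p.n + k, c) = B[3 * k + c];
    }
  return out;
}

// Per-frame inter-chain residue contacts: column (i-1)*n + j is TRUE when
// beads (A_i, B_j) are within `cutoff` (strict <, minimum image).
// [[Rcpp::export]]
LogicalMatrix dimer_contacts_cpp(List par, NumericMatrix states,
                                 double cutoff) {
  DimerPar p = unpack_par(par);
  int nf = states.nrow(), n = p.n;
  LogicalMatrix out(nf, n * n);
  std::vector<double> A(3 * n), B(3 * n);
  double s[8];
  double c2 = cutoff * cutoff;
  for (int f = 0; f < nf; ++f) {
    for (int c = 0; c < 8; ++c) s[c] = states(f, c);
    rod_beads(s, n, p.spacing, A.data());
    rod_beads_B(s, n, p.spacing, p.L, B.data());
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        double dx = A[3*i] - B[3*j];
        double dy = A[3*i+1] - B[3*j+1];
        double dz = A[3*i+2] - B[3*j+2];
        out(f, i * n + j) = (dx*dx + dy*dy + dz*dz < c2);
      }
  }
  return out;
}
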