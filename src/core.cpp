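// Energy/force kernels for the mbpef package.
//
// Conventions: coordinates in Angstrom, energies kcal/mol, charges in e,
// dipoles in e*Angstrom internally, forces kcal/mol/Angstrom. Atoms are
// ordered O,H,H within each water monomer; atom k belongs to molecule k/3
// and has site type k%3 (0 = O). A cubic periodic box of edge L is handled
// by molecule-based minimum images: molecule j is shifted as a rigid unit
// by the lattice vector that minimises the O...O distance to molecule i,
// and every intermolecular term of a molecule pair is tapered by a smooth
// function of that O...O distance so the energy stays C^2 as images swap.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>

using namespace Rcpp;

static const double FCOUL = 332.0637157; // kcal*Angstrom/mol/e^2

// ---------------------------------------------------------------------------
// small vector helpers
// ---------------------------------------------------------------------------

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// quintic switch: 1 below rin, 0 above rout, C2 at both ends
static inline void switch5(double r, double rin, double rout,
                           double& s, double& sp) {
  if (r <= rin) { s = 1.0; sp = 0.0; return; }
  if (r >= rout) { s = 0.0; sp = 0.0; return; }
  const double w = rout - rin;
  const double x = (r - rin) / w;
  const double x2 = x * x;
  s = 1.0 + x2 * x * (-10.0 + x * (15.0 - 6.0 * x));
  sp = x2 * (-30.0 + x * (60.0 - 30.0 * x)) / w;
}

// Tang-Toennies damping of order 6 and its derivative w.r.t. x
static inline void tt6(double x, double& f, double& fp) {
  double term = 1.0, sum = 1.0;
  for (int k = 1; k <= 6; ++k) { term *= x / k; sum += term; }
  const double ex = std::exp(-x);
  f = 1.0 - ex * sum;
  fp = ex * term; // e^{-x} x^6/720
}

// ---------------------------------------------------------------------------
// molecule pair list with minimum-image shifts and pair tapers
// ---------------------------------------------------------------------------

struct MolPair {
  int m, n;          // molecule indices, m < n
  double shift[3];   // add to every atom of molecule n
  double R;          // O...O distance after shifting
  double er[3];      // unit vector from O_n(+shift) to O_m
  double s, sp;      // taper value and derivative (d s / d R)
};

// L <= 0: gas phase (no wrap). rc <= 0: no cutoff, s = 1.
static void build_pairs(const double* P, int nmol, double L,
                        double rc, double tw, std::vector<MolPair>& out) {
  out.clear();
  for (int m = 0; m < nmol - 1; ++m) {
    const double* Om = P + 9 * m;
    for (int n = m + 1; n < nmol; ++n) {
      const double* On = P + 9 * n;
      MolPair pr;
      pr.m = m; pr.n = n;
      double d[3];
      for (int k = 0; k < 3; ++k) {
        d[k] = Om[k] - On[k];
        pr.shift[k] = 0.0;
        if (L > 0.0) {
          // O_m - (O_n + shift) is the minimum-image displacement, i.e.
          // shift is what we add to every atom of molecule n
          const double img = L * std::floor(d[k] / L + 0.5);
          pr.shift[k] = img;
          d[k] -= img;
        }
      }
      pr.R = norm3(d);
      if (rc > 0.0 && pr.R >= rc) continue;
      const double inv = pr.R > 0 ? 1.0 / pr.R : 0.0;
      for (int k = 0; k < 3; ++k) pr.er[k] = d[k] * inv;
      if (rc > 0.0) switch5(pr.R, rc - tw, rc, pr.s, pr.sp);
      else { pr.s = 1.0; pr.sp = 0.0; }
      out.push_back(pr);
    }
  }
}

// ---------------------------------------------------------------------------
// intramolecular surface: Morse O-H stretches + harmonic bend
// ---------------------------------------------------------------------------

struct OneBody { double D, a, re, kth, the; };

static double intra_energy(const double* P, int nmol, const OneBody& ob,
                           double* F) {
  double E = 0.0;
  for (int m = 0; m < nmol; ++m) {
    const double* O = P + 9 * m;
    const double* H1 = P + 9 * m + 3;
    const double* H2 = P + 9 * m + 6;
    double u[3], v[3];
    for (int k = 0; k < 3; ++k) { u[k] = H1[k] - O[k]; v[k] = H2[k] - O[k]; }
    const double ru = norm3(u), rv = norm3(v);
    // Morse stretches
    const double eu = std::exp(-ob.a * (ru - ob.re));
    const double ev = std::exp(-ob.a * (rv - ob.re));
    E += ob.D * (1.0 - eu) * (1.0 - eu) + ob.D * (1.0 - ev) * (1.0 - ev);
    if (F) {
      const double dEdru = 2.0 * ob.D * ob.a * eu * (1.0 - eu);
      const double dEdrv = 2.0 * ob.D * ob.a * ev * (1.0 - ev);
      for (int k = 0; k < 3; ++k) {
        const double fu = dEdru * u[k] / ru;   // dE/d(H1_k)
        const double fv = dEdrv * v[k] / rv;
        F[9 * m + 3 + k] += fu; F[9 * m + k] -= fu;
        F[9 * m + 6 + k] += fv; F[9 * m + k] -= fv;
      }
    }
    // harmonic bend
    double c = dot3(u, v) / (ru * rv);
    c = std::max(-1.0, std::min(1.0, c));
    const double th = std::acos(c);
    const double dth = th - ob.the;
    E += 0.5 * ob.kth * dth * dth;
    if (F) {
      const double st = std::max(std::sqrt(1.0 - c * c), 1e-10);
      const double dEdth = ob.kth * dth;
      for (int k = 0; k < 3; ++k) {
        const double dthdu = (c * u[k] / ru - v[k] / rv) / (st * ru);
        const double dthdv = (c * v[k] / rv - u[k] / ru) / (st * rv);
        F[9 * m + 3 + k] += dEdth * dthdu;
        F[9 * m + 6 + k] += dEdth * dthdv;
        F[9 * m + k]     -= dEdth * (dthdu + dthdv);
      }
    }
  }
  return E;
}

// ---------------------------------------------------------------------------
// self-consistent induced dipoles (Thole-damped, O sites polarizable)
// ---------------------------------------------------------------------------

struct PolParams {
  double alphaO;            // polarizability of O, Angstrom^3
  double adampO, adampH;    // damping "polarizabilities" used in Thole u
  double a;                 // Thole exponential parameter
  double tol;               // convergence on dipole change, e*Angstrom
  int maxit;
  double mix;
};

static inline void thole(double r, double Ai, double Aj, double a,
                         double& l3, double& l5, double& dl3, double& dl5) {
  const double u = r / std::pow(Ai * Aj, 1.0 / 6.0);
  const double w = a * u * u * u;
  const double ew = std::exp(-w);
  l3 = 1.0 - ew;
  l5 = 1.0 - (1.0 + w) * ew;
  const double dwdr = 3.0 * w / r;
  dl3 = ew * dwdr;
  dl5 = w * ew * dwdr;
}

// Solve for induced dipoles on O sites; returns induction energy. Charges q
// are per atom; only intermolecular interactions (through the pair list)
// enter. If F is non-null, accumulates forces via the variational gradient.
static double induction_solve(const double* P, int nmol,
                              const std::vector<MolPair>& pairs,
                              const double* q, const PolParams& pp,
                              double* F, int& iters, bool& converged,
                              std::vector<double>* mu_out) {
  const int np = (int)pairs.size();
  std::vector<double> E0(3 * nmol, 0.0);       // permanent field at O sites
  std::vector<double> T(9 * np);               // damped dipole-dipole tensor

  // permanent fields and O-O tensors
  for (int p = 0; p < np; ++p) {
    const MolPair& pr = pairs[p];
    if (pr.s == 0.0) { std::memset(&T[9 * p], 0, 9 * sizeof(double)); continue; }
    for (int dir = 0; dir < 2; ++dir) {
      const int mi = dir == 0 ? pr.m : pr.n;  // molecule holding the dipole
      const int mj = dir == 0 ? pr.n : pr.m;  // molecule holding the charges
      const double* Oi = P + 9 * mi;
      for (int sb = 0; sb < 3; ++sb) {
        const double* B = P + 9 * mj + 3 * sb;
        double r[3];
        for (int k = 0; k < 3; ++k) {
          double bk = B[k] + (mj == pr.n ? pr.shift[k] : -pr.shift[k]);
          r[k] = Oi[k] - bk;
        }
        const double rr = norm3(r);
        const double Ab = sb == 0 ? pp.adampO : pp.adampH;
        double l3, l5, d3, d5;
        thole(rr, pp.adampO, Ab, pp.a, l3, l5, d3, d5);
        const double g = FCOUL * q[3 * mj + sb] * pr.s * l3 / (rr * rr * rr);
        for (int k = 0; k < 3; ++k) E0[3 * mi + k] += g * r[k];
      }
    }
    // dipole-dipole tensor between O_m and O_n (separation = pr.R * pr.er)
    double l3, l5, d3, d5;
    thole(pr.R, pp.adampO, pp.adampO, pp.a, l3, l5, d3, d5);
    const double r3 = pr.R * pr.R * pr.R;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        T[9 * p + 3 * i + j] = FCOUL * pr.s *
          (3.0 * l5 * pr.er[i] * pr.er[j] - (i == j ? l3 : 0.0)) / r3;
  }

  // Jacobi iteration with mixing
  std::vector<double> mu(3 * nmol, 0.0), fld(3 * nmol);
  const double aof = pp.alphaO / FCOUL;
  converged = false;
  iters = 0;
  for (int it = 1; it <= pp.maxit; ++it) {
    std::copy(E0.begin(), E0.end(), fld.begin());
    for (int p = 0; p < np; ++p) {
      const MolPair& pr = pairs[p];
      const double* t = &T[9 * p];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          fld[3 * pr.m + i] += t[3 * i + j] * mu[3 * pr.n + j];
          fld[3 * pr.n + i] += t[3 * i + j] * mu[3 * pr.m + j];
        }
    }
    double dmax = 0.0;
    for (int i = 0; i < 3 * nmol; ++i) {
      const double nm = pp.mix * aof * fld[i] + (1.0 - pp.mix) * mu[i];
      dmax = std::max(dmax, std::fabs(nm - mu[i]));
      mu[i] = nm;
    }
    iters = it;
    if (dmax < pp.tol) { converged = true; break; }
  }

  double U = 0.0;
  for (int i = 0; i < 3 * nmol; ++i) U -= 0.5 * mu[i] * E0[i];
  if (mu_out) *mu_out = mu;
  if (!F) return U;

  // forces: dU/dx = -sum mu dE0/dx - sum_{pairs} mu_i dT/dx mu_j (envelope)
  for (int p = 0; p < np; ++p) {
    const MolPair& pr = pairs[p];
    if (pr.s == 0.0 && pr.sp == 0.0) continue;
    // charge-dipole part
    for (int dir = 0; dir < 2; ++dir) {
      const int mi = dir == 0 ? pr.m : pr.n;
      const int mj = dir == 0 ? pr.n : pr.m;
      const double* Oi = P + 9 * mi;
      const double* mui = &mu[3 * mi];
      for (int sb = 0; sb < 3; ++sb) {
        const double qb = q[3 * mj + sb];
        if (qb == 0.0) continue;
        const double* B = P + 9 * mj + 3 * sb;
        double r[3];
        for (int k = 0; k < 3; ++k) {
          double bk = B[k] + (mj == pr.n ? pr.shift[k] : -pr.shift[k]);
          r[k] = Oi[k] - bk;
        }
        const double rr = norm3(r);
        const double Ab = sb == 0 ? pp.adampO : pp.adampH;
        double l3, l5, d3, d5;
        thole(rr, pp.adampO, Ab, pp.a, l3, l5, d3, d5);
        const double r3 = rr * rr * rr;
        const double mur = dot3(mui, r);
        // U_cd = -f qb s l3 (mu.r)/r^3
        const double g = l3 / r3;
        const double gp = d3 / r3 - 3.0 * l3 / (r3 * rr);
        for (int k = 0; k < 3; ++k) {
          const double dU = -FCOUL * qb * pr.s *
            (g * mui[k] + mur * gp * r[k] / rr);  // dU/d(r_vec) component
          F[9 * mi + k] += dU;            // r_vec = r_i - r_b
          F[9 * mj + 3 * sb + k] -= dU;
        }
        // taper derivative acts on the O-O axis
        const double dUdR = -FCOUL * qb * pr.sp * g * mur;
        for (int k = 0; k < 3; ++k) {
          F[9 * pr.m + k] += dUdR * pr.er[k];
          F[9 * pr.n + k] -= dUdR * pr.er[k];
        }
      }
    }
    // dipole-dipole part: U_dd = -f [3 s l5 (mi.r)(mj.r)/r^5 - s l3 mi.mj/r^3]
    {
      const double* mi = &mu[3 * pr.m];
      const double* mj = &mu[3 * pr.n];
      double r[3];
      for (int k = 0; k < 3; ++k) r[k] = pr.R * pr.er[k];
      const double rr = pr.R;
      double l3, l5, d3, d5;
      thole(rr, pp.adampO, pp.adampO, pp.a, l3, l5, d3, d5);
      const double r3 = rr * rr * rr, r5 = r3 * rr * rr;
      const double mir = dot3(mi, r), mjr = dot3(mj, r), mm = dot3(mi, mj);
      const double phi = -FCOUL * (3.0 * l5 * mir * mjr / r5 - l3 * mm / r3);
      for (int k = 0; k < 3; ++k) {
        const double er = r[k] / rr;
        double dU = -FCOUL * pr.s * (
          3.0 * d5 * mir * mjr / r5 * er
          + 3.0 * l5 * (mjr * mi[k] + mir * mj[k]) / r5
          - 15.0 * l5 * mir * mjr / (r5 * rr) * er
          - d3 * mm / r3 * er
          + 3.0 * l3 * mm / (r3 * rr) * er);
        dU += pr.sp * phi * er; // taper (same O-O axis as r)
        F[9 * pr.m + k] += dU;  // r = r_Om - r_On
        F[9 * pr.n + k] -= dU;
      }
    }
  }
  return U;
}

// ---------------------------------------------------------------------------
// toy polarizable water backend
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List toy_eval_cpp(NumericMatrix coords, List params, double L, double rc,
                  double tw, bool forces) {
  const int natom = coords.nrow();
  if (natom % 3 != 0) stop("atom count not a multiple of 3");
  const int nmol = natom / 3;
  std::vector<double> P(3 * natom);
  for (int i = 0; i < natom; ++i)
    for (int k = 0; k < 3; ++k) P[3 * i + k] = coords(i, k);

  OneBody ob{as<double>(params["D"]), as<double>(params["a"]),
             as<double>(params["re"]), as<double>(params["ktheta"]),
             as<double>(params["thetae"])};
  const double qO = as<double>(params["qO"]), qH = as<double>(params["qH"]);
  const double eps = as<double>(params["eps"]), sig = as<double>(params["sigma"]);
  const bool pol = as<bool>(params["polarization"]);
  PolParams pp{as<double>(params["alpha"]), as<double>(params["adampO"]),
               as<double>(params["adampH"]), as<double>(params["thole_a"]),
               as<double>(params["tol"]), as<int>(params["maxit"]),
               as<double>(params["mix"])};

  std::vector<double> q(natom);
  for (int i = 0; i < natom; ++i) q[i] = (i % 3 == 0) ? qO : qH;

  std::vector<double> F;
  double* Fp = nullptr;
  if (forces) { F.assign(3 * natom, 0.0); Fp = F.data(); }

  const double Eintra = intra_energy(P.data(), nmol, ob, Fp);

  std::vector<MolPair> pairs;
  build_pairs(P.data(), nmol, L, rc, tw, pairs);

  double Elj = 0.0, Ecoul = 0.0;
  for (const MolPair& pr : pairs) {
    if (pr.s == 0.0 && pr.sp == 0.0) continue;
    // O-O Lennard-Jones on the pair's O...O distance
    const double sr6 = std::pow(sig / pr.R, 6);
    const double philj = 4.0 * eps * (sr6 * sr6 - sr6);
    double phicoul = 0.0;
    double dphi[18];  // d(phi_coul)/d(atom coords), 6 atoms of the pair
    std::memset(dphi, 0, sizeof(dphi));
    for (int sa = 0; sa < 3; ++sa)
      for (int sb = 0; sb < 3; ++sb) {
        const double* A = P.data() + 9 * pr.m + 3 * sa;
        const double* B = P.data() + 9 * pr.n + 3 * sb;
        double r[3];
        for (int k = 0; k < 3; ++k) r[k] = A[k] - B[k] - pr.shift[k];
        const double rr = norm3(r);
        const double qa = sa == 0 ? qO : qH, qb = sb == 0 ? qO : qH;
        // Thole-screened Coulomb: removes the bare H...O singularity
        const double Aa = sa == 0 ? pp.adampO : pp.adampH;
        const double Ab = sb == 0 ? pp.adampO : pp.adampH;
        double l1, l5u, dl1, dl5u;
        thole(rr, Aa, Ab, pp.a, l1, l5u, dl1, dl5u);
        const double e = FCOUL * qa * qb * l1 / rr;
        phicoul += e;
        if (forces) {
          const double dedr = FCOUL * qa * qb * (dl1 / rr - l1 / (rr * rr));
          for (int k = 0; k < 3; ++k) {
            dphi[3 * sa + k] += dedr * r[k] / rr;
            dphi[9 + 3 * sb + k] -= dedr * r[k] / rr;
          }
        }
      }
    Elj += pr.s * philj;
    Ecoul += pr.s * phicoul;
    if (forces) {
      const double dljdr = 4.0 * eps * (-12.0 * sr6 * sr6 + 6.0 * sr6) / pr.R;
      const double dR = pr.sp * (philj + phicoul) + pr.s * dljdr;
      for (int k = 0; k < 3; ++k) {
        F[9 * pr.m + k] += dR * pr.er[k];
        F[9 * pr.n + k] -= dR * pr.er[k];
        for (int s6 = 0; s6 < 3; ++s6) {
          F[9 * pr.m + 3 * s6 + k] += pr.s * dphi[3 * s6 + k];
          F[9 * pr.n + 3 * s6 + k] += pr.s * dphi[9 + 3 * s6 + k];
        }
      }
    }
  }

  double Eind = 0.0;
  int iters = 0;
  bool conv = true;
  std::vector<double> mu;
  if (pol) {
    Eind = induction_solve(P.data(), nmol, pairs, q.data(), pp, Fp, iters,
                           conv, &mu);
    if (!conv) stop("induced-dipole iteration failed to converge (%d iterations); reduce polarizability or increase Thole damping", iters);
  }

  List out = List::create(
    _["energy"] = Eintra + Elj + Ecoul + Eind,
    _["terms"] = NumericVector::create(_["intra"] = Eintra, _["lj"] = Elj,
                                       _["elec"] = Ecoul, _["induction"] = Eind),
    _["ind_iterations"] = iters);
  if (forces) {
    NumericMatrix Fm(natom, 3);
    for (int i = 0; i < natom; ++i)
      for (int k = 0; k < 3; ++k) Fm(i, k) = -F[3 * i + k];
    out["forces"] = Fm;
  }
  if (pol && mu.size()) {
    NumericMatrix Mu(nmol, 3);
    for (int m = 0; m < nmol; ++m)
      for (int k = 0; k < 3; ++k) Mu(m, k) = mu[3 * m + k];
    out["dipoles"] = Mu;
  }
  return out;
}

// ---------------------------------------------------------------------------
// PIP basis evaluation
// ---------------------------------------------------------------------------

struct PipBasis {
  int nmon, nvar, norbit;
  std::vector<int> va, vb;       // local atom indices per variable
  std::vector<double> kvec;      // exponential range parameter per variable
  std::vector<int> ptr, mvar, mpow, orbit;
  double rin, rout;              // switch window (2B: O..O; 3B: each O..O pair)
};

static PipBasis unpack_basis(const List& b) {
  PipBasis B;
  B.nmon = as<int>(b["nmon"]);
  B.nvar = as<int>(b["nvar"]);
  B.norbit = as<int>(b["norbit"]);
  B.va = as<std::vector<int>>(b["var_a"]);
  B.vb = as<std::vector<int>>(b["var_b"]);
  B.kvec = as<std::vector<double>>(b["k"]);
  B.ptr = as<std::vector<int>>(b["mono_ptr"]);
  B.mvar = as<std::vector<int>>(b["mono_var"]);
  B.mpow = as<std::vector<int>>(b["mono_pow"]);
  B.orbit = as<std::vector<int>>(b["orbit"]);
  B.rin = as<double>(b["rin"]);
  B.rout = as<double>(b["rout"]);
  return B;
}

// value and gradient w.r.t. xi of sum_orbits coef * orbit-sum; xi > 0
// always (exponentially transformed distances), so reciprocals are safe
static double pip_vg(const PipBasis& B, const double* xi, const double* coef,
                     double* g) {
  const int nm = (int)B.orbit.size();
  double V = 0.0;
  if (g) {
    std::memset(g, 0, B.nvar * sizeof(double));
    std::vector<double> inv(B.nvar);
    for (int v = 0; v < B.nvar; ++v) inv[v] = 1.0 / xi[v];
    for (int t = 0; t < nm; ++t) {
      const double c = coef[B.orbit[t]];
      if (c == 0.0) continue;
      double v = 1.0;
      const int j0 = B.ptr[t], j1 = B.ptr[t + 1];
      for (int j = j0; j < j1; ++j) {
        const double x = xi[B.mvar[j]];
        for (int e = 0; e < B.mpow[j]; ++e) v *= x;
      }
      const double cv = c * v;
      V += cv;
      for (int j = j0; j < j1; ++j)
        g[B.mvar[j]] += cv * B.mpow[j] * inv[B.mvar[j]];
    }
  } else {
    for (int t = 0; t < nm; ++t) {
      const double c = coef[B.orbit[t]];
      if (c == 0.0) continue;
      double v = 1.0;
      for (int j = B.ptr[t]; j < B.ptr[t + 1]; ++j) {
        const double x = xi[B.mvar[j]];
        for (int e = 0; e < B.mpow[j]; ++e) v *= x;
      }
      V += c * v;
    }
  }
  return V;
}

// orbit-sum design rows for a matrix of xi vectors (fitting)
// [[Rcpp::export]]
NumericMatrix pip_design_cpp(NumericMatrix xis, List basis) {
  PipBasis B = unpack_basis(basis);
  const int n = xis.nrow();
  if (xis.ncol() != B.nvar) stop("xi matrix has wrong number of columns");
  NumericMatrix out(n, B.norbit);
  const int nm = (int)B.orbit.size();
  std::vector<double> xi(B.nvar);
  for (int i = 0; i < n; ++i) {
    for (int v = 0; v < B.nvar; ++v) xi[v] = xis(i, v);
    for (int t = 0; t < nm; ++t) {
      double v = 1.0;
      for (int j = B.ptr[t]; j < B.ptr[t + 1]; ++j) {
        const double x = xi[B.mvar[j]];
        for (int e = 0; e < B.mpow[j]; ++e) v *= x;
      }
      out(i, B.orbit[t]) += v;
    }
  }
  return out;
}

// direct evaluation of every symmetrized basis function at one xi vector
// [[Rcpp::export]]
NumericVector pip_orbit_values_cpp(NumericVector xi, List basis) {
  PipBasis B = unpack_basis(basis);
  NumericVector out(B.norbit);
  const int nm = (int)B.orbit.size();
  for (int t = 0; t < nm; ++t) {
    double v = 1.0;
    for (int j = B.ptr[t]; j < B.ptr[t + 1]; ++j) {
      const double x = xi[B.mvar[j]];
      for (int e = 0; e < B.mpow[j]; ++e) v *= x;
    }
    out[B.orbit[t]] += v;
  }
  return out;
}

// ---------------------------------------------------------------------------
// full PEF evaluation
// ---------------------------------------------------------------------------

struct PefModel {
  OneBody ob;
  double qO, qH;
  double c6[3];      // OO, OH, HH keyed by number of H sites in the pair
  double delta;      // Tang-Toennies damping scale, 1/Angstrom
  double coreA[3], coreB[3];  // Born-Mayer repulsive core A e^{-b r}
  bool pol;
  PolParams pp;
  bool has2b, has3b;
  PipBasis b2, b3;
  std::vector<double> c2, c3;
};

static PefModel unpack_model(const List& model) {
  PefModel M;
  List ob = model["oneb"];
  M.ob = OneBody{as<double>(ob["D"]), as<double>(ob["a"]), as<double>(ob["re"]),
                 as<double>(ob["ktheta"]), as<double>(ob["thetae"])};
  M.qO = as<double>(model["qO"]);
  M.qH = as<double>(model["qH"]);
  NumericVector c6 = model["c6"];
  M.c6[0] = c6[0]; M.c6[1] = c6[1]; M.c6[2] = c6[2];
  M.delta = as<double>(model["delta"]);
  NumericVector cA = model["coreA"], cB = model["coreB"];
  for (int k = 0; k < 3; ++k) { M.coreA[k] = cA[k]; M.coreB[k] = cB[k]; }
  List pol = model["pol"];
  M.pol = as<bool>(pol["enabled"]);
  M.pp = PolParams{as<double>(pol["alpha"]), as<double>(pol["adampO"]),
                   as<double>(pol["adampH"]), as<double>(pol["thole_a"]),
                   as<double>(pol["tol"]), as<int>(pol["maxit"]),
                   as<double>(pol["mix"])};
  M.has2b = model.containsElementNamed("pip2b") &&
            !Rf_isNull(model["pip2b"]);
  if (M.has2b) {
    List p2 = model["pip2b"];
    M.b2 = unpack_basis(p2["basis"]);
    M.c2 = as<std::vector<double>>(p2["coef"]);
    bool any = false;
    for (double c : M.c2) if (c != 0.0) { any = true; break; }
    M.has2b = any;   // an all-zero term contributes nothing
  }
  M.has3b = model.containsElementNamed("pip3b") &&
            !Rf_isNull(model["pip3b"]);
  if (M.has3b) {
    List p3 = model["pip3b"];
    M.b3 = unpack_basis(p3["basis"]);
    M.c3 = as<std::vector<double>>(p3["coef"]);
    bool any = false;
    for (double c : M.c3) if (c != 0.0) { any = true; break; }
    M.has3b = any;
  }
  return M;
}

// evaluate the 2B PIP term for one molecule pair (with shift), switched on R
static double pef_pip2b_pair(const double* P, const MolPair& pr,
                             const PipBasis& B, const double* coef,
                             double* F) {
  double s, sp;
  switch5(pr.R, B.rin, B.rout, s, sp);
  if (s == 0.0 && sp == 0.0) return 0.0;
  // local atoms: 0..2 molecule m, 3..5 molecule n (+shift)
  double X[18];
  for (int k = 0; k < 3; ++k)
    for (int sloc = 0; sloc < 3; ++sloc) {
      X[3 * sloc + k] = P[9 * pr.m + 3 * sloc + k];
      X[9 + 3 * sloc + k] = P[9 * pr.n + 3 * sloc + k] + pr.shift[k];
    }
  std::vector<double> xi(B.nvar), gxi(F ? B.nvar : 0);
  std::vector<double> rv(3 * B.nvar), rl(B.nvar);
  for (int v = 0; v < B.nvar; ++v) {
    const double* A = X + 3 * B.va[v];
    const double* Bb = X + 3 * B.vb[v];
    double d[3];
    for (int k = 0; k < 3; ++k) d[k] = A[k] - Bb[k];
    rl[v] = norm3(d);
    for (int k = 0; k < 3; ++k) rv[3 * v + k] = d[k];
    xi[v] = std::exp(-B.kvec[v] * rl[v]);
  }
  const double V = pip_vg(B, xi.data(), coef, F ? gxi.data() : nullptr);
  if (F) {
    // switch derivative on O...O axis
    for (int k = 0; k < 3; ++k) {
      F[9 * pr.m + k] += sp * V * pr.er[k];
      F[9 * pr.n + k] -= sp * V * pr.er[k];
    }
    for (int v = 0; v < B.nvar; ++v) {
      const double dEdr = s * gxi[v] * (-B.kvec[v] * xi[v]);
      const int ga = B.va[v] < 3 ? 9 * pr.m + 3 * B.va[v]
                                 : 9 * pr.n + 3 * (B.va[v] - 3);
      const int gb = B.vb[v] < 3 ? 9 * pr.m + 3 * B.vb[v]
                                 : 9 * pr.n + 3 * (B.vb[v] - 3);
      for (int k = 0; k < 3; ++k) {
        const double fk = dEdr * rv[3 * v + k] / rl[v];
        F[ga + k] += fk;
        F[gb + k] -= fk;
      }
    }
  }
  return s * V;
}

// evaluate the 3B PIP term for one molecule triple
static double pef_pip3b_triple(const double* X /*27 coords, local*/,
                               const int* gidx /*global atom base per mon*/,
                               const double R[3], const double er[9],
                               const PipBasis& B, const double* coef,
                               double* F) {
  double s12, sp12, s13, sp13, s23, sp23;
  switch5(R[0], B.rin, B.rout, s12, sp12);
  switch5(R[1], B.rin, B.rout, s13, sp13);
  switch5(R[2], B.rin, B.rout, s23, sp23);
  const double sw = s12 * s13 * s23;
  if (sw == 0.0) return 0.0;
  std::vector<double> xi(B.nvar), gxi(F ? B.nvar : 0);
  std::vector<double> rv(3 * B.nvar), rl(B.nvar);
  for (int v = 0; v < B.nvar; ++v) {
    const double* A = X + 3 * B.va[v];
    const double* Bb = X + 3 * B.vb[v];
    double d[3];
    for (int k = 0; k < 3; ++k) d[k] = A[k] - Bb[k];
    rl[v] = norm3(d);
    for (int k = 0; k < 3; ++k) rv[3 * v + k] = d[k];
    xi[v] = std::exp(-B.kvec[v] * rl[v]);
  }
  const double V = pip_vg(B, xi.data(), coef, F ? gxi.data() : nullptr);
  if (F) {
    // switch products: dE/dR12 = sp12 s13 s23 V, etc.
    const double dR[3] = {sp12 * s13 * s23 * V, s12 * sp13 * s23 * V,
                          s12 * s13 * sp23 * V};
    const int pa[3] = {0, 0, 1}, pb[3] = {1, 2, 2};
    for (int e = 0; e < 3; ++e)
      for (int k = 0; k < 3; ++k) {
        F[gidx[pa[e]] + k] += dR[e] * er[3 * e + k];
        F[gidx[pb[e]] + k] -= dR[e] * er[3 * e + k];
      }
    for (int v = 0; v < B.nvar; ++v) {
      const double dEdr = sw * gxi[v] * (-B.kvec[v] * xi[v]);
      const int ga = gidx[B.va[v] / 3] + 3 * (B.va[v] % 3);
      const int gb = gidx[B.vb[v] / 3] + 3 * (B.vb[v] % 3);
      for (int k = 0; k < 3; ++k) {
        const double fk = dEdr * rv[3 * v + k] / rl[v];
        F[ga + k] += fk;
        F[gb + k] -= fk;
      }
    }
  }
  return sw * V;
}

// [[Rcpp::export]]
List pef_eval_cpp(NumericMatrix coords, List model, double L, double rc,
                  double tw, bool forces) {
  const int natom = coords.nrow();
  if (natom % 3 != 0) stop("atom count not a multiple of 3");
  const int nmol = natom / 3;
  std::vector<double> P(3 * natom);
  for (int i = 0; i < natom; ++i)
    for (int k = 0; k < 3; ++k) P[3 * i + k] = coords(i, k);
  PefModel M = unpack_model(model);

  std::vector<double> F;
  double* Fp = nullptr;
  if (forces) { F.assign(3 * natom, 0.0); Fp = F.data(); }

  const double E1 = intra_energy(P.data(), nmol, M.ob, Fp);

  // pair list wide enough for every term; per-term ranges applied inside
  double reach = rc;
  if (M.has2b) reach = std::max(reach, M.b2.rout);
  if (M.has3b) reach = std::max(reach, M.b3.rout);
  std::vector<MolPair> pairs;
  build_pairs(P.data(), nmol, L, L > 0.0 ? reach : -1.0, tw, pairs);

  std::vector<double> q(natom);
  for (int i = 0; i < natom; ++i) q[i] = (i % 3 == 0) ? M.qO : M.qH;

  double Eel = 0.0, Edisp = 0.0, Ecore = 0.0, E2 = 0.0, E3 = 0.0;
  // electrostatics + dispersion taper: s on O..O with window (rc-tw, rc)
  for (const MolPair& pr : pairs) {
    double s = 1.0, sp = 0.0;
    if (rc > 0.0) switch5(pr.R, rc - tw, rc, s, sp);
    if (s > 0.0 || sp != 0.0) {
      double phi = 0.0;
      double dphi[18];
      std::memset(dphi, 0, sizeof(dphi));
      for (int sa = 0; sa < 3; ++sa)
        for (int sb = 0; sb < 3; ++sb) {
          const double qa = sa == 0 ? M.qO : M.qH;
          const double qb = sb == 0 ? M.qO : M.qH;
          const int nH = (sa != 0) + (sb != 0);
          const double c6 = M.c6[nH];
          const double* A = P.data() + 9 * pr.m + 3 * sa;
          const double* B = P.data() + 9 * pr.n + 3 * sb;
          double r[3];
          for (int k = 0; k < 3; ++k) r[k] = A[k] - B[k] - pr.shift[k];
          const double rr = norm3(r);
          // Thole-screened Coulomb (same screening as the toy reference)
          const double Aa = sa == 0 ? M.pp.adampO : M.pp.adampH;
          const double Ab = sb == 0 ? M.pp.adampO : M.pp.adampH;
          double l1, l5u, dl1, dl5u;
          thole(rr, Aa, Ab, M.pp.a, l1, l5u, dl1, dl5u);
          const double ec = FCOUL * qa * qb * l1 / rr;
          double ed = 0.0;
          double dedr = FCOUL * qa * qb * (dl1 / rr - l1 / (rr * rr));
          if (c6 != 0.0) {
            double f6, f6p;
            tt6(M.delta * rr, f6, f6p);
            const double r6 = std::pow(rr, 6);
            ed = -f6 * c6 / r6;
            dedr += -c6 * (f6p * M.delta / r6 - 6.0 * f6 / (r6 * rr));
          }
          // fixed Born-Mayer repulsive core (not fitted): keeps penetration
          // geometries steeply uphill so the PIPs never extrapolate
          double eco = 0.0;
          if (M.coreA[nH] != 0.0) {
            eco = M.coreA[nH] * std::exp(-M.coreB[nH] * rr);
            dedr += -M.coreB[nH] * eco;
          }
          phi += ec + ed + eco;
          if (forces)
            for (int k = 0; k < 3; ++k) {
              dphi[3 * sa + k] += dedr * r[k] / rr;
              dphi[9 + 3 * sb + k] -= dedr * r[k] / rr;
            }
          // split bookkeeping
          Eel += s * ec;
          Edisp += s * ed;
          Ecore += s * eco;
        }
      if (forces) {
        const double dR = sp * phi;
        for (int k = 0; k < 3; ++k) {
          F[9 * pr.m + k] += dR * pr.er[k];
          F[9 * pr.n + k] -= dR * pr.er[k];
          for (int s6 = 0; s6 < 3; ++s6) {
            F[9 * pr.m + 3 * s6 + k] += s * dphi[3 * s6 + k];
            F[9 * pr.n + 3 * s6 + k] += s * dphi[9 + 3 * s6 + k];
          }
        }
      }
    }
    if (M.has2b)
      E2 += pef_pip2b_pair(P.data(), pr, M.b2, M.c2.data(), Fp);
  }

  // 3B triples: all pairs within the 3B switch window
  if (M.has3b) {
    const double r3out = M.b3.rout;
    // adjacency from the pair list
    std::vector<std::vector<int>> nb(nmol);
    std::vector<const MolPair*> pk;
    for (const MolPair& pr : pairs)
      if (pr.R < r3out) {
        nb[pr.m].push_back((int)pk.size());
        nb[pr.n].push_back((int)pk.size());
        pk.push_back(&pr);
      }
    for (size_t a = 0; a < pk.size(); ++a) {
      const MolPair& pmn = *pk[a];
      const int m = pmn.m, n = pmn.n;
      for (int idx : nb[m]) {
        const MolPair& pmp = *pk[idx];
        const int p = pmp.m == m ? pmp.n : pmp.m;
        if (p <= n) continue;           // enforce m < n < p once
        // coordinates: molecule m unshifted; n shifted by pmn.shift;
        // p shifted relative to m
        double shp[3];
        for (int k = 0; k < 3; ++k)
          shp[k] = pmp.m == m ? pmp.shift[k] : -pmp.shift[k];
        double X[27];
        for (int k = 0; k < 3; ++k)
          for (int sloc = 0; sloc < 3; ++sloc) {
            X[3 * sloc + k] = P[9 * m + 3 * sloc + k];
            X[9 + 3 * sloc + k] = P[9 * n + 3 * sloc + k] + pmn.shift[k];
            X[18 + 3 * sloc + k] = P[9 * p + 3 * sloc + k] + shp[k];
          }
        double R[3], er[9];
        const int oa[3] = {0, 0, 9}, obx[3] = {9, 18, 18};
        bool keep = true;
        for (int e = 0; e < 3; ++e) {
          double d[3];
          for (int k = 0; k < 3; ++k) d[k] = X[oa[e] + k] - X[obx[e] + k];
          R[e] = norm3(d);
          if (R[e] >= r3out) { keep = false; break; }
          for (int k = 0; k < 3; ++k) er[3 * e + k] = d[k] / R[e];
        }
        if (!keep) continue;
        const int gidx[3] = {9 * m, 9 * n, 9 * p};
        E3 += pef_pip3b_triple(X, gidx, R, er, M.b3, M.c3.data(), Fp);
      }
    }
  }

  double Eind = 0.0;
  int iters = 0;
  bool conv = true;
  if (M.pol) {
    // induction shares the electrostatic taper
    std::vector<MolPair> epairs;
    build_pairs(P.data(), nmol, L, rc, tw, epairs);
    Eind = induction_solve(P.data(), nmol, epairs, q.data(), M.pp, Fp, iters,
                           conv, nullptr);
    if (!conv) stop("induced-dipole iteration failed to converge (%d iterations); reduce polarizability or increase Thole damping", iters);
  }

  List out = List::create(
    _["energy"] = E1 + E2 + E3 + Eel + Edisp + Ecore + Eind,
    _["terms"] = NumericVector::create(
      _["oneb"] = E1, _["pip2b"] = E2, _["pip3b"] = E3,
      _["elec"] = Eel, _["dispersion"] = Edisp, _["core"] = Ecore,
      _["induction"] = Eind),
    _["ind_iterations"] = iters);
  if (forces) {
    NumericMatrix Fm(natom, 3);
    for (int i = 0; i < natom; ++i)
      for (int k = 0; k < 3; ++k) Fm(i, k) = -F[3 * i + k];
    out["forces"] = Fm;
  }
  return out;
}

// ---------------------------------------------------------------------------
// generic induced-dipole solver for arbitrary site sets (gas phase)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List induction_generic_cpp(NumericMatrix sites, NumericVector q,
                           NumericVector alpha, NumericVector adamp,
                           IntegerVector group, double thole_a, double tol,
                           int maxit, double mix) {
  const int n = sites.nrow();
  std::vector<double> E0(3 * n, 0.0);
  // permanent field from charges outside the site's exclusion group
  for (int i = 0; i < n; ++i) {
    if (alpha[i] <= 0.0) continue;
    for (int j = 0; j < n; ++j) {
      if (j == i || group[j] == group[i] || q[j] == 0.0) continue;
      double r[3];
      for (int k = 0; k < 3; ++k) r[k] = sites(i, k) - sites(j, k);
      const double rr = norm3(r);
      double l3, l5, d3, d5;
      thole(rr, adamp[i], adamp[j], thole_a, l3, l5, d3, d5);
      const double g = FCOUL * q[j] * l3 / (rr * rr * rr);
      for (int k = 0; k < 3; ++k) E0[3 * i + k] += g * r[k];
    }
  }
  std::vector<double> mu(3 * n, 0.0), fld(3 * n);
  bool conv = false;
  int iters = 0;
  for (int it = 1; it <= maxit; ++it) {
    std::copy(E0.begin(), E0.end(), fld.begin());
    for (int i = 0; i < n; ++i) {
      if (alpha[i] <= 0.0) continue;
      for (int j = 0; j < n; ++j) {
        if (j == i || group[j] == group[i] || alpha[j] <= 0.0) continue;
        double r[3];
        for (int k = 0; k < 3; ++k) r[k] = sites(i, k) - sites(j, k);
        const double rr = norm3(r);
        double l3, l5, d3, d5;
        thole(rr, adamp[i], adamp[j], thole_a, l3, l5, d3, d5);
        const double r3 = rr * rr * rr;
        const double mjr = (mu[3 * j] * r[0] + mu[3 * j + 1] * r[1] +
                            mu[3 * j + 2] * r[2]);
        for (int k = 0; k < 3; ++k)
          fld[3 * i + k] += FCOUL *
            (3.0 * l5 * mjr * r[k] / (r3 * rr * rr) - l3 * mu[3 * j + k] / r3);
      }
    }
    double dmax = 0.0;
    for (int i = 0; i < n; ++i) {
      if (alpha[i] <= 0.0) continue;
      for (int k = 0; k < 3; ++k) {
        const double nm = mix * (alpha[i] / FCOUL) * fld[3 * i + k] +
                          (1.0 - mix) * mu[3 * i + k];
        dmax = std::max(dmax, std::fabs(nm - mu[3 * i + k]));
        mu[3 * i + k] = nm;
      }
    }
    iters = it;
    if (dmax < tol) { conv = true; break; }
  }
  double U = 0.0;
  for (int i = 0; i < 3 * n; ++i) U -= 0.5 * mu[i] * E0[i];
  NumericMatrix Mu(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) Mu(i, k) = mu[3 * i + k];
  return List::create(_["dipoles_eA"] = Mu, _["energy"] = U,
                      _["iterations"] = iters, _["converged"] = conv);
}

// ---------------------------------------------------------------------------
// RDF pair-distance histogram (minimum image, atom-based)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector rdf_hist_cpp(NumericMatrix A, NumericMatrix B, bool same_set,
                           IntegerVector molA, IntegerVector molB,
                           double L, double rmax, int nbin) {
  NumericVector h(nbin);
  const double dr = rmax / nbin;
  const int na = A.nrow(), nb = B.nrow();
  for (int i = 0; i < na; ++i) {
    const int j0 = same_set ? i + 1 : 0;
    for (int j = j0; j < nb; ++j) {
      if (molA[i] == molB[j]) continue;
      double d2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = A(i, k) - B(j, k);
        if (L > 0.0) d -= L * std::floor(d / L + 0.5);
        d2 += d * d;
      }
      const double r = std::sqrt(d2);
      if (r < rmax) {
        const int b = (int)(r / dr);
        h[b] += same_set ? 2.0 : 1.0;
      }
    }
  }
  return h;
}
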