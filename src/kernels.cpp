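// Numerical kernels: McMurchie-Davidson Gaussian integrals (s/p shells),
// determinant-basis full CI, and statevector excitation-gate simulation.
// All quantities in Hartree atomic units; centers/points in bohr.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
#include <complex>
using namespace Rcpp;

// ---------------------------------------------------------------- Boys F_n(x)
// Lower-incomplete-gamma form; series for small/moderate x, asymptotic + upward
// recursion for large x.  Accurate to ~1e-14 for the n <= 12 needed here.
static void boys(int nmax, double x, double* F) {
  if (x < 1e-13) {
    for (int n = 0; n <= nmax; ++n) F[n] = 1.0 / (2.0 * n + 1.0);
    return;
  }
  if (x > 35.0) {
    F[0] = 0.5 * std::sqrt(M_PI / x) * std::erf(std::sqrt(x));
    double ex = std::exp(-x);
    for (int n = 0; n < nmax; ++n)
      F[n + 1] = ((2.0 * n + 1.0) * F[n] - ex) / (2.0 * x);
    return;
  }
  // series for F_nmax, then downward recursion (stable)
  double ex = std::exp(-x);
  double term = 1.0 / (2.0 * nmax + 1.0);
  double sum = term;
  for (int k = 1; k < 200; ++k) {
    term *= (2.0 * x) / (2.0 * nmax + 2.0 * k + 1.0);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  F[nmax] = ex * sum;
  for (int n = nmax - 1; n >= 0; --n)
    F[n] = (2.0 * x * F[n + 1] + ex) / (2.0 * n + 1.0);
}

// ------------------------------------------------- Hermite expansion E(i,j,t)
// 1-D expansion coefficients of G_i(a,A) G_j(b,B) in Hermite Gaussians at P.
static double Ecoef(int i, int j, int t, double Xab, double a, double b) {
  double p = a + b, mu = a * b / p;
  if (t < 0 || t > i + j) return 0.0;
  if (i == 0 && j == 0 && t == 0) return std::exp(-mu * Xab * Xab);
  if (j == 0) { // bring down i
    return (1.0 / (2.0 * p)) * Ecoef(i - 1, j, t - 1, Xab, a, b)
         - (mu * Xab / a)    * Ecoef(i - 1, j, t,     Xab, a, b)
         + (t + 1.0)         * Ecoef(i - 1, j, t + 1, Xab, a, b);
  }
  return (1.0 / (2.0 * p)) * Ecoef(i, j - 1, t - 1, Xab, a, b)
       + (mu * Xab / b)    * Ecoef(i, j - 1, t,     Xab, a, b)
       + (t + 1.0)         * Ecoef(i, j - 1, t + 1, Xab, a, b);
}

// ------------------------------------------- Hermite Coulomb integrals R_tuv
static double hermiteR(int t, int u, int v, int n, double p,
                       double X, double Y, double Z, const double* F) {
  if (t == 0 && u == 0 && v == 0) {
    double val = F[n];
    double f = -2.0 * p;
    for (int k = 0; k < n; ++k) val *= f;
    return val;
  }
  if (t > 0) {
    double r = X * hermiteR(t - 1, u, v, n + 1, p, X, Y, Z, F);
    if (t > 1) r += (t - 1) * hermiteR(t - 2, u, v, n + 1, p, X, Y, Z, F);
    return r;
  }
  if (u > 0) {
    double r = Y * hermiteR(t, u - 1, v, n + 1, p, X, Y, Z, F);
    if (u > 1) r += (u - 1) * hermiteR(t, u - 2, v, n + 1, p, X, Y, Z, F);
    return r;
  }
  double r = Z * hermiteR(t, u, v - 1, n + 1, p, X, Y, Z, F);
  if (v > 1) r += (v - 1) * hermiteR(t, u, v - 2, n + 1, p, X, Y, Z, F);
  return r;
}

struct Prim { double a, c; };
struct AO {
  int l[3];
  double R[3];
  std::vector<Prim> prims;
};

static std::vector<AO> unpack_basis(const IntegerMatrix& ao_l,
                                    const NumericMatrix& ao_center,
                                    const IntegerVector& prim_ptr,
                                    const NumericVector& prim_exp,
                                    const NumericVector& prim_coef) {
  int n = ao_l.nrow();
  std::vector<AO> aos(n);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) { aos[i].l[d] = ao_l(i, d); aos[i].R[d] = ao_center(i, d); }
    for (int k = prim_ptr[i]; k < prim_ptr[i + 1]; ++k)
      aos[i].prims.push_back({prim_exp[k], prim_coef[k]});
  }
  return aos;
}

// 1-D overlap S_ij = E(i,j,0) * sqrt(pi/p); exp factor folded in Ecoef.
static double s1d(int i, int j, double Xab, double a, double b) {
  return Ecoef(i, j, 0, Xab, a, b) * std::sqrt(M_PI / (a + b));
}

// [[Rcpp::export]]
List cpp_one_electron(IntegerMatrix ao_l, NumericMatrix ao_center,
                      IntegerVector prim_ptr, NumericVector prim_exp,
                      NumericVector prim_coef, NumericMatrix atom_pos,
                      NumericVector atom_Z) {
  std::vector<AO> aos = unpack_basis(ao_l, ao_center, prim_ptr, prim_exp, prim_coef);
  int n = aos.size(), natom = atom_Z.size();
  NumericMatrix S(n, n), T(n, n), V(n, n);
  double F[16];
  for (int i = 0; i < n; ++i) for (int j = i; j < n; ++j) {
    const AO &A = aos[i], &B = aos[j];
    double Xab[3];
    for (int d = 0; d < 3; ++d) Xab[d] = A.R[d] - B.R[d];
    double s = 0, t = 0, v = 0;
    for (const Prim& pa : A.prims) for (const Prim& pb : B.prims) {
      double a = pa.a, b = pb.a, cc = pa.c * pb.c, p = a + b;
      double sx[3], kx[3];
      for (int d = 0; d < 3; ++d) {
        int li = A.l[d], lj = B.l[d];
        sx[d] = s1d(li, lj, Xab[d], a, b);
        double k = -2.0 * b * b * s1d(li, lj + 2, Xab[d], a, b)
                 + b * (2.0 * lj + 1.0) * sx[d];
        if (lj >= 2) k -= 0.5 * lj * (lj - 1.0) * s1d(li, lj - 2, Xab[d], a, b);
        kx[d] = k;
      }
      s += cc * sx[0] * sx[1] * sx[2];
      t += cc * (kx[0] * sx[1] * sx[2] + sx[0] * kx[1] * sx[2] + sx[0] * sx[1] * kx[2]);
      // nuclear attraction
      double P[3];
      for (int d = 0; d < 3; ++d) P[d] = (a * A.R[d] + b * B.R[d]) / p;
      int ltot = A.l[0] + A.l[1] + A.l[2] + B.l[0] + B.l[1] + B.l[2];
      for (int m = 0; m < natom; ++m) {
        double PC[3], r2 = 0;
        for (int d = 0; d < 3; ++d) { PC[d] = P[d] - atom_pos(m, d); r2 += PC[d] * PC[d]; }
        boys(ltot, p * r2, F);
        double acc = 0;
        for (int tt = 0; tt <= A.l[0] + B.l[0]; ++tt)
          for (int uu = 0; uu <= A.l[1] + B.l[1]; ++uu)
            for (int vv = 0; vv <= A.l[2] + B.l[2]; ++vv) {
              double e = Ecoef(A.l[0], B.l[0], tt, Xab[0], a, b)
                       * Ecoef(A.l[1], B.l[1], uu, Xab[1], a, b)
                       * Ecoef(A.l[2], B.l[2], vv, Xab[2], a, b);
              if (e != 0.0)
                acc += e * hermiteR(tt, uu, vv, 0, p, PC[0], PC[1], PC[2], F);
            }
        v += cc * (-atom_Z[m]) * (2.0 * M_PI / p) * acc;
      }
    }
    S(i, j) = S(j, i) = s;
    T(i, j) = T(j, i) = t;
    V(i, j) = V(j, i) = v;
  }
  return List::create(_["overlap"] = S, _["kinetic"] = T, _["nuclear"] = V);
}

// Electrostatic potential of chi_i chi_j at arbitrary points:
// out[i,j,k] = \int chi_i(r) chi_j(r) / |r - C_k| d^3r   (positive-kernel sign)
// [[Rcpp::export]]
NumericVector cpp_esp_integrals(IntegerMatrix ao_l, NumericMatrix ao_center,
                                IntegerVector prim_ptr, NumericVector prim_exp,
                                NumericVector prim_coef, NumericMatrix points) {
  std::vector<AO> aos = unpack_basis(ao_l, ao_center, prim_ptr, prim_exp, prim_coef);
  int n = aos.size(), np = points.nrow();
  NumericVector out(n * n * (R_xlen_t)np);
  double F[16];
  for (int i = 0; i < n; ++i) for (int j = i; j < n; ++j) {
    const AO &A = aos[i], &B = aos[j];
    double Xab[3];
    for (int d = 0; d < 3; ++d) Xab[d] = A.R[d] - B.R[d];
    int lx = A.l[0] + B.l[0], ly = A.l[1] + B.l[1], lz = A.l[2] + B.l[2];
    int ltot = lx + ly + lz;
    std::vector<double> acc(np, 0.0);
    for (const Prim& pa : A.prims) for (const Prim& pb : B.prims) {
      double a = pa.a, b = pb.a, cc = pa.c * pb.c, p = a + b;
      double P[3];
      for (int d = 0; d < 3; ++d) P[d] = (a * A.R[d] + b * B.R[d]) / p;
      // precompute E products over (t,u,v)
      std::vector<double> E((lx + 1) * (ly + 1) * (lz + 1));
      for (int tt = 0; tt <= lx; ++tt) for (int uu = 0; uu <= ly; ++uu)
        for (int vv = 0; vv <= lz; ++vv)
          E[(tt * (ly + 1) + uu) * (lz + 1) + vv] =
              Ecoef(A.l[0], B.l[0], tt, Xab[0], a, b)
            * Ecoef(A.l[1], B.l[1], uu, Xab[1], a, b)
            * Ecoef(A.l[2], B.l[2], vv, Xab[2], a, b);
      double pref = cc * 2.0 * M_PI / p;
      for (int k = 0; k < np; ++k) {
        double PC[3], r2 = 0;
        for (int d = 0; d < 3; ++d) { PC[d] = P[d] - points(k, d); r2 += PC[d] * PC[d]; }
        boys(ltot, p * r2, F);
        double s = 0;
        for (int tt = 0; tt <= lx; ++tt) for (int uu = 0; uu <= ly; ++uu)
          for (int vv = 0; vv <= lz; ++vv) {
            double e = E[(tt * (ly + 1) + uu) * (lz + 1) + vv];
            if (e != 0.0) s += e * hermiteR(tt, uu, vv, 0, p, PC[0], PC[1], PC[2], F);
          }
        acc[k] += pref * s;
      }
    }
    for (int k = 0; k < np; ++k) {
      out[(R_xlen_t)k * n * n + j * n + i] = acc[k];
      out[(R_xlen_t)k * n * n + i * n + j] = acc[k];
    }
  }
  out.attr("dim") = IntegerVector::create(n, n, np);
  return out;
}

// Two-electron repulsion integrals, chemists' notation (ij|kl), full n^4 array.
// [[Rcpp::export]]
NumericVector cpp_eri(IntegerMatrix ao_l, NumericMatrix ao_center,
                      IntegerVector prim_ptr, NumericVector prim_exp,
                      NumericVector prim_coef) {
  std::vector<AO> aos = unpack_basis(ao_l, ao_center, prim_ptr, prim_exp, prim_coef);
  int n = aos.size();
  NumericVector out((R_xlen_t)n * n * n * n);
  double F[16];
  for (int i = 0; i < n; ++i) for (int j = 0; j <= i; ++j) {
    int ij = i * (i + 1) / 2 + j;
    for (int k = 0; k < n; ++k) for (int l = 0; l <= k; ++l) {
      int kl = k * (k + 1) / 2 + l;
      if (ij < kl) continue;
      const AO &A = aos[i], &B = aos[j], &C = aos[k], &D = aos[l];
      double Xab[3], Xcd[3];
      for (int d = 0; d < 3; ++d) { Xab[d] = A.R[d] - B.R[d]; Xcd[d] = C.R[d] - D.R[d]; }
      int l1x = A.l[0] + B.l[0], l1y = A.l[1] + B.l[1], l1z = A.l[2] + B.l[2];
      int l2x = C.l[0] + D.l[0], l2y = C.l[1] + D.l[1], l2z = C.l[2] + D.l[2];
      int ltot = l1x + l1y + l1z + l2x + l2y + l2z;
      double val = 0;
      for (const Prim& pa : A.prims) for (const Prim& pb : B.prims) {
        double a = pa.a, b = pb.a, p = a + b;
        double P[3];
        for (int d = 0; d < 3; ++d) P[d] = (a * A.R[d] + b * B.R[d]) / p;
        std::vector<double> E1((l1x + 1) * (l1y + 1) * (l1z + 1));
        for (int tt = 0; tt <= l1x; ++tt) for (int uu = 0; uu <= l1y; ++uu)
          for (int vv = 0; vv <= l1z; ++vv)
            E1[(tt * (l1y + 1) + uu) * (l1z + 1) + vv] =
                Ecoef(A.l[0], B.l[0], tt, Xab[0], a, b)
              * Ecoef(A.l[1], B.l[1], uu, Xab[1], a, b)
              * Ecoef(A.l[2], B.l[2], vv, Xab[2], a, b);
        for (const Prim& pc : C.prims) for (const Prim& pd : D.prims) {
          double c = pc.a, dd = pd.a, q = c + dd;
          double Qc[3];
          for (int d = 0; d < 3; ++d) Qc[d] = (c * C.R[d] + dd * D.R[d]) / q;
          double alpha = p * q / (p + q);
          double PQ[3], r2 = 0;
          for (int d = 0; d < 3; ++d) { PQ[d] = P[d] - Qc[d]; r2 += PQ[d] * PQ[d]; }
          boys(ltot, alpha * r2, F);
          double cpref = pa.c * pb.c * pc.c * pd.c *
            2.0 * std::pow(M_PI, 2.5) / (p * q * std::sqrt(p + q));
          double s = 0;
          for (int t1 = 0; t1 <= l1x; ++t1) for (int u1 = 0; u1 <= l1y; ++u1)
            for (int v1 = 0; v1 <= l1z; ++v1) {
              double e1 = E1[(t1 * (l1y + 1) + u1) * (l1z + 1) + v1];
              if (e1 == 0.0) continue;
              for (int t2 = 0; t2 <= l2x; ++t2) for (int u2 = 0; u2 <= l2y; ++u2)
                for (int v2 = 0; v2 <= l2z; ++v2) {
                  double e2 = Ecoef(C.l[0], D.l[0], t2, Xcd[0], c, dd)
                            * Ecoef(C.l[1], D.l[1], u2, Xcd[1], c, dd)
                            * Ecoef(C.l[2], D.l[2], v2, Xcd[2], c, dd);
                  if (e2 == 0.0) continue;
                  double sgn = ((t2 + u2 + v2) % 2 == 0) ? 1.0 : -1.0;
                  s += e1 * e2 * sgn *
                    hermiteR(t1 + t2, u1 + u2, v1 + v2, 0, alpha,
                             PQ[0], PQ[1], PQ[2], F);
                }
            }
          val += cpref * s;
        }
      }
      // scatter to the 8 permutationally equivalent slots
      int idx[8][4] = {{i,j,k,l},{j,i,k,l},{i,j,l,k},{j,i,l,k},
                       {k,l,i,j},{l,k,i,j},{k,l,j,i},{l,k,j,i}};
      for (int s8 = 0; s8 < 8; ++s8) {
        R_xlen_t ix = ((R_xlen_t)idx[s8][3] * n + idx[s8][2]) * n * n +
                      (R_xlen_t)idx[s8][1] * n + idx[s8][0];
        out[ix] = val;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(n, n, n, n);
  return out;
}

// ======================================================================= FCI
// Determinants encoded as bitmasks: bits 0..n_orb-1 alpha, n_orb..2n_orb-1 beta.
static void enum_strings(int n_orb, int ne, std::vector<int>& out) {
  for (int m = 0; m < (1 << n_orb); ++m)
    if (__builtin_popcount(m) == ne) out.push_back(m);
}

// [[Rcpp::export]]
IntegerMatrix cpp_fci_dets(int n_orb, int n_alpha, int n_beta) {
  std::vector<int> as, bs;
  enum_strings(n_orb, n_alpha, as);
  enum_strings(n_orb, n_beta, bs);
  int dim = as.size() * bs.size();
  IntegerMatrix dets(dim, 2);
  int r = 0;
  for (int ia = 0; ia < (int)as.size(); ++ia)
    for (int ib = 0; ib < (int)bs.size(); ++ib) {
      dets(r, 0) = as[ia]; dets(r, 1) = bs[ib]; ++r;
    }
  return dets;
}

// spin-orbital index: spatial p, spin s(0=alpha,1=beta) -> p + s*n_orb
static inline double eri_at(const double* g, int n, int p, int q, int r, int s) {
  return g[((R_xlen_t)s * n + r) * n * n + (R_xlen_t)q * n + p];
}

// [[Rcpp::export]]
NumericMatrix cpp_fci_hamiltonian(NumericMatrix h, NumericVector g,
                                  int n_orb, IntegerMatrix dets) {
  int dim = dets.nrow();
  const double* gp = g.begin();
  NumericMatrix H(dim, dim);
  int N = 2 * n_orb;
  std::vector<long long> mask(dim);
  for (int I = 0; I < dim; ++I)
    mask[I] = (long long)dets(I, 0) | ((long long)dets(I, 1) << n_orb);
  auto sp  = [n_orb](int so) { return so % n_orb; };
  auto spn = [n_orb](int so) { return so / n_orb; };
  for (int I = 0; I < dim; ++I) {
    long long mI = mask[I];
    std::vector<int> occI;
    for (int t = 0; t < N; ++t) if ((mI >> t) & 1) occI.push_back(t);
    // diagonal
    double e = 0;
    for (size_t x = 0; x < occI.size(); ++x) {
      int p = occI[x];
      e += h(sp(p), sp(p));
      for (size_t y = x + 1; y < occI.size(); ++y) {
        int q = occI[y];
        e += eri_at(gp, n_orb, sp(p), sp(p), sp(q), sp(q));
        if (spn(p) == spn(q))
          e -= eri_at(gp, n_orb, sp(p), sp(q), sp(q), sp(p));
      }
    }
    H(I, I) = e;
    for (int J = I + 1; J < dim; ++J) {
      long long mJ = mask[J];
      long long x = mI ^ mJ;
      int nd = __builtin_popcountll(x);
      if (nd > 4) continue;
      if (nd == 2) { // single excitation m -> r
        long long bi = mI & x, bj = mJ & x;
        int m = __builtin_ctzll(bi), r = __builtin_ctzll(bj);
        if (spn(m) != spn(r)) continue;
        int lo = std::min(m, r), hi = std::max(m, r);
        long long between = mI & (((1LL << hi) - 1) ^ ((1LL << (lo + 1)) - 1));
        double sgn = (__builtin_popcountll(between) % 2) ? -1.0 : 1.0;
        double el = h(sp(m), sp(r));
        for (int q : occI) {
          if (q == m) continue;
          el += eri_at(gp, n_orb, sp(m), sp(r), sp(q), sp(q));
          if (spn(q) == spn(m))
            el -= eri_at(gp, n_orb, sp(m), sp(q), sp(q), sp(r));
        }
        H(I, J) = H(J, I) = sgn * el;
      } else { // double excitation {i<j} -> {a<b}
        long long bi = mI & x, bj = mJ & x;
        int i1 = __builtin_ctzll(bi);
        int j1 = 63 - __builtin_clzll(bi);
        int a1 = __builtin_ctzll(bj);
        int b1 = 63 - __builtin_clzll(bj);
        // phase: annihilate i1 then j1 from I, create b1 then a1
        long long mtmp = mI;
        auto pb = [](long long m, int pos) {
          long long below = m & ((1LL << pos) - 1);
          return (__builtin_popcountll(below) % 2) ? -1.0 : 1.0;
        };
        double sgn = pb(mtmp, i1); mtmp &= ~(1LL << i1);
        sgn *= pb(mtmp, j1); mtmp &= ~(1LL << j1);
        sgn *= pb(mtmp, b1); mtmp |= (1LL << b1);
        sgn *= pb(mtmp, a1); mtmp |= (1LL << a1);
        double el = 0;
        // <j1 i1 || b1 a1> with pairing from operator string a+_a a+_b a_j a_i
        // matrix element: sgn * ( <i1 j1 | a1 b1> - <i1 j1 | b1 a1> ) in
        // physicists' notation with spin deltas; chemists' below.
        if (spn(i1) == spn(a1) && spn(j1) == spn(b1))
          el += eri_at(gp, n_orb, sp(i1), sp(a1), sp(j1), sp(b1));
        if (spn(i1) == spn(b1) && spn(j1) == spn(a1))
          el -= eri_at(gp, n_orb, sp(i1), sp(b1), sp(j1), sp(a1));
        H(I, J) = H(J, I) = sgn * el;
      }
    }
  }
  return H;
}

// E_pq c for all (p,q): returns dim x n_orb^2 matrix, column index p + q*n_orb
// (E_pq = sum_sigma a^+_{p sigma} a_{q sigma}, spatial singlet operator).
// [[Rcpp::export]]
NumericMatrix cpp_fci_epq_all(NumericVector civec, int n_orb, IntegerMatrix dets) {
  int dim = dets.nrow();
  std::unordered_map<long long, int> index;
  std::vector<long long> mask(dim);
  for (int I = 0; I < dim; ++I) {
    mask[I] = (long long)dets(I, 0) | ((long long)dets(I, 1) << n_orb);
    index[mask[I]] = I;
  }
  NumericMatrix out(dim, n_orb * n_orb);
  auto pb = [](long long m, int pos) {
    long long below = m & ((1LL << pos) - 1);
    return (__builtin_popcountll(below) % 2) ? -1.0 : 1.0;
  };
  for (int I = 0; I < dim; ++I) {
    double c = civec[I];
    if (c == 0.0) continue;
    long long mI = mask[I];
    for (int s = 0; s < 2; ++s) {
      for (int q = 0; q < n_orb; ++q) {
        int qso = q + s * n_orb;
        if (!((mI >> qso) & 1)) continue;
        double s1 = pb(mI, qso);
        long long m1 = mI & ~(1LL << qso);
        for (int p = 0; p < n_orb; ++p) {
          int pso = p + s * n_orb;
          if ((m1 >> pso) & 1) continue;
          double s2 = pb(m1, pso);
          long long m2 = m1 | (1LL << pso);
          auto it = index.find(m2);
          if (it != index.end())
            out(it->second, p + q * n_orb) += s1 * s2 * c;
        }
      }
    }
  }
  return out;
}

// ============================================================== statevector
// qubit k <-> spin-orbital k, ordering (phi1a, phi1b, phi2a, ...): qubit of
// spatial p, spin s is 2p+s.  Basis index bit k (of index-1) = occupation of
// qubit k.

// Givens rotation in the two-dimensional subspace spanned by the occupation
// patterns; no Jordan-Wigner parity inside the gate (subspace rotation).
// [[Rcpp::export]]
ComplexVector cpp_sv_excitation(ComplexVector amps, int n_qubits,
                                IntegerVector wires, double theta) {
  R_xlen_t dim = amps.size();
  ComplexVector out = clone(amps);
  double ct = std::cos(theta / 2.0), st = std::sin(theta / 2.0);
  int nw = wires.size();
  if (nw == 2) {
    int a = wires[0], b = wires[1];
    long long ba = 1LL << a, bb = 1LL << b;
    for (R_xlen_t ix = 0; ix < dim; ++ix) {
      long long m = ix;
      if (((m & ba) != 0) && ((m & bb) == 0)) {     // |1_a 0_b> component
        long long jx = (m & ~ba) | bb;              // |0_a 1_b>
        std::complex<double> v10(out[ix].r, out[ix].i);
        std::complex<double> v01(out[jx].r, out[jx].i);
        // |01> -> cos|01> + sin|10>;  |10> -> cos|10> - sin|01>
        std::complex<double> n10 = ct * v10 + st * v01;
        std::complex<double> n01 = ct * v01 - st * v10;
        out[ix].r = n10.real(); out[ix].i = n10.imag();
        out[jx].r = n01.real(); out[jx].i = n01.imag();
      }
    }
  } else {
    int a = wires[0], b = wires[1], c = wires[2], d = wires[3];
    long long ba = 1LL << a, bb = 1LL << b, bc = 1LL << c, bd = 1LL << d;
    for (R_xlen_t ix = 0; ix < dim; ++ix) {
      long long m = ix;
      if (((m & ba) != 0) && ((m & bb) != 0) && ((m & bc) == 0) && ((m & bd) == 0)) {
        long long jx = (m & ~(ba | bb)) | bc | bd;   // |0011> on (a,b,c,d)
        std::complex<double> v1100(out[ix].r, out[ix].i);
        std::complex<double> v0011(out[jx].r, out[jx].i);
        std::complex<double> n1100 = ct * v1100 + st * v0011;
        std::complex<double> n0011 = ct * v0011 - st * v1100;
        out[ix].r = n1100.real(); out[ix].i = n1100.imag();
        out[jx].r = n0011.real(); out[jx].i = n0011.imag();
      }
    }
  }
  return out;
}

// E_pq |psi> for all (p,q) with full Jordan-Wigner parity strings.
// Columns indexed p + q*n_orb (0-based spatial p,q).
// [[Rcpp::export]]
ComplexMatrix cpp_sv_epq_all(ComplexVector amps, int n_orb) {
  int nq = 2 * n_orb;
  R_xlen_t dim = (R_xlen_t)1 << nq;
  ComplexMatrix out(dim, n_orb * n_orb);
  for (R_xlen_t ix = 0; ix < dim; ++ix) {
    double ar = amps[ix].r, ai = amps[ix].i;
    if (ar == 0.0 && ai == 0.0) continue;
    long long m = ix;
    for (int s = 0; s < 2; ++s) for (int q = 0; q < n_orb; ++q) {
      int qq = 2 * q + s;
      if (!((m >> qq) & 1)) continue;
      long long below1 = m & ((1LL << qq) - 1);
      double s1 = (__builtin_popcountll(below1) % 2) ? -1.0 : 1.0;
      long long m1 = m & ~(1LL << qq);
      for (int p = 0; p < n_orb; ++p) {
        int pp = 2 * p + s;
        if ((m1 >> pp) & 1) continue;
        long long below2 = m1 & ((1LL << pp) - 1);
        double s2 = (__builtin_popcountll(below2) % 2) ? -1.0 : 1.0;
        long long m2 = m1 | (1LL << pp);
        double f = s1 * s2;
        int col = p + q * n_orb;
        out(m2, col).r += f * ar;
        out(m2, col).i += f * ai;
      }
    }
  }
  return out;
}

// gamma_pq = <E_pq>, Gamma_pqrs = <E_pq E_rs> - delta_qr <E_ps>
// (real parts; all states reachable here have real-valued RDMs).
// E_pq conserves particle number and S_z, so all work is restricted to the
// rows actually touched (the symmetry sector of the input state).
// [[Rcpp::export]]
List cpp_sv_rdms(ComplexVector amps, int n_orb) {
  int nq = 2 * n_orb;
  R_xlen_t dim = (R_xlen_t)1 << nq;
  int n2 = n_orb * n_orb;
  // build Phi = E_pq |psi> for all columns, tracking active rows
  std::vector<std::complex<double>> Phi((size_t)dim * n2, 0.0);
  std::vector<char> active(dim, 0);
  for (R_xlen_t ix = 0; ix < dim; ++ix) {
    double ar = amps[ix].r, ai = amps[ix].i;
    if (ar == 0.0 && ai == 0.0) continue;
    long long m = ix;
    for (int s = 0; s < 2; ++s) for (int q = 0; q < n_orb; ++q) {
      int qq = 2 * q + s;
      if (!((m >> qq) & 1)) continue;
      long long below1 = m & ((1LL << qq) - 1);
      double s1 = (__builtin_popcountll(below1) % 2) ? -1.0 : 1.0;
      long long m1 = m & ~(1LL << qq);
      for (int p = 0; p < n_orb; ++p) {
        int pp = 2 * p + s;
        if ((m1 >> pp) & 1) continue;
        long long below2 = m1 & ((1LL << pp) - 1);
        double s2 = (__builtin_popcountll(below2) % 2) ? -1.0 : 1.0;
        long long m2 = m1 | (1LL << pp);
        double f = s1 * s2;
        Phi[(size_t)(p + q * n_orb) * dim + m2] += std::complex<double>(f * ar, f * ai);
        active[m2] = 1;
      }
    }
  }
  std::vector<R_xlen_t> rows;
  for (R_xlen_t ix = 0; ix < dim; ++ix) if (active[ix]) rows.push_back(ix);
  NumericMatrix gamma(n_orb, n_orb);
  NumericVector Gamma((R_xlen_t)n2 * n2);
  for (int p = 0; p < n_orb; ++p) for (int q = 0; q < n_orb; ++q) {
    double acc = 0;
    const std::complex<double>* col = &Phi[(size_t)(p + q * n_orb) * dim];
    for (R_xlen_t ix : rows)
      acc += amps[ix].r * col[ix].real() + amps[ix].i * col[ix].imag();
    gamma(p, q) = acc;
  }
  // M[c1, c2] = conj(col c1) . col c2 over active rows (Hermitian)
  std::vector<double> M((size_t)n2 * n2, 0.0);
  for (int c1 = 0; c1 < n2; ++c1) {
    const std::complex<double>* a = &Phi[(size_t)c1 * dim];
    for (int c2 = c1; c2 < n2; ++c2) {
      const std::complex<double>* b = &Phi[(size_t)c2 * dim];
      double acc = 0;
      for (R_xlen_t ix : rows)
        acc += a[ix].real() * b[ix].real() + a[ix].imag() * b[ix].imag();
      M[(size_t)c1 * n2 + c2] = acc;
      M[(size_t)c2 * n2 + c1] = acc;
    }
  }
  for (int p = 0; p < n_orb; ++p) for (int q = 0; q < n_orb; ++q)
    for (int r = 0; r < n_orb; ++r) for (int s = 0; s < n_orb; ++s) {
      double acc = M[(size_t)(q + p * n_orb) * n2 + (r + s * n_orb)];
      if (q == r) acc -= gamma(p, s);
      Gamma[((R_xlen_t)s * n_orb + r) * n2 + (R_xlen_t)q * n_orb + p] = acc;
    }
  Gamma.attr("dim") = IntegerVector::create(n_orb, n_orb, n_orb, n_orb);
  return List::create(_["gamma"] = gamma, _["Gamma"] = Gamma);
}
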