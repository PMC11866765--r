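// Core numerics: solid-harmonic FMM operators, octree evaluation with
// periodic boundary handling, renormalized lattice sums, Ewald summation,
// and a BAOAB integrator for single-site lambda dynamics.
//
// Conventions (validated by unit tests):
//   R_lm(r) = r^l P_l^m(cos th) e^{i m phi} / (l+m)!   (regular)
//   I_lm(r) = (l-m)! P_l^m(cos th) e^{i m phi} / r^{l+1}  (irregular)
//   1/|x-y| = sum_lm conj(R_lm(y)) I_lm(x)   for |y| < |x|
// Multipole about c:  M_lm = sum_i q_i conj(R_lm(x_i - c))
// Local expansion:    phi(x) = Re sum_jk L_jk conj(R_jk(x - c))
// M2L (t = c_tgt - c_src): L_jk = (-1)^j sum_lm I_{j+l,k+m}(t) M_lm
// All potentials are returned without the Coulomb prefactor (applied in R).
//
// The operator pipeline is templated on the real type: double for production
// runs, float for the genuine single-precision mode (the error-floor
// behaviour of single precision comes from float arithmetic in the
// recursions and translations, not merely from rounded storage). The
// lattice-sum response involves factorial-scale magnitudes and therefore
// always stays in double; its result is rounded to float in single mode.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

static inline int hidx(int l, int m) { return l * (l + 1) + m; }
static inline int ncoef(int p) { return (p + 1) * (p + 1); }

// ---------------------------------------------------------------------------
// solid harmonics
// ---------------------------------------------------------------------------

// regular solid harmonics R_lm up to degree p at point (x,y,z)
template <typename T>
static void reg_harm(T x, T y, T z, int p, std::vector<std::complex<T> > &R) {
  typedef std::complex<T> CT;
  R.assign(ncoef(p), CT(0, 0));
  const T r2 = x * x + y * y + z * z;
  const CT xy(x, y);
  R[hidx(0, 0)] = CT(1, 0);
  for (int l = 1; l <= p; ++l) {
    R[hidx(l, l)] = -xy * (T(1) / T(2 * l)) * R[hidx(l - 1, l - 1)];
    for (int m = 0; m < l; ++m) {
      CT prev2 = (m <= l - 2) ? R[hidx(l - 2, m)] : CT(0, 0);
      R[hidx(l, m)] = (T(2 * l - 1) * z * R[hidx(l - 1, m)] - r2 * prev2) *
                      (T(1) / T((l + m) * (l - m)));
    }
    for (int m = 1; m <= l; ++m) {
      T sg = (m % 2 == 0) ? T(1) : T(-1);
      R[hidx(l, -m)] = sg * std::conj(R[hidx(l, m)]);
    }
  }
}

// irregular solid harmonics I_lm up to degree p
template <typename T>
static void irr_harm(T x, T y, T z, int p, std::vector<std::complex<T> > &I) {
  typedef std::complex<T> CT;
  I.assign(ncoef(p), CT(0, 0));
  const T r2 = x * x + y * y + z * z;
  if (r2 == T(0)) stop("irregular harmonics undefined at the origin");
  const CT xy(x, y);
  I[hidx(0, 0)] = CT(T(1) / std::sqrt(r2), 0);
  for (int l = 1; l <= p; ++l) {
    I[hidx(l, l)] = -T(2 * l - 1) * xy * I[hidx(l - 1, l - 1)] / r2;
    for (int m = 0; m < l; ++m) {
      T c2 = T((l - 1) * (l - 1) - m * m);
      CT prev2 = (m <= l - 2) ? I[hidx(l - 2, m)] : CT(0, 0);
      I[hidx(l, m)] = (T(2 * l - 1) * z * I[hidx(l - 1, m)] - c2 * prev2) / r2;
    }
    for (int m = 1; m <= l; ++m) {
      T sg = (m % 2 == 0) ? T(1) : T(-1);
      I[hidx(l, -m)] = sg * std::conj(I[hidx(l, m)]);
    }
  }
}

// [[Rcpp::export]]
ComplexVector cpp_regular_harmonics(NumericVector x, int p) {
  std::vector<cplx> R;
  reg_harm<double>(x[0], x[1], x[2], p, R);
  ComplexVector out(R.size());
  for (size_t i = 0; i < R.size(); ++i) { out[i].r = R[i].real(); out[i].i = R[i].imag(); }
  return out;
}

// [[Rcpp::export]]
ComplexVector cpp_irregular_harmonics(NumericVector x, int p) {
  std::vector<cplx> I;
  irr_harm<double>(x[0], x[1], x[2], p, I);
  ComplexVector out(I.size());
  for (size_t i = 0; i < I.size(); ++i) { out[i].r = I[i].real(); out[i].i = I[i].imag(); }
  return out;
}

static std::vector<cplx> as_cvec(const ComplexVector &v) {
  std::vector<cplx> out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = cplx(v[i].r, v[i].i);
  return out;
}
static ComplexVector as_Cvec(const std::vector<cplx> &v) {
  ComplexVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) { out[i].r = v[i].real(); out[i].i = v[i].imag(); }
  return out;
}

// ---------------------------------------------------------------------------
// operators (templated on the real type)
// ---------------------------------------------------------------------------

template <typename T>
static void p2m_add(const double *xi, double q, const double *c, int p,
                    std::vector<std::complex<T> > &R,
                    std::vector<std::complex<T> > &M) {
  reg_harm<T>(T(xi[0] - c[0]), T(xi[1] - c[1]), T(xi[2] - c[2]), p, R);
  for (int i = 0; i < ncoef(p); ++i) M[i] += T(q) * std::conj(R[i]);
}

// shift multipole from child center to parent center
template <typename T>
static void m2m(const std::vector<std::complex<T> > &Mc,
                const std::vector<std::complex<T> > &Rt, int p,
                std::vector<std::complex<T> > &Mp) {
  typedef std::complex<T> CT;
  for (int l = 0; l <= p; ++l)
    for (int m = -l; m <= l; ++m) {
      CT acc(0, 0);
      for (int j = 0; j <= l; ++j) {
        int lo = std::max(-j, m - (l - j)), hi = std::min(j, m + (l - j));
        for (int k = lo; k <= hi; ++k)
          acc += std::conj(Rt[hidx(j, k)]) * Mc[hidx(l - j, m - k)];
      }
      Mp[hidx(l, m)] += acc;
    }
}

// multipole to local; It = irregular harmonics of t = c_tgt - c_src, degree 2p
template <typename T>
static void m2l(const std::vector<std::complex<T> > &M,
                const std::vector<std::complex<T> > &It, int p,
                std::vector<std::complex<T> > &L) {
  typedef std::complex<T> CT;
  for (int j = 0; j <= p; ++j) {
    T sg = (j % 2 == 0) ? T(1) : T(-1);
    for (int k = -j; k <= j; ++k) {
      CT acc(0, 0);
      for (int l = 0; l <= p; ++l)
        for (int m = -l; m <= l; ++m)
          acc += It[hidx(j + l, k + m)] * M[hidx(l, m)];
      L[hidx(j, k)] += sg * acc;
    }
  }
}

// m2l exploiting conjugate symmetry of real-source multipoles: only k >= 0
// targets are computed; the caller restores k < 0 via L_{j,-k} = (-1)^k conj
template <typename T>
static void m2l_half(const std::complex<T> *M,
                     const std::vector<std::complex<T> > &It, int p,
                     std::vector<std::complex<T> > &L) {
  typedef std::complex<T> CT;
  for (int j = 0; j <= p; ++j) {
    T sg = (j % 2 == 0) ? T(1) : T(-1);
    for (int k = 0; k <= j; ++k) {
      CT acc(0, 0);
      const CT *Mrow = M;
      for (int l = 0; l <= p; ++l) {
        const CT *Irow = &It[hidx(j + l, k)];
        for (int m = -l; m <= l; ++m)
          acc += Irow[m] * Mrow[l + m];
        Mrow += 2 * l + 1;
      }
      L[hidx(j, k)] += sg * acc;
    }
  }
}

template <typename T>
static void restore_negative_k(std::vector<std::complex<T> > &L, int p) {
  for (int j = 1; j <= p; ++j)
    for (int k = 1; k <= j; ++k) {
      T sg = (k % 2 == 0) ? T(1) : T(-1);
      L[hidx(j, -k)] = sg * std::conj(L[hidx(j, k)]);
    }
}

// shift local from parent to child
template <typename T>
static void l2l(const std::vector<std::complex<T> > &Lp,
                const std::vector<std::complex<T> > &Rs, int p,
                std::vector<std::complex<T> > &Lc) {
  typedef std::complex<T> CT;
  for (int j = 0; j <= p; ++j)
    for (int k = -j; k <= j; ++k) {
      CT acc(0, 0);
      for (int l = j; l <= p; ++l) {
        int lo = std::max(-l, k - (l - j)), hi = std::min(l, k + (l - j));
        for (int m = lo; m <= hi; ++m)
          acc += Lp[hidx(l, m)] * std::conj(Rs[hidx(l - j, m - k)]);
      }
      Lc[hidx(j, k)] += acc;
    }
}

// evaluate local expansion (potential and gradient) at dx = x - center
template <typename T>
static void l2p(const std::vector<std::complex<T> > &L, int p,
                T dx, T dy, T dz, double &phi, double *grad) {
  typedef std::complex<T> CT;
  std::vector<CT> R;
  reg_harm<T>(dx, dy, dz, p, R);
  CT sphi(0, 0), sgx(0, 0), sgy(0, 0), sgz(0, 0);
  for (int j = 0; j <= p; ++j)
    for (int k = -j; k <= j; ++k) {
      CT Ljk = L[hidx(j, k)];
      sphi += Ljk * std::conj(R[hidx(j, k)]);
      if (j >= 1) {
        CT rm = (std::abs(k - 1) <= j - 1) ? std::conj(R[hidx(j - 1, k - 1)]) : CT(0, 0);
        CT rp = (std::abs(k + 1) <= j - 1) ? std::conj(R[hidx(j - 1, k + 1)]) : CT(0, 0);
        CT r0 = (std::abs(k) <= j - 1) ? std::conj(R[hidx(j - 1, k)]) : CT(0, 0);
        sgx += Ljk * (rp - rm) * T(0.5);
        sgy += Ljk * CT(0, T(0.5)) * (rp + rm);
        sgz += Ljk * r0;
      }
    }
  phi = (double)sphi.real();
  grad[0] = (double)sgx.real(); grad[1] = (double)sgy.real();
  grad[2] = (double)sgz.real();
}

// [[Rcpp::export]]
ComplexVector cpp_p2m(NumericMatrix pos, NumericVector q, NumericVector center, int p) {
  std::vector<cplx> M(ncoef(p), cplx(0, 0)), R;
  double c[3] = {center[0], center[1], center[2]};
  for (int i = 0; i < pos.nrow(); ++i) {
    double xi[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    p2m_add<double>(xi, q[i], c, p, R, M);
  }
  return as_Cvec(M);
}

// [[Rcpp::export]]
ComplexVector cpp_m2m(ComplexVector M, NumericVector t, int p) {
  std::vector<cplx> Mc = as_cvec(M), Rt, Mp(ncoef(p), cplx(0, 0));
  reg_harm<double>(t[0], t[1], t[2], p, Rt);
  m2m<double>(Mc, Rt, p, Mp);
  return as_Cvec(Mp);
}

// [[Rcpp::export]]
ComplexVector cpp_m2l(ComplexVector M, NumericVector t, int p) {
  std::vector<cplx> Ms = as_cvec(M), It, L(ncoef(p), cplx(0, 0));
  irr_harm<double>(t[0], t[1], t[2], 2 * p, It);
  m2l<double>(Ms, It, p, L);
  return as_Cvec(L);
}

// [[Rcpp::export]]
ComplexVector cpp_l2l(ComplexVector L, NumericVector s, int p) {
  std::vector<cplx> Lp = as_cvec(L), Rs, Lc(ncoef(p), cplx(0, 0));
  reg_harm<double>(s[0], s[1], s[2], p, Rs);
  l2l<double>(Lp, Rs, p, Lc);
  return as_Cvec(Lc);
}

// [[Rcpp::export]]
List cpp_l2p(ComplexVector L, NumericMatrix pos, NumericVector center, int p) {
  std::vector<cplx> Lc = as_cvec(L);
  int n = pos.nrow();
  NumericVector phi(n);
  NumericMatrix grad(n, 3);
  for (int i = 0; i < n; ++i) {
    double ph, g[3];
    l2p<double>(Lc, p, pos(i, 0) - center[0], pos(i, 1) - center[1],
                pos(i, 2) - center[2], ph, g);
    phi[i] = ph;
    grad(i, 0) = g[0]; grad(i, 1) = g[1]; grad(i, 2) = g[2];
  }
  return List::create(_["phi"] = phi, _["grad"] = grad);
}

// evaluate multipole expansion far away (potential only; used in tests)
// [[Rcpp::export]]
NumericVector cpp_m2p(ComplexVector M, NumericMatrix pos, NumericVector center, int p) {
  std::vector<cplx> Ms = as_cvec(M), I;
  int n = pos.nrow();
  NumericVector phi(n);
  for (int i = 0; i < n; ++i) {
    irr_harm<double>(pos(i, 0) - center[0], pos(i, 1) - center[1],
                     pos(i, 2) - center[2], p, I);
    cplx s(0, 0);
    for (int j = 0; j < ncoef(p); ++j) s += Ms[j] * I[j];
    phi[i] = s.real();
  }
  return phi;
}

// ---------------------------------------------------------------------------
// direct sums
// ---------------------------------------------------------------------------

// isolated all-pairs potential/gradient (no prefactor), deterministic order
// [[Rcpp::export]]
List cpp_direct_isolated(NumericMatrix pos, NumericVector q) {
  int n = pos.nrow();
  NumericVector phi(n);
  NumericMatrix grad(n, 3);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1), dz = pos(i, 2) - pos(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 == 0.0) stop("coincident particles %d and %d", i + 1, j + 1);
      double r = std::sqrt(r2), ir3 = 1.0 / (r2 * r);
      phi[i] += q[j] / r;
      grad(i, 0) -= q[j] * dx * ir3;
      grad(i, 1) -= q[j] * dy * ir3;
      grad(i, 2) -= q[j] * dz * ir3;
    }
  return List::create(_["phi"] = phi, _["grad"] = grad);
}

// periodic first-shell direct sum: central box pairs plus the 26 nearest
// image cells, self-images included (the d = 0 near field)
template <typename REAL>
static void shell_sum(const NumericMatrix &pos, const NumericVector &q, double L,
                      NumericVector &phi, NumericMatrix &grad) {
  int n = pos.nrow();
  std::vector<REAL> ph(n, (REAL)0), gx(n, (REAL)0), gy(n, (REAL)0), gz(n, (REAL)0);
  for (int sx = -1; sx <= 1; ++sx)
    for (int sy = -1; sy <= 1; ++sy)
      for (int sz = -1; sz <= 1; ++sz) {
        bool central = (sx == 0 && sy == 0 && sz == 0);
        for (int i = 0; i < n; ++i)
          for (int j = 0; j < n; ++j) {
            if (central && i == j) continue;
            REAL dx = (REAL)(pos(i, 0) - pos(j, 0) - sx * L);
            REAL dy = (REAL)(pos(i, 1) - pos(j, 1) - sy * L);
            REAL dz = (REAL)(pos(i, 2) - pos(j, 2) - sz * L);
            REAL r2 = dx * dx + dy * dy + dz * dz;
            if (r2 == (REAL)0) stop("coincident particles %d and %d", i + 1, j + 1);
            REAL r = std::sqrt(r2), ir3 = (REAL)1 / (r2 * r);
            ph[i] += (REAL)q[j] / r;
            gx[i] -= (REAL)q[j] * dx * ir3;
            gy[i] -= (REAL)q[j] * dy * ir3;
            gz[i] -= (REAL)q[j] * dz * ir3;
          }
      }
  for (int i = 0; i < n; ++i) {
    phi[i] = (double)ph[i];
    grad(i, 0) = (double)gx[i]; grad(i, 1) = (double)gy[i]; grad(i, 2) = (double)gz[i];
  }
}

// [[Rcpp::export]]
List cpp_direct_first_shell(NumericMatrix pos, NumericVector q, double L,
                            bool single_precision = false) {
  int n = pos.nrow();
  NumericVector phi(n);
  NumericMatrix grad(n, 3);
  if (single_precision) shell_sum<float>(pos, q, L, phi, grad);
  else shell_sum<double>(pos, q, L, phi, grad);
  return List::create(_["phi"] = phi, _["grad"] = grad);
}

// ---------------------------------------------------------------------------
// Ewald summation (tinfoil boundary), no prefactor
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_ewald(NumericMatrix pos, NumericVector q, double L, double beta,
               int nreal, int kmax, bool background = false) {
  int n = pos.nrow();
  double V = L * L * L;
  NumericVector phi(n);
  NumericMatrix grad(n, 3);
  const double twob_sqpi = 2.0 * beta / std::sqrt(M_PI);

  // real space
  for (int sx = -nreal; sx <= nreal; ++sx)
    for (int sy = -nreal; sy <= nreal; ++sy)
      for (int sz = -nreal; sz <= nreal; ++sz) {
        bool central = (sx == 0 && sy == 0 && sz == 0);
        for (int i = 0; i < n; ++i)
          for (int j = 0; j < n; ++j) {
            if (central && i == j) continue;
            double dx = pos(i, 0) - pos(j, 0) - sx * L;
            double dy = pos(i, 1) - pos(j, 1) - sy * L;
            double dz = pos(i, 2) - pos(j, 2) - sz * L;
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 == 0.0) stop("coincident particles %d and %d", i + 1, j + 1);
            double r = std::sqrt(r2);
            double er = std::erfc(beta * r);
            phi[i] += q[j] * er / r;
            double fr = (er / r2 + twob_sqpi * std::exp(-beta * beta * r2) / r) / r;
            grad(i, 0) -= q[j] * fr * dx;
            grad(i, 1) -= q[j] * fr * dy;
            grad(i, 2) -= q[j] * fr * dz;
          }
      }

  // reciprocal space
  double pref = 4.0 * M_PI / V;
  for (int hx = -kmax; hx <= kmax; ++hx)
    for (int hy = -kmax; hy <= kmax; ++hy)
      for (int hz = -kmax; hz <= kmax; ++hz) {
        if (hx == 0 && hy == 0 && hz == 0) continue;
        double gx = 2.0 * M_PI * hx / L, gy = 2.0 * M_PI * hy / L, gz = 2.0 * M_PI * hz / L;
        double g2 = gx * gx + gy * gy + gz * gz;
        double w = pref * std::exp(-g2 / (4.0 * beta * beta)) / g2;
        if (w < 1e-20) continue;
        double Sre = 0.0, Sim = 0.0;
        for (int j = 0; j < n; ++j) {
          double ph = gx * pos(j, 0) + gy * pos(j, 1) + gz * pos(j, 2);
          Sre += q[j] * std::cos(ph);
          Sim += q[j] * std::sin(ph);
        }
        for (int i = 0; i < n; ++i) {
          double ph = gx * pos(i, 0) + gy * pos(i, 1) + gz * pos(i, 2);
          double cp = std::cos(ph), sp = std::sin(ph);
          phi[i] += w * (cp * Sre + sp * Sim);
          double dd = w * (-sp * Sre + cp * Sim);
          grad(i, 0) += dd * gx; grad(i, 1) += dd * gy; grad(i, 2) += dd * gz;
        }
      }

  // self term and optional neutralizing background
  double Q = 0.0;
  for (int i = 0; i < n; ++i) Q += q[i];
  for (int i = 0; i < n; ++i) phi[i] -= twob_sqpi * q[i];
  if (background)
    for (int i = 0; i < n; ++i) phi[i] -= M_PI / (beta * beta * V) * Q;

  return List::create(_["phi"] = phi, _["grad"] = grad, _["total_charge"] = Q);
}

// ---------------------------------------------------------------------------
// lattice sums Lambda_JK = sum_{|n|_inf >= 2} I_JK(n)  (unit box lattice)
// high degrees by shellwise direct summation, low degrees by the factor-3
// hierarchical renormalization fixed point; conditionally convergent degrees
// (J <= 2) pinned to zero
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
ComplexVector cpp_lattice_sums(int jtop, int jext = 60, int maxshell = 24,
                               int jdirect_min = 16, double tol = 1e-15,
                               int maxit = 200) {
  int NC = ncoef(jtop);
  std::vector<cplx> lam(NC, cplx(0, 0));   // working values
  std::vector<cplx> lamR(NC, cplx(0, 0));  // sum over shells 2..4 only
  std::vector<cplx> I;

  // shellwise direct summation; per-shell degree cap from (2/s)^(J-1) <= tol
  for (int s = 2; s <= maxshell; ++s) {
    int jcap = jtop;
    if (s > 2) {
      double need = 1.0 + (-std::log10(tol)) / std::log10(0.5 * s);
      jcap = std::min(jtop, (int)std::ceil(need) + 4);
    }
    for (int nx = -s; nx <= s; ++nx)
      for (int ny = -s; ny <= s; ++ny)
        for (int nz = -s; nz <= s; ++nz) {
          if (std::max(std::abs(nx), std::max(std::abs(ny), std::abs(nz))) != s) continue;
          irr_harm<double>((double)nx, (double)ny, (double)nz, jcap, I);
          for (int J = 0; J <= jcap; ++J)
            for (int K = -J; K <= J; ++K) {
              lam[hidx(J, K)] += I[hidx(J, K)];
              if (s <= 4) lamR[hidx(J, K)] += I[hidx(J, K)];
            }
        }
  }

  // supercell aggregation coefficients G_{j'k'} = (-1)^{j'} sum_r conj(R_{j'k'}(r))
  std::vector<cplx> G(ncoef(jext), cplx(0, 0)), R;
  for (int rx = -1; rx <= 1; ++rx)
    for (int ry = -1; ry <= 1; ++ry)
      for (int rz = -1; rz <= 1; ++rz) {
        reg_harm<double>((double)rx, (double)ry, (double)rz, jext, R);
        for (int j = 0; j <= jext; ++j) {
          double sg = (j % 2 == 0) ? 1.0 : -1.0;
          for (int k = -j; k <= j; ++k) G[hidx(j, k)] += sg * std::conj(R[hidx(j, k)]);
        }
      }

  // fixed point for low degrees: Lambda_J = LambdaR_J +
  //   sum_{j'} G_{j'k'} 3^{-(J+j'+1)} Lambda_{J+j',K+k'}
  int jlow = jdirect_min - 1;  // degrees 3..jlow solved by iteration
  for (int it = 0; it < maxit; ++it) {
    double delta = 0.0;
    for (int J = 3; J <= std::min(jlow, jtop); ++J)
      for (int K = -J; K <= J; ++K) {
        cplx acc = lamR[hidx(J, K)];
        for (int j = 0; j <= jext && J + j <= jtop; ++j) {
          double sc = std::pow(3.0, -(double)(J + j + 1));
          int lo = std::max(-j, -(J + j) - K), hi = std::min(j, (J + j) - K);
          for (int k = lo; k <= hi; ++k) {
            cplx g = G[hidx(j, k)];
            if (g == cplx(0, 0)) continue;
            acc += g * sc * lam[hidx(J + j, K + k)];
          }
        }
        delta = std::max(delta, std::abs(acc - lam[hidx(J, K)]));
        lam[hidx(J, K)] = acc;
      }
    if (delta < tol) break;
    if (it == maxit - 1) stop("lattice-sum renormalization did not converge (residual %g)", delta);
  }

  // enforce exact cubic symmetry: J odd, or K not a multiple of 4 -> 0;
  // J in {0,1,2} conditionally convergent -> pinned to 0
  for (int J = 0; J <= jtop; ++J)
    for (int K = -J; K <= J; ++K) {
      if (J <= 2 || J % 2 == 1 || ((K % 4) + 4) % 4 != 0)
        lam[hidx(J, K)] = cplx(0, 0);
    }
  return as_Cvec(lam);
}

// apply the lattice operator: local expansion (about the box center) of all
// periodic images beyond the first shell, from box multipole omega, box edge L
static void lattice_apply(const std::vector<cplx> &omega, const std::vector<cplx> &lam,
                          int p, int jtop, double L, std::vector<cplx> &Lloc) {
  std::vector<double> Lpow(2 * p + 2);
  double il = 1.0 / L;
  Lpow[0] = il;  // L^{-(J+1)} with J = 0 -> 1/L
  for (int J = 1; J <= 2 * p + 1; ++J) Lpow[J] = Lpow[J - 1] * il;
  if (2 * p > jtop) stop("lattice sums built to degree %d, need %d", jtop, 2 * p);
  for (int j = 0; j <= p; ++j) {
    double sg = (j % 2 == 0) ? 1.0 : -1.0;
    for (int k = -j; k <= j; ++k) {
      cplx acc(0, 0);
      for (int l = 0; l <= p; ++l)
        for (int m = -l; m <= l; ++m)
          acc += lam[hidx(j + l, k + m)] * Lpow[j + l] * omega[hidx(l, m)];
      Lloc[hidx(j, k)] += sg * acc;
    }
  }
}

// [[Rcpp::export]]
ComplexVector cpp_lattice_apply(ComplexVector omega, ComplexVector lambda_sums,
                                int p, int jtop, double L) {
  std::vector<cplx> om = as_cvec(omega), lam = as_cvec(lambda_sums);
  std::vector<cplx> Lloc(ncoef(p), cplx(0, 0));
  lattice_apply(om, lam, p, jtop, L, Lloc);
  return as_Cvec(Lloc);
}

// ---------------------------------------------------------------------------
// octree FMM evaluation
// ---------------------------------------------------------------------------

static inline int wrap_mod(int a, int g) { int r = a % g; return (r < 0) ? r + g : r; }
static inline int floor_div(int a, int g) { return (a >= 0) ? a / g : -(((-a) + g - 1) / g); }

// near-field P2P over adjacent leaf cells (periodic wrap optional)
template <typename REAL>
static void p2p_tree(const NumericMatrix &pos, const NumericVector &q, double L,
                     int d, bool periodic, const std::vector<std::vector<int> > &members,
                     NumericVector &phi, NumericMatrix &grad) {
  int g = 1 << d;
  int n = pos.nrow();
  std::vector<REAL> ph(n, (REAL)0), gx(n, (REAL)0), gy(n, (REAL)0), gz(n, (REAL)0);
  for (int bx = 0; bx < g; ++bx)
    for (int by = 0; by < g; ++by)
      for (int bz = 0; bz < g; ++bz) {
        int b = (bx * g + by) * g + bz;
        const std::vector<int> &ti = members[b];
        if (ti.empty()) continue;
        for (int ox = -1; ox <= 1; ++ox)
          for (int oy = -1; oy <= 1; ++oy)
            for (int oz = -1; oz <= 1; ++oz) {
              int ax = bx + ox, ay = by + oy, az = bz + oz;
              double shx = 0, shy = 0, shz = 0;
              int sxr = ax, syr = ay, szr = az;
              if (periodic) {
                shx = floor_div(ax, g) * L; shy = floor_div(ay, g) * L; shz = floor_div(az, g) * L;
                sxr = wrap_mod(ax, g); syr = wrap_mod(ay, g); szr = wrap_mod(az, g);
              } else if (ax < 0 || ay < 0 || az < 0 || ax >= g || ay >= g || az >= g) {
                continue;
              }
              int s = (sxr * g + syr) * g + szr;
              const std::vector<int> &sj = members[s];
              bool self_cell = (s == b && shx == 0 && shy == 0 && shz == 0);
              for (size_t a = 0; a < ti.size(); ++a) {
                int i = ti[a];
                REAL pxi = (REAL)pos(i, 0), pyi = (REAL)pos(i, 1), pzi = (REAL)pos(i, 2);
                REAL aph = 0, agx = 0, agy = 0, agz = 0;
                for (size_t bb = 0; bb < sj.size(); ++bb) {
                  int j = sj[bb];
                  if (self_cell && i == j) continue;
                  REAL dx = pxi - (REAL)(pos(j, 0) + shx);
                  REAL dy = pyi - (REAL)(pos(j, 1) + shy);
                  REAL dz = pzi - (REAL)(pos(j, 2) + shz);
                  REAL r2 = dx * dx + dy * dy + dz * dz;
                  if (r2 == (REAL)0) stop("coincident particles %d and %d", i + 1, j + 1);
                  REAL r = std::sqrt(r2), ir3 = (REAL)1 / (r2 * r);
                  aph += (REAL)q[j] / r;
                  agx -= (REAL)q[j] * dx * ir3;
                  agy -= (REAL)q[j] * dy * ir3;
                  agz -= (REAL)q[j] * dz * ir3;
                }
                ph[i] += aph; gx[i] += agx; gy[i] += agy; gz[i] += agz;
              }
            }
      }
  for (int i = 0; i < n; ++i) {
    phi[i] = (double)ph[i];
    grad(i, 0) = (double)gx[i]; grad(i, 1) = (double)gy[i]; grad(i, 2) = (double)gz[i];
  }
}

// [[Rcpp::export]]
IntegerVector cpp_leaf_assign(NumericMatrix pos, double L, int d) {
  int g = 1 << d, n = pos.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (pos(i, 0) < 0 || pos(i, 1) < 0 || pos(i, 2) < 0 ||
        pos(i, 0) >= L || pos(i, 1) >= L || pos(i, 2) >= L)
      stop("particle %d outside the box [0, L)", i + 1);
    int ix = std::min((int)(pos(i, 0) / L * g), g - 1);
    int iy = std::min((int)(pos(i, 1) / L * g), g - 1);
    int iz = std::min((int)(pos(i, 2) / L * g), g - 1);
    out[i] = (ix * g + iy) * g + iz + 1;  // 1-based box id
  }
  return out;
}

// tree pipeline (everything except the lattice far field) in real type T
template <typename T>
static void fmm_tree(const NumericMatrix &pos, const NumericVector &q, double L,
                     int p, int d, bool periodic,
                     const std::vector<std::vector<int> > &members,
                     NumericVector &phi_near, NumericMatrix &grad_near,
                     NumericVector &phi_far, NumericMatrix &grad_far,
                     std::vector<cplx> &omega_out) {
  typedef std::complex<T> CT;
  int n = pos.nrow(), nc = ncoef(p);
  int g = 1 << d;
  int nleaf = g * g * g;

  std::vector<std::vector<CT> > M(d + 1);
  for (int ell = d; ell >= 0; --ell) {
    int ge = 1 << ell;
    M[ell].assign((size_t)ge * ge * ge * nc, CT(0, 0));
  }
  // P2M at leaves
  {
    double w = L / g;
    std::vector<CT> Rtmp;
    for (int b = 0; b < nleaf; ++b) {
      if (members[b].empty()) continue;
      int bx = b / (g * g), by = (b / g) % g, bz = b % g;
      double c[3] = {(bx + 0.5) * w, (by + 0.5) * w, (bz + 0.5) * w};
      std::vector<CT> Mb(nc, CT(0, 0));
      for (size_t a = 0; a < members[b].size(); ++a) {
        int i = members[b][a];
        double xi[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
        p2m_add<T>(xi, q[i], c, p, Rtmp, Mb);
      }
      for (int t = 0; t < nc; ++t) M[d][(size_t)b * nc + t] = Mb[t];
    }
  }
  // M2M upwards
  for (int ell = d; ell >= 1; --ell) {
    int ge = 1 << ell, gp = ge / 2;
    double w = L / ge;
    std::vector<std::vector<CT> > R8(8);
    for (int cc = 0; cc < 8; ++cc) {
      int cx = (cc >> 2) & 1, cy = (cc >> 1) & 1, cz = cc & 1;
      reg_harm<T>(T((cx ? 0.5 : -0.5) * w), T((cy ? 0.5 : -0.5) * w),
                  T((cz ? 0.5 : -0.5) * w), p, R8[cc]);
    }
    for (int bx = 0; bx < ge; ++bx)
      for (int by = 0; by < ge; ++by)
        for (int bz = 0; bz < ge; ++bz) {
          int b = (bx * ge + by) * ge + bz;
          std::vector<CT> Mc(M[ell].begin() + (size_t)b * nc,
                             M[ell].begin() + (size_t)(b + 1) * nc);
          bool empty = true;
          for (int t = 0; t < nc; ++t) if (Mc[t] != CT(0, 0)) { empty = false; break; }
          if (empty) continue;
          int pb = ((bx / 2) * gp + (by / 2)) * gp + (bz / 2);
          int cc = ((bx & 1) << 2) | ((by & 1) << 1) | (bz & 1);
          std::vector<CT> Mp(nc, CT(0, 0));
          m2m<T>(Mc, R8[cc], p, Mp);
          for (int t = 0; t < nc; ++t) M[ell - 1][(size_t)pb * nc + t] += Mp[t];
        }
  }

  // local expansions per level
  std::vector<std::vector<CT> > Lex(d + 1);
  for (int ell = 1; ell <= d; ++ell) {
    int ge = 1 << ell;
    Lex[ell].assign((size_t)ge * ge * ge * nc, CT(0, 0));
  }

  // M2L with cached translation harmonics for integer offsets
  for (int ell = 1; ell <= d; ++ell) {
    int ge = 1 << ell, gp = ge / 2;
    double w = L / ge;
    std::vector<std::vector<CT> > Icache(7 * 7 * 7);
    for (int ox = -3; ox <= 3; ++ox)
      for (int oy = -3; oy <= 3; ++oy)
        for (int oz = -3; oz <= 3; ++oz) {
          if (std::abs(ox) <= 1 && std::abs(oy) <= 1 && std::abs(oz) <= 1) continue;
          int ci = ((ox + 3) * 7 + (oy + 3)) * 7 + (oz + 3);
          irr_harm<T>(T(-ox * w), T(-oy * w), T(-oz * w), 2 * p, Icache[ci]);
        }
    std::vector<char> occ((size_t)ge * ge * ge, 0);
    for (size_t b = 0; b < occ.size(); ++b) {
      const CT *Ms = &M[ell][(size_t)b * nc];
      for (int t = 0; t < nc; ++t)
        if (Ms[t] != CT(0, 0)) { occ[b] = 1; break; }
    }
    for (int tx = 0; tx < ge; ++tx)
      for (int ty = 0; ty < ge; ++ty)
        for (int tz = 0; tz < ge; ++tz) {
          int tb = (tx * ge + ty) * ge + tz;
          std::vector<CT> Lacc(nc, CT(0, 0));
          bool any = false;
          int px = tx / 2, py = ty / 2, pz = tz / 2;
          for (int pox = -1; pox <= 1; ++pox)
            for (int poy = -1; poy <= 1; ++poy)
              for (int poz = -1; poz <= 1; ++poz) {
                int spx = px + pox, spy = py + poy, spz = pz + poz;
                if (!periodic &&
                    (spx < 0 || spy < 0 || spz < 0 || spx >= gp || spy >= gp || spz >= gp))
                  continue;
                for (int cc = 0; cc < 8; ++cc) {
                  int ax = 2 * spx + ((cc >> 2) & 1);
                  int ay = 2 * spy + ((cc >> 1) & 1);
                  int az = 2 * spz + (cc & 1);
                  int ox = ax - tx, oy = ay - ty, oz = az - tz;
                  if (std::abs(ox) <= 1 && std::abs(oy) <= 1 && std::abs(oz) <= 1) continue;
                  int sxr = ax, syr = ay, szr = az;
                  if (periodic) { sxr = wrap_mod(ax, ge); syr = wrap_mod(ay, ge); szr = wrap_mod(az, ge); }
                  int sb = (sxr * ge + syr) * ge + szr;
                  if (!occ[sb]) continue;
                  int ci = ((ox + 3) * 7 + (oy + 3)) * 7 + (oz + 3);
                  m2l_half<T>(&M[ell][(size_t)sb * nc], Icache[ci], p, Lacc);
                  any = true;
                }
              }
          if (any) {
            restore_negative_k<T>(Lacc, p);
            for (int t = 0; t < nc; ++t) Lex[ell][(size_t)tb * nc + t] += Lacc[t];
          }
        }
  }

  // L2L downwards
  for (int ell = 1; ell < d; ++ell) {
    int ge = 1 << ell, gc = ge * 2;
    double wc = L / gc;
    std::vector<std::vector<CT> > R8(8);
    for (int cc = 0; cc < 8; ++cc) {
      int cx = (cc >> 2) & 1, cy = (cc >> 1) & 1, cz = cc & 1;
      reg_harm<T>(T((cx ? 0.5 : -0.5) * wc), T((cy ? 0.5 : -0.5) * wc),
                  T((cz ? 0.5 : -0.5) * wc), p, R8[cc]);
    }
    for (int bx = 0; bx < ge; ++bx)
      for (int by = 0; by < ge; ++by)
        for (int bz = 0; bz < ge; ++bz) {
          int b = (bx * ge + by) * ge + bz;
          std::vector<CT> Lp(Lex[ell].begin() + (size_t)b * nc,
                             Lex[ell].begin() + (size_t)(b + 1) * nc);
          bool empty = true;
          for (int t = 0; t < nc; ++t) if (Lp[t] != CT(0, 0)) { empty = false; break; }
          if (empty) continue;
          for (int cc = 0; cc < 8; ++cc) {
            int cxi = 2 * bx + ((cc >> 2) & 1), cyi = 2 * by + ((cc >> 1) & 1), czi = 2 * bz + (cc & 1);
            int cb = (cxi * gc + cyi) * gc + czi;
            std::vector<CT> Lc(nc, CT(0, 0));
            l2l<T>(Lp, R8[cc], p, Lc);
            for (int t = 0; t < nc; ++t) Lex[ell + 1][(size_t)cb * nc + t] += Lc[t];
          }
        }
  }

  // far-field evaluation at particles
  if (d >= 1) {
    double w = L / g;
    for (int b = 0; b < nleaf; ++b) {
      if (members[b].empty()) continue;
      int bx = b / (g * g), by = (b / g) % g, bz = b % g;
      double c[3] = {(bx + 0.5) * w, (by + 0.5) * w, (bz + 0.5) * w};
      std::vector<CT> Lb(Lex[d].begin() + (size_t)b * nc,
                         Lex[d].begin() + (size_t)(b + 1) * nc);
      for (size_t a = 0; a < members[b].size(); ++a) {
        int i = members[b][a];
        double ph, gr[3];
        l2p<T>(Lb, p, T(pos(i, 0) - c[0]), T(pos(i, 1) - c[1]),
               T(pos(i, 2) - c[2]), ph, gr);
        phi_far[i] = ph;
        grad_far(i, 0) = gr[0]; grad_far(i, 1) = gr[1]; grad_far(i, 2) = gr[2];
      }
    }
  }

  // near field
  p2p_tree<T>(pos, q, L, d, periodic, members, phi_near, grad_near);

  // root multipole (double copy for the lattice stage)
  omega_out.assign(nc, cplx(0, 0));
  for (int t = 0; t < nc; ++t)
    omega_out[t] = cplx((double)M[0][t].real(), (double)M[0][t].imag());
}

// full FMM evaluation; returns decomposed potentials/gradients (no prefactor)
// [[Rcpp::export]]
List cpp_fmm(NumericMatrix pos, NumericVector q, double L, int p, int d,
             bool periodic, Nullable<ComplexVector> lattice_sums_ = R_NilValue,
             int jtop = 0, bool single_mode = false) {
  int n = pos.nrow(), nc = ncoef(p);
  int g = 1 << d;
  int nleaf = g * g * g;

  std::vector<std::vector<int> > members(nleaf);
  {
    IntegerVector ids = cpp_leaf_assign(pos, L, d);
    for (int i = 0; i < n; ++i) members[ids[i] - 1].push_back(i);
  }

  NumericVector phi_near(n), phi_far(n), phi_lat(n);
  NumericMatrix grad_near(n, 3), grad_far(n, 3), grad_lat(n, 3);
  std::vector<cplx> omega;
  if (single_mode) {
    if (p > 20) stop("single-precision mode supports p <= 20 (float range)");
    fmm_tree<float>(pos, q, L, p, d, periodic, members,
                    phi_near, grad_near, phi_far, grad_far, omega);
  } else {
    fmm_tree<double>(pos, q, L, p, d, periodic, members,
                     phi_near, grad_near, phi_far, grad_far, omega);
  }

  if (periodic) {
    if (lattice_sums_.isNull()) stop("periodic evaluation requires lattice sums");
    std::vector<cplx> lam = as_cvec(ComplexVector(lattice_sums_));
    std::vector<cplx> Lroot(nc, cplx(0, 0));
    lattice_apply(omega, lam, p, jtop, L, Lroot);
    if (single_mode)
      for (int t = 0; t < nc; ++t)
        Lroot[t] = cplx((double)(float)Lroot[t].real(), (double)(float)Lroot[t].imag());
    double cb[3] = {L / 2, L / 2, L / 2};
    for (int i = 0; i < n; ++i) {
      double ph, gr[3];
      l2p<double>(Lroot, p, pos(i, 0) - cb[0], pos(i, 1) - cb[1], pos(i, 2) - cb[2], ph, gr);
      phi_lat[i] = single_mode ? (double)(float)ph : ph;
      for (int kk = 0; kk < 3; ++kk)
        grad_lat(i, kk) = single_mode ? (double)(float)gr[kk] : gr[kk];
    }
  }

  return List::create(_["phi_near"] = phi_near, _["grad_near"] = grad_near,
                      _["phi_far"] = phi_far, _["grad_far"] = grad_far,
                      _["phi_lat"] = phi_lat, _["grad_lat"] = grad_lat,
                      _["omega"] = as_Cvec(omega));
}

// ---------------------------------------------------------------------------
// lambda-dynamics BAOAB kernel (frozen coordinates, one titratable site)
// H(site part) = c' wt + 0.5 wt' A wt  with wt the form weights; A = 0 for HI
// ---------------------------------------------------------------------------

// binary-tree form weights; lambda_0 is the most significant bit; ghost-leaf
// weights are folded into the last real form
static void form_weights(const double *lam, int nl, int nf, double *w) {
  int nleaf = 1 << nl;
  for (int b = 0; b < nleaf; ++b) {
    double wb = 1.0;
    for (int l = 0; l < nl; ++l) {
      int bit = (b >> (nl - 1 - l)) & 1;
      wb *= bit ? lam[l] : (1.0 - lam[l]);
    }
    if (b < nf - 1) w[b] = wb;
    else if (b == nf - 1) w[nf - 1] = wb;
    else w[nf - 1] += wb;
  }
}

// d w_rho / d lambda_l
static void form_weights_jac(const double *lam, int nl, int nf, double *J) {
  int nleaf = 1 << nl;
  for (int t = 0; t < nf * nl; ++t) J[t] = 0.0;
  for (int b = 0; b < nleaf; ++b) {
    int rho = (b < nf) ? b : nf - 1;
    for (int l = 0; l < nl; ++l) {
      double d = 1.0;
      for (int l2 = 0; l2 < nl; ++l2) {
        int bit = (b >> (nl - 1 - l2)) & 1;
        if (l2 == l) d *= bit ? 1.0 : -1.0;
        else d *= bit ? lam[l2] : (1.0 - lam[l2]);
      }
      J[rho * nl + l] += d;
    }
  }
}

// [[Rcpp::export]]
List cpp_baoab_site(NumericVector lambda0, NumericVector v0, NumericVector mass,
                    int n_forms, NumericVector cvec, NumericMatrix Amat,
                    double dt, double gamma, double kT, double barrier,
                    int n_steps, int sample_every) {
  int nl = lambda0.size(), nf = n_forms;
  std::vector<double> lam(lambda0.begin(), lambda0.end());
  std::vector<double> vel(v0.begin(), v0.end());
  std::vector<double> w(nf), J(nf * nl), F(nl), Aw(nf);
  double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;

  int nsamp = n_steps / sample_every;
  NumericMatrix lam_out(nsamp, nl), vel_out(nsamp, nl);
  NumericVector ener(nsamp);

  // force on each lambda: -J^T (c + A w) - dV/dlambda
  #define COMPUTE_F do {                                            \
    form_weights(lam.data(), nl, nf, w.data());                     \
    form_weights_jac(lam.data(), nl, nf, J.data());                 \
    for (int r = 0; r < nf; ++r) {                                  \
      Aw[r] = cvec[r];                                              \
      for (int r2 = 0; r2 < nf; ++r2) Aw[r] += Amat(r, r2) * w[r2]; \
    }                                                               \
    for (int l = 0; l < nl; ++l) {                                  \
      double f = 0.0;                                               \
      for (int r = 0; r < nf; ++r) f -= J[r * nl + l] * Aw[r];      \
      double x = lam[l];                                            \
      f -= 32.0 * barrier * x * (1.0 - x) * (1.0 - 2.0 * x);        \
      F[l] = f;                                                     \
    }                                                               \
  } while (0)

  COMPUTE_F;
  int isamp = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int l = 0; l < nl; ++l) vel[l] += 0.5 * dt * F[l] / mass[l];
    for (int l = 0; l < nl; ++l) {
      lam[l] += 0.5 * dt * vel[l];
      while (lam[l] < 0.0 || lam[l] > 1.0) {
        if (lam[l] < 0.0) lam[l] = -lam[l]; else lam[l] = 2.0 - lam[l];
        vel[l] = -vel[l];
      }
    }
    if (gamma > 0) {
      for (int l = 0; l < nl; ++l) {
        double c2 = std::sqrt(kT / mass[l] * (1.0 - c1 * c1));
        vel[l] = c1 * vel[l] + c2 * R::norm_rand();
      }
    }
    for (int l = 0; l < nl; ++l) {
      lam[l] += 0.5 * dt * vel[l];
      while (lam[l] < 0.0 || lam[l] > 1.0) {
        if (lam[l] < 0.0) lam[l] = -lam[l]; else lam[l] = 2.0 - lam[l];
        vel[l] = -vel[l];
      }
    }
    COMPUTE_F;
    for (int l = 0; l < nl; ++l) vel[l] += 0.5 * dt * F[l] / mass[l];

    if (step % sample_every == 0 && isamp < nsamp) {
      double epot = 0.0, ekin = 0.0;
      form_weights(lam.data(), nl, nf, w.data());
      for (int r = 0; r < nf; ++r) {
        double aw = 0.0;
        for (int r2 = 0; r2 < nf; ++r2) aw += Amat(r, r2) * w[r2];
        epot += cvec[r] * w[r] + 0.5 * aw * w[r];
      }
      for (int l = 0; l < nl; ++l) {
        double x = lam[l];
        epot += 16.0 * barrier * x * x * (1.0 - x) * (1.0 - x);
        ekin += 0.5 * mass[l] * vel[l] * vel[l];
        lam_out(isamp, l) = lam[l];
        vel_out(isamp, l) = vel[l];
      }
      ener[isamp] = epot + ekin;
      ++isamp;
    }
  }
  #undef COMPUTE_F
  return List::create(_["lambda"] = lam_out, _["velocity"] = vel_out,
                      _["energy"] = ener,
                      _["final_lambda"] = NumericVector(lam.begin(), lam.end()),
                      _["final_velocity"] = NumericVector(vel.begin(), vel.end()));
}

// round to 32-bit storage (single-precision staging)
// [[Rcpp::export]]
NumericVector cpp_float_round(NumericVector x) {
  NumericVector out(x.size());
  for (int i = 0; i < x.size(); ++i) out[i] = (double)(float)x[i];
  return out;
}
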