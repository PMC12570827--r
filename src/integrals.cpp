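// One- and two-electron integrals over contracted Cartesian Gaussians
// (McMurchie-Davidson scheme) plus the closed-shell Fock build.
//
// The R side passes a shell specification (angular momentum, center,
// primitive exponents and raw contraction coefficients); everything else --
// primitive and contracted normalization, Cartesian component expansion,
// Boys function, shell-pair data reuse, Schwarz screening, packed ERI
// storage -- lives here.  Recursions are general in l; the shipped basis
// sets use s, p and d functions.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>

using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// ---------------------------------------------------------------- Boys F_m(T)
static void boys(double T, int mmax, double *F) {
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (T > 30.0) {
    // asymptotic F0 then stable upward recursion
    F[0] = 0.5 * std::sqrt(PI / T);
    double expT = std::exp(-T);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - expT) / (2.0 * T);
    return;
  }
  // series for the highest order, then downward recursion (both stable)
  double expT = std::exp(-T);
  double sum = 0.0, term = 1.0 / (2.0 * mmax + 1.0);
  for (int k = 0; k < 250; ++k) {
    sum += term;
    term *= 2.0 * T / (2.0 * mmax + 2.0 * k + 3.0);
    if (term < 1e-17 * sum) break;
  }
  F[mmax] = expT * sum;
  for (int m = mmax; m > 0; --m)
    F[m - 1] = (2.0 * T * F[m] + expT) / (2.0 * m - 1.0);
}

// ------------------------------------------- Hermite expansion coefficients
// E_t^{ij} for the product of two 1D Gaussians.
struct Etab {
  int imax, jmax, tmax;
  std::vector<double> v;
  double at(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(i * (jmax + 1) + j) * (tmax + 1) + t];
  }
};

static Etab build_E(int imax, int jmax, double a, double b, double AB) {
  Etab E;
  E.imax = imax; E.jmax = jmax; E.tmax = imax + jmax;
  E.v.assign((imax + 1) * (jmax + 1) * (E.tmax + 1), 0.0);
  double p = a + b, mu = a * b / p;
  auto set = [&](int i, int j, int t, double val) {
    E.v[(i * (jmax + 1) + j) * (E.tmax + 1) + t] = val;
  };
  set(0, 0, 0, std::exp(-mu * AB * AB));
  for (int i = 1; i <= imax; ++i)
    for (int t = 0; t <= i; ++t) {
      double val = 0.0;
      if (t - 1 >= 0) val += E.at(i - 1, 0, t - 1) / (2.0 * p);
      val += -(b / p) * AB * E.at(i - 1, 0, t);
      val += (t + 1) * E.at(i - 1, 0, t + 1);
      set(i, 0, t, val);
    }
  for (int j = 1; j <= jmax; ++j)
    for (int i = 0; i <= imax; ++i)
      for (int t = 0; t <= i + j; ++t) {
        double val = 0.0;
        if (t - 1 >= 0) val += E.at(i, j - 1, t - 1) / (2.0 * p);
        val += (a / p) * AB * E.at(i, j - 1, t);
        val += (t + 1) * E.at(i, j - 1, t + 1);
        set(i, j, t, val);
      }
  return E;
}

// --------------------------------------------- Hermite Coulomb R^0_{t,u,v}
// Fixed-capacity table, reused across primitive quartets.
struct Rtab {
  int nmax, dim;
  std::vector<double> v;
  void resize(int n) {
    nmax = n; dim = n + 1;
    size_t need = (size_t)dim * dim * dim * dim;
    if (v.size() < need) v.resize(need);
  }
  double &at(int n, int t, int u, int w) {
    return v[((size_t)(n * dim + t) * dim + u) * dim + w];
  }
};

static void build_R(int tmax, double alpha, double X, double Y, double Z,
                    Rtab &R) {
  int n = tmax;
  R.resize(n);
  double T = alpha * (X * X + Y * Y + Z * Z);
  double F[32];
  boys(T, n, F);
  double fac = 1.0;
  for (int m = 0; m <= n; ++m) { R.at(m, 0, 0, 0) = fac * F[m]; fac *= -2.0 * alpha; }
  for (int t = 0; t <= n; ++t)
    for (int u = 0; u <= n - t; ++u)
      for (int w = 0; w <= n - t - u; ++w) {
        if (t + u + w == 0) continue;
        for (int m = 0; m <= n - t - u - w; ++m) {
          double val;
          if (t > 0) {
            val = X * R.at(m + 1, t - 1, u, w);
            if (t > 1) val += (t - 1) * R.at(m + 1, t - 2, u, w);
          } else if (u > 0) {
            val = Y * R.at(m + 1, t, u - 1, w);
            if (u > 1) val += (u - 1) * R.at(m + 1, t, u - 2, w);
          } else {
            val = Z * R.at(m + 1, t, u, w - 1);
            if (w > 1) val += (w - 1) * R.at(m + 1, t, u, w - 2);
          }
          R.at(m, t, u, w) = val;
        }
      }
}

// ------------------------------------------------------------- basis set-up
static double dfact(int n) { // (2n-1)!! with (-1)!! = 1
  double r = 1.0;
  for (int k = 2 * n - 1; k > 1; k -= 2) r *= k;
  return r;
}

static double prim_norm(double a, int lx, int ly, int lz) {
  int L = lx + ly + lz;
  double num = std::pow(2.0, 2 * L + 1.5) * std::pow(a, L + 1.5);
  double den = dfact(lx) * dfact(ly) * dfact(lz) * std::pow(PI, 1.5);
  return std::sqrt(num / den);
}

struct Shell {
  int l, atom;                  // atom 0-based
  double x, y, z;
  std::vector<double> exps;
  std::vector<double> coefs;    // includes prim_norm for (l,0,0)
  int bf0, ncomp;               // first basis-function index, #components
};

struct Comp { int lx, ly, lz; double scale; }; // scale: component/(l,0,0) norm

static std::vector<Comp> components(int l) {
  std::vector<Comp> out;
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly) {
      int lz = l - lx - ly;
      double scale = std::sqrt(dfact(l) / (dfact(lx) * dfact(ly) * dfact(lz)));
      out.push_back({lx, ly, lz, scale});
    }
  return out;
}

// per primitive pair of a shell pair: totals and E tables for all components
struct PrimPair {
  double p, px, py, pz, c; // c = c1*c2 (with (l,0,0) norms)
  Etab Ex, Ey, Ez;         // imax = l1, jmax = l2, per dimension
};

struct ShellPair {
  int s1, s2;
  std::vector<PrimPair> pp;
};

static ShellPair make_shell_pair(const Shell &A, const Shell &B,
                                 int s1, int s2) {
  ShellPair sp; sp.s1 = s1; sp.s2 = s2;
  for (size_t i = 0; i < A.exps.size(); ++i)
    for (size_t j = 0; j < B.exps.size(); ++j) {
      PrimPair q;
      double a = A.exps[i], b = B.exps[j];
      q.p = a + b;
      q.px = (a * A.x + b * B.x) / q.p;
      q.py = (a * A.y + b * B.y) / q.p;
      q.pz = (a * A.z + b * B.z) / q.p;
      q.c = A.coefs[i] * B.coefs[j];
      q.Ex = build_E(A.l, B.l, a, b, A.x - B.x);
      q.Ey = build_E(A.l, B.l, a, b, A.y - B.y);
      q.Ez = build_E(A.l, B.l, a, b, A.z - B.z);
      sp.pp.push_back(q);
    }
  return sp;
}

// contracted ERI block for a shell quartet; out is indexed
// [ca*ncompB*ncompC*ncompD + cb*ncompC*ncompD + cc*ncompD + cd]
static void eri_shell_quartet(const Shell &A, const Shell &B,
                              const Shell &C, const Shell &D,
                              const ShellPair &ab, const ShellPair &cd,
                              const std::vector<Comp> &cA,
                              const std::vector<Comp> &cB,
                              const std::vector<Comp> &cC,
                              const std::vector<Comp> &cD,
                              Rtab &R, std::vector<double> &out) {
  int nB = (int)cB.size(), nC = (int)cC.size(), nD = (int)cD.size();
  int ntot = (int)cA.size() * nB * nC * nD;
  out.assign(ntot, 0.0);
  int Lmax = A.l + B.l + C.l + D.l;
  for (const PrimPair &q1 : ab.pp) {
    for (const PrimPair &q2 : cd.pp) {
      double p = q1.p, q = q2.p;
      double alpha = p * q / (p + q);
      build_R(Lmax, alpha, q1.px - q2.px, q1.py - q2.py, q1.pz - q2.pz, R);
      double pref = q1.c * q2.c * 2.0 * std::pow(PI, 2.5) /
                    (p * q * std::sqrt(p + q));
      int idx = 0;
      for (int ca = 0; ca < (int)cA.size(); ++ca)
        for (int cb = 0; cb < nB; ++cb)
          for (int cc = 0; cc < nC; ++cc)
            for (int cdx = 0; cdx < nD; ++cdx, ++idx) {
              const Comp &a = cA[ca], &b = cB[cb], &c = cC[cc], &d = cD[cdx];
              int tmax = a.lx + b.lx, umax = a.ly + b.ly, wmax = a.lz + b.lz;
              int smax = c.lx + d.lx, vmax = c.ly + d.ly, gmax = c.lz + d.lz;
              double sum = 0.0;
              for (int t = 0; t <= tmax; ++t) {
                double ex1 = q1.Ex.at(a.lx, b.lx, t);
                if (ex1 == 0.0) continue;
                for (int u = 0; u <= umax; ++u) {
                  double exy1 = ex1 * q1.Ey.at(a.ly, b.ly, u);
                  if (exy1 == 0.0) continue;
                  for (int w = 0; w <= wmax; ++w) {
                    double e1 = exy1 * q1.Ez.at(a.lz, b.lz, w);
                    if (e1 == 0.0) continue;
                    for (int s = 0; s <= smax; ++s) {
                      double ex2 = q2.Ex.at(c.lx, d.lx, s);
                      if (ex2 == 0.0) continue;
                      for (int v = 0; v <= vmax; ++v) {
                        double exy2 = ex2 * q2.Ey.at(c.ly, d.ly, v);
                        if (exy2 == 0.0) continue;
                        for (int g = 0; g <= gmax; ++g) {
                          double e2 = exy2 * q2.Ez.at(c.lz, d.lz, g);
                          if (e2 == 0.0) continue;
                          double sign = ((s + v + g) % 2) ? -1.0 : 1.0;
                          sum += e1 * e2 * sign * R.at(0, t + s, u + v, w + g);
                        }
                      }
                    }
                  }
                }
              }
              out[idx] += pref * a.scale * b.scale * c.scale * d.scale * sum;
            }
    }
  }
}

static inline R_xlen_t pair_index(R_xlen_t i, R_xlen_t j) {
  return (i >= j) ? i * (i + 1) / 2 + j : j * (j + 1) / 2 + i;
}

// one-electron contracted integrals over two shell components
struct BFview { int lx, ly, lz; double x, y, z; };

static double overlap_contr(const ShellPair &sp, const Comp &a, const Comp &b) {
  double s = 0.0;
  for (const PrimPair &q : sp.pp)
    s += q.c * q.Ex.at(a.lx, b.lx, 0) * q.Ey.at(a.ly, b.ly, 0) *
         q.Ez.at(a.lz, b.lz, 0) * std::pow(PI / q.p, 1.5);
  return s * a.scale * b.scale;
}

// [[Rcpp::export(name = ".integrals_cpp")]]
List integrals_cpp(IntegerVector atom_z, NumericMatrix coords,
                   IntegerVector shell_l, IntegerVector shell_atom,
                   List shell_exps, List shell_coefs,
                   double schwarz_cut = 1e-11) {
  int nsh = shell_l.size();
  std::vector<Shell> shells(nsh);
  int nbf = 0;
  for (int s = 0; s < nsh; ++s) {
    Shell &sh = shells[s];
    sh.l = shell_l[s]; sh.atom = shell_atom[s] - 1;
    sh.x = coords(sh.atom, 0); sh.y = coords(sh.atom, 1);
    sh.z = coords(sh.atom, 2);
    NumericVector ex = shell_exps[s], cf = shell_coefs[s];
    for (int k = 0; k < ex.size(); ++k) {
      sh.exps.push_back(ex[k]);
      sh.coefs.push_back(cf[k] * prim_norm(ex[k], sh.l, 0, 0));
    }
    sh.bf0 = nbf;
    sh.ncomp = (sh.l + 1) * (sh.l + 2) / 2;
    nbf += sh.ncomp;
  }
  if (nbf > 160)
    stop("basis too large (%d functions); molecule beyond supported size", nbf);

  // component tables per l actually present
  int lmax = 0;
  for (int s = 0; s < nsh; ++s) lmax = std::max(lmax, shells[s].l);
  std::vector<std::vector<Comp>> comp_l(lmax + 1);
  for (int l = 0; l <= lmax; ++l) comp_l[l] = components(l);

  // shell pairs (s1 >= s2)
  std::vector<ShellPair> pairs;
  std::vector<std::vector<int>> pair_of(nsh, std::vector<int>(nsh, -1));
  for (int s1 = 0; s1 < nsh; ++s1)
    for (int s2 = 0; s2 <= s1; ++s2) {
      pair_of[s1][s2] = pair_of[s2][s1] = (int)pairs.size();
      pairs.push_back(make_shell_pair(shells[s1], shells[s2], s1, s2));
    }

  // contracted normalization per basis function (via diagonal overlap)
  std::vector<double> bfnorm(nbf);
  IntegerVector bf_atom(nbf);
  for (int s = 0; s < nsh; ++s) {
    const ShellPair &sp = pairs[pair_of[s][s]];
    const std::vector<Comp> &cs = comp_l[shells[s].l];
    for (int c = 0; c < shells[s].ncomp; ++c) {
      double s00 = overlap_contr(sp, cs[c], cs[c]);
      bfnorm[shells[s].bf0 + c] = 1.0 / std::sqrt(s00);
      bf_atom[shells[s].bf0 + c] = shells[s].atom + 1;
    }
  }

  // ---- overlap, kinetic, nuclear attraction
  NumericMatrix S(nbf, nbf), T(nbf, nbf), V(nbf, nbf);
  std::vector<double> Zs(atom_z.size());
  std::vector<double> cx(atom_z.size()), cy(atom_z.size()), cz(atom_z.size());
  for (int k = 0; k < atom_z.size(); ++k) {
    Zs[k] = atom_z[k];
    cx[k] = coords(k, 0); cy[k] = coords(k, 1); cz[k] = coords(k, 2);
  }
  Rtab Rbuf;
  for (int s1 = 0; s1 < nsh; ++s1)
    for (int s2 = 0; s2 <= s1; ++s2) {
      const Shell &A = shells[s1], &B = shells[s2];
      const std::vector<Comp> &cA = comp_l[A.l], &cB = comp_l[B.l];
      for (int ca = 0; ca < A.ncomp; ++ca)
        for (int cb = 0; cb < B.ncomp; ++cb) {
          int i = A.bf0 + ca, j = B.bf0 + cb;
          if (j > i) continue;
          const Comp &a = cA[ca], &b = cB[cb];
          double sv = 0.0, tv = 0.0, vv = 0.0;
          for (size_t ip = 0; ip < A.exps.size(); ++ip)
            for (size_t jp = 0; jp < B.exps.size(); ++jp) {
              double ea = A.exps[ip], eb = B.exps[jp];
              double cc = A.coefs[ip] * B.coefs[jp];
              double p = ea + eb, pref = std::pow(PI / p, 1.5);
              Etab Ex = build_E(A.l + 2, B.l + 2, ea, eb, A.x - B.x);
              Etab Ey = build_E(A.l + 2, B.l + 2, ea, eb, A.y - B.y);
              Etab Ez = build_E(A.l + 2, B.l + 2, ea, eb, A.z - B.z);
              double sx = Ex.at(a.lx, b.lx, 0), sy = Ey.at(a.ly, b.ly, 0),
                     sz = Ez.at(a.lz, b.lz, 0);
              sv += cc * pref * sx * sy * sz;
              // kinetic via l+/-2 overlaps in each dimension
              auto k1d = [&](const Etab &E, int l1, int l2) {
                double t = 0.0;
                if (l2 >= 2) t += l2 * (l2 - 1) * E.at(l1, l2 - 2, 0);
                t += -2.0 * eb * (2.0 * l2 + 1.0) * E.at(l1, l2, 0);
                t += 4.0 * eb * eb * E.at(l1, l2 + 2, 0);
                return -0.5 * t;
              };
              tv += cc * pref * (k1d(Ex, a.lx, b.lx) * sy * sz +
                                 sx * k1d(Ey, a.ly, b.ly) * sz +
                                 sx * sy * k1d(Ez, a.lz, b.lz));
              // nuclear attraction
              double Px = (ea * A.x + eb * B.x) / p;
              double Py = (ea * A.y + eb * B.y) / p;
              double Pz = (ea * A.z + eb * B.z) / p;
              int tmax = a.lx + b.lx, umax = a.ly + b.ly, wmax = a.lz + b.lz;
              double vk = 0.0;
              for (size_t k = 0; k < Zs.size(); ++k) {
                build_R(tmax + umax + wmax, p, Px - cx[k], Py - cy[k],
                        Pz - cz[k], Rbuf);
                double acc = 0.0;
                for (int t = 0; t <= tmax; ++t)
                  for (int u = 0; u <= umax; ++u)
                    for (int w = 0; w <= wmax; ++w)
                      acc += Ex.at(a.lx, b.lx, t) * Ey.at(a.ly, b.ly, u) *
                             Ez.at(a.lz, b.lz, w) * Rbuf.at(0, t, u, w);
                vk += -Zs[k] * acc;
              }
              vv += cc * (2.0 * PI / p) * vk;
            }
          double nn = a.scale * b.scale * bfnorm[i] * bfnorm[j];
          S(i, j) = S(j, i) = sv * nn;
          T(i, j) = T(j, i) = tv * nn;
          V(i, j) = V(j, i) = vv * nn;
        }
    }

  // ---- two-electron integrals, shell-quartet driven
  R_xlen_t npair = (R_xlen_t)nbf * (nbf + 1) / 2;
  NumericVector eri(npair * (npair + 1) / 2);
  std::vector<double> block;

  // Schwarz bound per shell pair: max over components of sqrt(|(ab|ab)|)
  std::vector<double> Qsh(pairs.size(), 0.0);
  for (size_t sp = 0; sp < pairs.size(); ++sp) {
    const Shell &A = shells[pairs[sp].s1], &B = shells[pairs[sp].s2];
    eri_shell_quartet(A, B, A, B, pairs[sp], pairs[sp],
                      comp_l[A.l], comp_l[B.l], comp_l[A.l], comp_l[B.l],
                      Rbuf, block);
    int nA = A.ncomp, nB = B.ncomp;
    double qmax = 0.0;
    for (int ca = 0; ca < nA; ++ca)
      for (int cb = 0; cb < nB; ++cb) {
        int idx = ((ca * nB + cb) * nA + ca) * nB + cb;
        double nrm = bfnorm[A.bf0 + ca] * bfnorm[B.bf0 + cb];
        qmax = std::max(qmax, std::sqrt(std::fabs(block[idx])) * nrm);
      }
    Qsh[sp] = qmax;
  }

  for (int s1 = 0; s1 < nsh; ++s1)
    for (int s2 = 0; s2 <= s1; ++s2) {
      int sp12 = pair_of[s1][s2];
      for (int s3 = 0; s3 <= s1; ++s3) {
        int s4max = (s3 == s1) ? s2 : s3;
        for (int s4 = 0; s4 <= s4max; ++s4) {
          int sp34 = pair_of[s3][s4];
          if (Qsh[sp12] * Qsh[sp34] < schwarz_cut) continue;
          const Shell &A = shells[s1], &B = shells[s2],
                      &C = shells[s3], &D = shells[s4];
          eri_shell_quartet(A, B, C, D, pairs[sp12], pairs[sp34],
                            comp_l[A.l], comp_l[B.l], comp_l[C.l],
                            comp_l[D.l], Rbuf, block);
          int nB2 = B.ncomp, nC = C.ncomp, nD = D.ncomp;
          int idx = 0;
          for (int ca = 0; ca < A.ncomp; ++ca)
            for (int cb = 0; cb < nB2; ++cb)
              for (int cc = 0; cc < nC; ++cc)
                for (int cdx = 0; cdx < nD; ++cdx, ++idx) {
                  int i = A.bf0 + ca, j = B.bf0 + cb,
                      k = C.bf0 + cc, l = D.bf0 + cdx;
                  double val = block[idx] * bfnorm[i] * bfnorm[j] *
                               bfnorm[k] * bfnorm[l];
                  eri[pair_index(pair_index(i, j), pair_index(k, l))] = val;
                }
        }
      }
    }

  // nuclear repulsion
  double enuc = 0.0;
  for (int a = 0; a < atom_z.size(); ++a)
    for (int b = 0; b < a; ++b) {
      double dx = cx[a] - cx[b], dy = cy[a] - cy[b], dz = cz[a] - cz[b];
      enuc += Zs[a] * Zs[b] / std::sqrt(dx * dx + dy * dy + dz * dz);
    }

  return List::create(_["S"] = S, _["T"] = T, _["V"] = V, _["eri"] = eri,
                      _["n_basis"] = nbf, _["bf_atom"] = bf_atom,
                      _["e_nuc"] = enuc);
}

// [[Rcpp::export(name = ".fock_g_cpp")]]
NumericMatrix fock_g_cpp(NumericMatrix D, NumericVector eri, int n) {
  NumericMatrix J(n, n), K(n, n);
  int perms[8][4];
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j) {
      R_xlen_t ij = pair_index(i, j);
      for (int k = 0; k <= i; ++k) {
        int lmax = (k == i) ? j : k;
        for (int l = 0; l <= lmax; ++l) {
          R_xlen_t kl = pair_index(k, l);
          double val = eri[pair_index(ij, kl)];
          if (val == 0.0) continue;
          // all 8 symmetry-related index tuples, deduplicated, so that
          // J_pq = sum_rs D_rs (pq|rs) and K_pr = sum_qs D_qs (pq|rs)
          // each receive every (pq|rs) exactly once
          int cand[8][4] = {{i,j,k,l},{j,i,k,l},{i,j,l,k},{j,i,l,k},
                            {k,l,i,j},{l,k,i,j},{k,l,j,i},{l,k,j,i}};
          int nperm = 0;
          for (int c = 0; c < 8; ++c) {
            bool dup = false;
            for (int d = 0; d < nperm; ++d)
              if (perms[d][0]==cand[c][0] && perms[d][1]==cand[c][1] &&
                  perms[d][2]==cand[c][2] && perms[d][3]==cand[c][3]) {
                dup = true; break;
              }
            if (!dup) {
              for (int q = 0; q < 4; ++q) perms[nperm][q] = cand[c][q];
              ++nperm;
            }
          }
          for (int c = 0; c < nperm; ++c) {
            int p = perms[c][0], q = perms[c][1], r = perms[c][2],
                s = perms[c][3];
            J(p, q) += D(r, s) * val;
            K(p, r) += D(q, s) * val;
          }
        }
      }
    }
  NumericMatrix G(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      G(i, j) = J(i, j) - 0.5 * K(i, j);
  return G;
}
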