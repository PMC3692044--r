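// Simplified nearest-neighbor energy backend at 37 C.
//
// Two dynamic programs share the stack table:
//  * duplex_dp: intermolecular hybridization (no intramolecular pairs),
//    minimum free energy and inside-recursion partition function over
//    stacked helices separated by affine internal loops/bulges.
//  * ss_ensemble_energy: single-strand ensemble free energy -RT ln Z over
//    nested secondary structures (pair penalty + stack energies, minimum
//    hairpin loop 3), with an optional forced-unpaired constraint mask.
//
// All partition-function arithmetic is in log space so long windows and
// deep helices cannot overflow.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// bases: A=1 C=2 G=3 U=4, N=0 (never pairs)
// pair types: 1 A:U, 2 U:A, 3 C:G, 4 G:C, 5 G:U, 6 U:G (left = top strand)
static inline int pair_type(int a, int b) {
  if (a == 1 && b == 4) return 1;
  if (a == 4 && b == 1) return 2;
  if (a == 2 && b == 3) return 3;
  if (a == 3 && b == 2) return 4;
  if (a == 3 && b == 4) return 5;
  if (a == 4 && b == 3) return 6;
  return 0;
}

static inline bool weak_end(int pt) {
  return pt == 1 || pt == 2 || pt == 5 || pt == 6;  // A:U or G:U terminal
}

static inline double lse(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// [[Rcpp::export]]
List duplex_dp(IntegerVector x, IntegerVector y, NumericMatrix S,
               double init, double au_end, double loop_base,
               double loop_per_nt, int max_loop, double rt) {
  int m = x.size(), n = y.size();
  // H(i,j): MFE over duplexes whose last pair (3'-most on x) is (i,j),
  // including init and the terminal penalty of the first pair, excluding
  // the terminal penalty of (i,j) itself. W: log-space partition analog.
  NumericMatrix H(m, n), W(m, n);
  std::fill(H.begin(), H.end(), R_PosInf);
  std::fill(W.begin(), W.end(), R_NegInf);
  double best = R_PosInf, zlog = R_NegInf;
  for (int i = 0; i < m; ++i) {
    for (int j = n - 1; j >= 0; --j) {
      int pt = pair_type(x[i], y[j]);
      if (!pt) continue;
      double aup = weak_end(pt) ? au_end : 0.0;
      double h = init + aup;            // helix of a single pair
      double w = -(init + aup) / rt;
      int p0 = i - max_loop - 1; if (p0 < 0) p0 = 0;
      int q1 = j + max_loop + 1; if (q1 > n - 1) q1 = n - 1;
      for (int p = p0; p < i; ++p) {
        for (int q = q1; q > j; --q) {
          if (H(p, q) == R_PosInf) continue;
          int l1 = i - p - 1, l2 = q - j - 1;
          double le;
          if (l1 == 0 && l2 == 0) {
            le = S(pair_type(x[p], y[q]) - 1, pt - 1);
          } else {
            le = loop_base + loop_per_nt * (l1 + l2);
          }
          double cand = H(p, q) + le;
          if (cand < h) h = cand;
          w = lse(w, W(p, q) - le / rt);
        }
      }
      H(i, j) = h;
      W(i, j) = w;
      if (h + aup < best) best = h + aup;
      zlog = lse(zlog, w - aup / rt);
    }
  }
  double mfe = (best == R_PosInf) ? 0.0 : std::min(0.0, best);
  // ensemble includes the empty (unbound) structure with weight 1
  double dgb = (zlog == R_NegInf) ? 0.0 : -rt * lse(0.0, zlog);
  return List::create(_["dg_duplex"] = mfe, _["dg_binding"] = dgb,
                      _["mfe_raw"] = (best == R_PosInf) ? NA_REAL : best);
}

// [[Rcpp::export]]
double ss_ensemble_energy(IntegerVector x, LogicalVector unpaired_mask,
                          NumericMatrix S, double pair_penalty, double rt,
                          int min_hairpin) {
  int n = x.size();
  if (n < 2) return 0.0;
  // log-space: Zb (i paired to j), Zn (i..j, (i,j) not paired together),
  // Z = Zn + Zb. Empty segments have Z = 1 (log 0).
  std::vector<double> Zb((size_t)n * n, R_NegInf);
  std::vector<double> Zn((size_t)n * n, R_NegInf);
  std::vector<double> Z((size_t)n * n, R_NegInf);
  auto ix = [n](int i, int j) { return (size_t)i * n + j; };
  auto Zget = [&](int i, int j) -> double {
    return (i > j) ? 0.0 : Z[ix(i, j)];
  };
  auto Znget = [&](int i, int j) -> double {
    return (i > j) ? 0.0 : Zn[ix(i, j)];
  };
  for (int len = 0; len < n; ++len) {
    for (int i = 0; i + len < n; ++i) {
      int j = i + len;
      double zb = R_NegInf;
      int pt = pair_type(x[i], x[j]);
      if (pt && (j - i - 1) >= min_hairpin &&
          !unpaired_mask[i] && !unpaired_mask[j]) {
        double inner = Znget(i + 1, j - 1);
        double zbin = Zb[ix(i + 1, j - 1)];
        if (zbin != R_NegInf) {
          int ptin = pair_type(x[i + 1], x[j - 1]);
          inner = lse(inner, zbin - S(pt - 1, ptin - 1) / rt);
        }
        zb = -pair_penalty / rt + inner;
      }
      double zn = Zget(i, j - 1);  // j unpaired
      for (int k = i + 1; k <= j - min_hairpin - 1; ++k) {
        if (Zb[ix(k, j)] == R_NegInf) continue;
        zn = lse(zn, Zget(i, k - 1) + Zb[ix(k, j)]);
      }
      Zb[ix(i, j)] = zb;
      Zn[ix(i, j)] = zn;
      Z[ix(i, j)] = lse(zn, zb);
    }
  }
  return -rt * Z[ix(0, n - 1)];
}
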