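#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Minimum-free-energy secondary structure (pseudoknot-free, no dangles) with
// nearest-neighbor stacks, tabulated hairpin/bulge/internal loop penalties and
// an affine multiloop term E_ml = a + b * (branches incl. closing) + c * unpaired.
// Tie-breaks are deterministic: decision branches are evaluated in a fixed
// order and the first optimum found is kept.

namespace {

inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return 4;
  }
}

// pair type 0 = none; 1 AU, 2 UA, 3 CG, 4 GC, 5 GU, 6 UG (T == U)
inline int ptype(int a, int b) {
  if (a == 0 && b == 3) return 1;
  if (a == 3 && b == 0) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 1) return 4;
  if (a == 2 && b == 3) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

const double INF = 1e9;

struct FoldCtx {
  int n, min_loop, max_loop;
  std::vector<int> S;
  std::vector<int> PT;        // pair types, (i-1)*n + (j-1)
  NumericMatrix stack;        // 6x6, [outer-1, inner-1]
  NumericVector hp, bulge, internal_; // indexed by loop size (1-based)
  double ml_close, ml_branch, ml_unpaired;
  std::vector<double> V, WM, WM2;
  inline double& v(int i, int j)  { return V[(size_t)(i - 1) * n + (j - 1)]; }
  inline double& wm(int i, int j) { return WM[(size_t)(i - 1) * n + (j - 1)]; }
  inline double& wm2(int i, int j){ return WM2[(size_t)(i - 1) * n + (j - 1)]; }
  inline int pt(int i, int j) const { return PT[(size_t)(i - 1) * n + (j - 1)]; }
  inline double loop_tab(const NumericVector& t, int sz) const {
    return (sz >= 1 && sz <= t.size()) ? t[sz - 1] : INF;
  }
};

// energy of the internal element between closing pair (i,j) and inner (k,l)
inline double two_loop_energy(FoldCtx& C, int i, int j, int k, int l) {
  int a = k - i - 1, b = j - l - 1;
  if (a + b > C.max_loop) return INF;
  if (a == 0 && b == 0) return C.stack(C.pt(i, j) - 1, C.pt(k, l) - 1);
  if (a == 0 || b == 0) return C.loop_tab(C.bulge, a + b);
  return C.loop_tab(C.internal_, a + b);
}

void fill(FoldCtx& C) {
  int n = C.n;
  for (int d = 1; d < n; ++d) {
    for (int i = 1; i + d <= n; ++i) {
      int j = i + d;
      // V
      double best = INF;
      if (C.pt(i, j) && j - i - 1 >= C.min_loop) {
        best = C.loop_tab(C.hp, j - i - 1);                  // hairpin
        for (int k = i + 1; k < j; ++k) {                     // stack/bulge/internal
          if (k - i - 1 > C.max_loop) break;
          for (int l = j - 1; l > k; --l) {
            if ((k - i - 1) + (j - l - 1) > C.max_loop) break;
            if (!C.pt(k, l)) continue;
            double e = two_loop_energy(C, i, j, k, l) + C.v(k, l);
            if (e < best) best = e;
          }
        }
        if (j - i - 1 >= 2) {                                 // multiloop closing
          double e = C.ml_close + C.ml_branch + C.wm2(i + 1, j - 1);
          if (e < best) best = e;
        }
      }
      C.v(i, j) = best;

      // WM (>=1 branch in [i..j], multiloop interior context)
      double w = INF;
      if (C.v(i, j) < INF / 2) w = C.v(i, j) + C.ml_branch;
      if (j > i) {
        w = std::min(w, C.wm(i, j - 1) + C.ml_unpaired);
        w = std::min(w, C.wm(i + 1, j) + C.ml_unpaired);
      }
      // WM2 (>=2 branches) via bifurcation
      double w2 = INF;
      for (int k = i + 1; k <= j; ++k) {
        double lhs = C.wm(i, k - 1), rhs = C.wm(k, j);
        if (lhs < INF / 2 && rhs < INF / 2) w2 = std::min(w2, lhs + rhs);
      }
      w = std::min(w, w2);
      C.wm(i, j) = w;
      C.wm2(i, j) = w2;
    }
  }
}

void traceback_v(FoldCtx& C, int i, int j, std::string& db);

void traceback_wm(FoldCtx& C, int i, int j, std::string& db, bool need2) {
  const double eps = 1e-7;
  if (i > j) return;
  double w = need2 ? C.wm2(i, j) : C.wm(i, j);
  if (!need2) {
    if (C.v(i, j) < INF / 2 && std::abs(C.v(i, j) + C.ml_branch - w) < eps) {
      traceback_v(C, i, j, db); return;
    }
    if (j > i && std::abs(C.wm(i, j - 1) + C.ml_unpaired - w) < eps) {
      traceback_wm(C, i, j - 1, db, false); return;
    }
    if (j > i && std::abs(C.wm(i + 1, j) + C.ml_unpaired - w) < eps) {
      traceback_wm(C, i + 1, j, db, false); return;
    }
  }
  for (int k = i + 1; k <= j; ++k) {
    if (C.wm(i, k - 1) < INF / 2 && C.wm(k, j) < INF / 2 &&
        std::abs(C.wm(i, k - 1) + C.wm(k, j) - w) < eps) {
      traceback_wm(C, i, k - 1, db, false);
      traceback_wm(C, k, j, db, false);
      return;
    }
  }
  Rcpp::stop("fold traceback failed (WM)");
}

void traceback_v(FoldCtx& C, int i, int j, std::string& db) {
  const double eps = 1e-7;
  db[i - 1] = '('; db[j - 1] = ')';
  double e = C.v(i, j);
  if (std::abs(C.loop_tab(C.hp, j - i - 1) - e) < eps) return;
  for (int k = i + 1; k < j; ++k) {
    if (k - i - 1 > C.max_loop) break;
    for (int l = j - 1; l > k; --l) {
      if ((k - i - 1) + (j - l - 1) > C.max_loop) break;
      if (!C.pt(k, l) || C.v(k, l) > INF / 2) continue;
      if (std::abs(two_loop_energy(C, i, j, k, l) + C.v(k, l) - e) < eps) {
        traceback_v(C, k, l, db);
        return;
      }
    }
  }
  if (j - i - 1 >= 2 &&
      std::abs(C.ml_close + C.ml_branch + C.wm2(i + 1, j - 1) - e) < eps) {
    traceback_wm(C, i + 1, j - 1, db, true);
    return;
  }
  Rcpp::stop("fold traceback failed (V)");
}

} // namespace

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq, NumericMatrix stack,
                  NumericVector hairpin, NumericVector bulge,
                  NumericVector internal_loop,
                  double ml_close, double ml_branch, double ml_unpaired,
                  int min_loop, int max_loop) {
  int n = (int) seq.size();
  FoldCtx C;
  C.n = n; C.min_loop = min_loop; C.max_loop = max_loop;
  C.stack = stack; C.hp = hairpin; C.bulge = bulge; C.internal_ = internal_loop;
  C.ml_close = ml_close; C.ml_branch = ml_branch; C.ml_unpaired = ml_unpaired;
  C.S.resize(n);
  for (int i = 0; i < n; ++i) C.S[i] = enc(seq[i]);
  C.PT.assign((size_t) n * n, 0);
  for (int i = 1; i <= n; ++i)
    for (int j = i + 1; j <= n; ++j)
      C.PT[(size_t)(i - 1) * n + (j - 1)] = ptype(C.S[i - 1], C.S[j - 1]);
  C.V.assign((size_t) n * n, INF);
  C.WM.assign((size_t) n * n, INF);
  C.WM2.assign((size_t) n * n, INF);
  if (n > 1) fill(C);

  // exterior loop
  std::vector<double> W(n + 1, 0.0);
  std::vector<int> Wk(n + 1, 0); // pair start for traceback, 0 = unpaired
  for (int j = 1; j <= n; ++j) {
    W[j] = W[j - 1];
    Wk[j] = 0;
    for (int i = 1; i < j; ++i) {
      if (C.v(i, j) < INF / 2 && W[i - 1] + C.v(i, j) < W[j] - 1e-12) {
        W[j] = W[i - 1] + C.v(i, j);
        Wk[j] = i;
      }
    }
  }

  std::string db(n, '.');
  int j = n;
  while (j >= 1) {
    if (Wk[j] == 0) { --j; continue; }
    int i = Wk[j];
    traceback_v(C, i, j, db);
    j = i - 1;
  }

  int paired = 0;
  for (char c : db) if (c != '.') ++paired;

  return List::create(Named("structure") = db,
                      Named("mfe") = W[n],
                      Named("n_paired") = paired);
}
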