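#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Intermolecular duplex MFE: miRNA (A, 5'->3') hybridized to a target site
// (B, 5'->3') antiparallel; only inter-molecular pairs, no intramolecular
// structure.  Pairs are monotone non-crossing: if (i,j) and (i',j') are both
// pairs and i' > i then j' < j.  Consecutive pairs contribute a stack energy
// when directly adjacent and a bulge/internal-loop penalty otherwise.  The
// empty pairing has energy 0, so dG <= 0 always.

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

// pair type of (a, b) where b is the base a is paired with (complementary
// reading): AU, UA, CG, GC, GU, UG as 1..6, 0 otherwise
inline int ptype(int a, int b) {
  if (a == 0 && b == 3) return 1;
  if (a == 3 && b == 0) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 1) return 4;
  if (a == 2 && b == 3) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

inline bool is_gu(int t) { return t == 5 || t == 6; }

const double INF = 1e9;

} // namespace

// [[Rcpp::export(name = ".hybrid_dg_cpp")]]
List hybrid_dg_cpp(std::string mirna, std::string site,
                   NumericMatrix stack, NumericVector bulge,
                   NumericVector internal_loop, int max_loop,
                   bool forbid_seed_gu, int seed_lo, int seed_hi) {
  int m = (int) mirna.size(), s = (int) site.size();
  std::vector<int> A(m), B(s);
  for (int i = 0; i < m; ++i) A[i] = enc(mirna[i]);
  for (int j = 0; j < s; ++j) B[j] = enc(site[j]);

  auto pairable = [&](int i, int j) -> int { // 1-based
    int t = ptype(A[i - 1], B[j - 1]);
    if (!t) return 0;
    if (forbid_seed_gu && is_gu(t) && i >= seed_lo && i <= seed_hi) return 0;
    return t;
  };

  auto loop_tab = [&](const NumericVector& t, int sz) -> double {
    return (sz >= 1 && sz <= t.size()) ? t[sz - 1] : INF;
  };

  // D[i][j]: min energy of a duplex whose 3'-most miRNA pair is (i, j)
  std::vector<double> D((size_t) m * s, INF);
  std::vector<int> Pi((size_t) m * s, 0), Pj((size_t) m * s, 0); // predecessor
  auto at = [&](int i, int j) -> size_t { return (size_t)(i - 1) * s + (j - 1); };

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = s; j >= 1; --j) {
      if (!pairable(i, j)) continue;
      double e = 0.0; int pi = 0, pj = 0;      // duplex starting at this pair
      for (int i0 = std::max(1, i - max_loop - 1); i0 < i; ++i0) {
        for (int j0 = j + 1; j0 <= std::min(s, j + max_loop + 1); ++j0) {
          if (D[at(i0, j0)] > INF / 2) continue;
          int a = i - i0 - 1, b = j0 - j - 1;
          double link;
          if (a == 0 && b == 0)
            link = stack(pairable(i0, j0) - 1, pairable(i, j) - 1);
          else if (a == 0 || b == 0)
            link = loop_tab(bulge, a + b);
          else if (a + b <= max_loop)
            link = loop_tab(internal_loop, a + b);
          else
            continue;
          double cand = D[at(i0, j0)] + link;
          if (cand < e) { e = cand; pi = i0; pj = j0; }
        }
      }
      D[at(i, j)] = e;
      Pi[at(i, j)] = pi; Pj[at(i, j)] = pj;
      if (e < best) { best = e; bi = i; bj = j; }
    }
  }

  // traceback pair list
  std::vector<int> pair_i, pair_j;
  int i = bi, j = bj;
  while (i > 0) {
    pair_i.push_back(i); pair_j.push_back(j);
    int ni = Pi[at(i, j)], nj = Pj[at(i, j)];
    i = ni; j = nj;
  }
  std::reverse(pair_i.begin(), pair_i.end());
  std::reverse(pair_j.begin(), pair_j.end());

  // pairing string along the miRNA: '|' Watson-Crick, ':' G:U, '.' unpaired
  std::string pairing(m, '.');
  for (size_t k = 0; k < pair_i.size(); ++k) {
    int t = ptype(A[pair_i[k] - 1], B[pair_j[k] - 1]);
    pairing[pair_i[k] - 1] = is_gu(t) ? ':' : '|';
  }

  return List::create(Named("dG") = best,
                      Named("pairing") = pairing,
                      Named("pair_i") = IntegerVector(pair_i.begin(), pair_i.end()),
                      Named("pair_j") = IntegerVector(pair_j.begin(), pair_j.end()));
}
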