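#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Banded local DP for inverted repeats, einverted-style scoring:
//   score = match * n_match + mismatch * n_mismatch - gap * n_gap
// A stem pairs a left arm (positions ascending) with a right arm (positions
// descending); cell (i, j) holds the best score of a stem whose innermost
// columns consume left position i and right position j (i < j).  Restricting
// the band to j - i + 1 <= max_extent enforces the repeat-span cap exactly,
// because the outermost pair of any reported repeat is its widest column.

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

inline bool wc_pair(int a, int b) { return (a < 4 && b < 4 && a + b == 3); }

struct Cand { int score, i, d; };

} // namespace

// [[Rcpp::export(name = ".find_inverted_repeats_cpp")]]
DataFrame find_inverted_repeats_cpp(std::string seq,
                                    int match, int mismatch, int gap,
                                    int min_score, int max_extent,
                                    double max_arm_overlap) {
  const int n = (int) seq.size();
  const int D = std::min(max_extent - 1, n - 1); // offsets d = j - i, 1..D
  std::vector<int> S(n);
  for (int i = 0; i < n; ++i) S[i] = enc(seq[i]);

  const int NEG = INT32_MIN / 4;
  // M[(i-1)*D + (d-1)] for i in 1..n, d in 1..D, j = i + d <= n
  std::vector<int> M((size_t) n * D, NEG);
  std::vector<int8_t> P((size_t) n * D, 0); // 0 fresh pair-col, 1 diag, 2 left-gap, 3 right-gap
  std::vector<Cand> cands;

  for (int i = 1; i <= n; ++i) {
    for (int d = D; d >= 1; --d) {
      int j = i + d;
      if (j > n) continue;
      size_t idx = (size_t) (i - 1) * D + (d - 1);
      int s = wc_pair(S[i - 1], S[j - 1]) ? match : mismatch;

      int best = s;          // fresh start with this column
      int8_t ptr = 0;
      if (i >= 2 && d + 2 <= D) {
        int prev = M[(size_t) (i - 2) * D + (d + 1)]; // (i-1, j+1)
        if (prev > 0 && prev + s > best) { best = prev + s; ptr = 1; }
      }
      if (d + 1 <= D) {
        int left = M[idx + 1];                        // (i, j+1): gap in left arm
        if (left > NEG / 2 && left - gap > best) { best = left - gap; ptr = 2; }
      }
      if (i >= 2 && d + 1 <= D) {
        int up = M[(size_t) (i - 2) * D + d];          // (i-1, j): gap in right arm
        if (up > NEG / 2 && up - gap > best) { best = up - gap; ptr = 3; }
      }
      M[idx] = best;
      P[idx] = ptr;
      if (best >= min_score) cands.push_back({best, i, d});
    }
  }

  std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.i != b.i) return a.i < b.i;
    return a.d < b.d;
  });

  std::vector<int> ls, le, rs, re, sc, nm, nx, ng, lp;
  std::vector<std::string> al, ar;

  for (const Cand& c : cands) {
    // traceback from innermost column (i, j) outwards
    int i = c.i, d = c.d;
    std::string aln_l, aln_r; // collected inner->outer, reversed later
    int n_match = 0, n_mis = 0, n_gap = 0;
    int li2 = c.i, rj1 = c.i + c.d; // innermost consumed positions
    int li1 = li2, rj2 = rj1;
    for (;;) {
      size_t idx = (size_t) (i - 1) * D + (d - 1);
      int j = i + d;
      int8_t ptr = P[idx];
      if (ptr <= 1) { // pair/mismatch column
        aln_l.push_back(seq[i - 1]);
        aln_r.push_back(seq[j - 1]);
        if (wc_pair(S[i - 1], S[j - 1])) ++n_match; else ++n_mis;
        li1 = i; rj2 = j;
        if (ptr == 0) break;
        i -= 1; d += 2;
      } else if (ptr == 2) { // gap in left arm, consumed right j
        aln_l.push_back('-');
        aln_r.push_back(seq[j - 1]);
        ++n_gap; rj2 = j;
        d += 1;
      } else {               // gap in right arm, consumed left i
        aln_l.push_back(seq[i - 1]);
        aln_r.push_back('-');
        ++n_gap; li1 = i;
        i -= 1; d += 1;
      }
    }
    std::reverse(aln_l.begin(), aln_l.end());
    std::reverse(aln_r.begin(), aln_r.end());

    int cls = li1, cle = li2, crs = rj1, cre = rj2;
    // redundancy suppression: drop if either arm overlaps an accepted
    // repeat's corresponding arm by more than max_arm_overlap of its length
    bool keep = true;
    for (size_t k = 0; k < ls.size(); ++k) {
      int ovl = std::min(cle, le[k]) - std::max(cls, ls[k]) + 1;
      int ovr = std::min(cre, re[k]) - std::max(crs, rs[k]) + 1;
      double lenl = cle - cls + 1, lenr = cre - crs + 1;
      if ((ovl > 0 && ovl > max_arm_overlap * lenl) ||
          (ovr > 0 && ovr > max_arm_overlap * lenr)) { keep = false; break; }
    }
    if (!keep) continue;

    ls.push_back(cls); le.push_back(cle);
    rs.push_back(crs); re.push_back(cre);
    sc.push_back(c.score);
    nm.push_back(n_match); nx.push_back(n_mis); ng.push_back(n_gap);
    lp.push_back(crs - cle - 1);
    al.push_back(aln_l); ar.push_back(aln_r);
  }

  // sort final reports by left arm start, then right arm start
  std::vector<int> ord(ls.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = (int) k;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (ls[a] != ls[b]) return ls[a] < ls[b];
    return rs[a] < rs[b];
  });

  auto take_i = [&](const std::vector<int>& v) {
    IntegerVector out(ord.size());
    for (size_t k = 0; k < ord.size(); ++k) out[k] = v[ord[k]];
    return out;
  };
  CharacterVector aL(ord.size()), aR(ord.size());
  for (size_t k = 0; k < ord.size(); ++k) { aL[k] = al[ord[k]]; aR[k] = ar[ord[k]]; }

  return DataFrame::create(
    Named("left_start") = take_i(ls), Named("left_end") = take_i(le),
    Named("right_start") = take_i(rs), Named("right_end") = take_i(re),
    Named("score") = take_i(sc),
    Named("n_match") = take_i(nm), Named("n_mismatch") = take_i(nx),
    Named("n_gap") = take_i(ng), Named("loop_len") = take_i(lp),
    Named("aln_left") = aL, Named("aln_right") = aR,
    Named("stringsAsFactors") = false);
}
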