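#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// 5'-weighted complementarity scan, miRanda-style.  The miRNA (5'->3') is
// aligned antiparallel against one strand of the target (5'->3'): the miRNA's
// 3' end pairs the 5' start of the binding site, so the DP walks the miRNA
// reversed.  Per-column score is the base-pair score (Watson-Crick, G:U
// wobble, mismatch) multiplied by w when the miRNA position lies in the seed
// range.  Gaps are charged open + extend * length and are never weighted.
// All local optima with S >= min_S are reported after greedy suppression of
// alignments whose target interval overlaps an accepted one by > 50%.

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

inline int pclass(int a, int b) { // 2 = WC, 1 = GU wobble, 0 = mismatch
  if (a < 4 && b < 4 && a + b == 3) return 2;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1;
  return 0;
}

struct Hit { double score; int q, t; }; // DP cell (1-based)

const double NEG = -1e12;

} // namespace

// [[Rcpp::export(name = ".complementarity_scan_cpp")]]
DataFrame complementarity_scan_cpp(std::string mirna, std::string target,
                                   double match_score, double wobble_score,
                                   double mismatch_score,
                                   double gap_open, double gap_extend,
                                   double w, int seed_lo, int seed_hi,
                                   double min_S, bool allow_gaps) {
  int m = (int) mirna.size(), n = (int) target.size();
  std::vector<int> Q(m), T(n);
  for (int i = 0; i < m; ++i) Q[i] = enc(mirna[i]);
  for (int j = 0; j < n; ++j) T[j] = enc(target[j]);

  // column score for reversed-miRNA row q (1-based) against target base t
  auto col = [&](int q, int t) -> double {
    int p = m + 1 - q; // original miRNA position
    int pc = pclass(Q[p - 1], T[t - 1]);
    double s = pc == 2 ? match_score : (pc == 1 ? wobble_score : mismatch_score);
    if (p >= seed_lo && p <= seed_hi) s *= w;
    return s;
  };

  // Gotoh local alignment; full matrices kept for traceback
  std::vector<double> H((size_t)(m + 1) * (n + 1), 0.0);
  std::vector<double> E((size_t)(m + 1) * (n + 1), NEG); // gap in miRNA (consumes target)
  std::vector<double> F((size_t)(m + 1) * (n + 1), NEG); // gap in target (consumes miRNA)
  auto at = [&](int q, int t) -> size_t { return (size_t) q * (n + 1) + t; };

  std::vector<Hit> cands;
  for (int q = 1; q <= m; ++q) {
    for (int t = 1; t <= n; ++t) {
      if (allow_gaps) {
        E[at(q, t)] = std::max(H[at(q, t - 1)] - (gap_open + gap_extend),
                               E[at(q, t - 1)] - gap_extend);
        F[at(q, t)] = std::max(H[at(q - 1, t)] - (gap_open + gap_extend),
                               F[at(q - 1, t)] - gap_extend);
      }
      double h = H[at(q - 1, t - 1)] + col(q, t);
      h = std::max(h, std::max(E[at(q, t)], F[at(q, t)]));
      if (h < 0) h = 0;
      H[at(q, t)] = h;
      if (h >= min_S) cands.push_back({h, q, t});
    }
  }

  std::sort(cands.begin(), cands.end(), [](const Hit& a, const Hit& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.t != b.t) return a.t < b.t;
    return a.q < b.q;
  });

  std::vector<int> ts, te, ms, me;
  std::vector<double> sc;
  std::vector<std::string> aq, ap, at_;

  const double eps = 1e-9;
  for (const Hit& hit : cands) {
    // traceback
    int q = hit.q, t = hit.t;
    std::string s_q, s_p, s_t; // built 3'->5' of reversed row, reversed at end
    char state = 'H';
    int q_end = q, t_end = t, q_start = q, t_start = t;
    bool ok = true;
    while (q >= 1 && t >= 1) {
      if (state == 'H') {
        double h = H[at(q, t)];
        if (h < eps) break; // local alignment start reached
        if (std::abs(H[at(q - 1, t - 1)] + col(q, t) - h) < eps) {
          int p = m + 1 - q;
          int pc = pclass(Q[p - 1], T[t - 1]);
          s_q.push_back(mirna[p - 1]);
          s_p.push_back(pc == 2 ? '|' : (pc == 1 ? ':' : ' '));
          s_t.push_back(target[t - 1]);
          q_start = q; t_start = t;
          --q; --t;
          continue;
        }
        if (allow_gaps && std::abs(E[at(q, t)] - h) < eps) { state = 'E'; continue; }
        if (allow_gaps && std::abs(F[at(q, t)] - h) < eps) { state = 'F'; continue; }
        ok = false; break;
      } else if (state == 'E') {
        s_q.push_back('-');
        s_p.push_back(' ');
        s_t.push_back(target[t - 1]);
        t_start = t;
        double e = E[at(q, t)];
        if (std::abs(H[at(q, t - 1)] - (gap_open + gap_extend) - e) < eps) {
          --t; state = 'H';
        } else { --t; state = 'E'; }
      } else { // F
        int p = m + 1 - q;
        s_q.push_back(mirna[p - 1]);
        s_p.push_back(' ');
        s_t.push_back('-');
        q_start = q;
        double f = F[at(q, t)];
        if (std::abs(H[at(q - 1, t)] - (gap_open + gap_extend) - f) < eps) {
          --q; state = 'H';
        } else { --q; state = 'F'; }
      }
    }
    if (!ok) continue;

    int tstart = t_start, tend = t_end;
    // greedy suppression on target interval overlap > 50%
    bool keep = true;
    for (size_t k = 0; k < ts.size(); ++k) {
      int ov = std::min(tend, te[k]) - std::max(tstart, ts[k]) + 1;
      if (ov > 0 && ov > 0.5 * (tend - tstart + 1)) { keep = false; break; }
    }
    if (!keep) continue;

    std::reverse(s_q.begin(), s_q.end());
    std::reverse(s_p.begin(), s_p.end());
    std::reverse(s_t.begin(), s_t.end());
    ts.push_back(tstart); te.push_back(tend);
    // miRNA positions covered (original coordinates): row q covers p = m+1-q
    ms.push_back(m + 1 - q_end); me.push_back(m + 1 - q_start);
    sc.push_back(hit.score);
    aq.push_back(s_q); ap.push_back(s_p); at_.push_back(s_t);
  }

  // order by target start
  std::vector<int> ord(ts.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = (int) k;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (ts[a] != ts[b]) return ts[a] < ts[b];
    return te[a] < te[b];
  });
  IntegerVector o_ts(ord.size()), o_te(ord.size()), o_ms(ord.size()), o_me(ord.size());
  NumericVector o_sc(ord.size());
  CharacterVector o_aq(ord.size()), o_ap(ord.size()), o_at(ord.size());
  for (size_t k = 0; k < ord.size(); ++k) {
    int v = ord[k];
    o_ts[k] = ts[v]; o_te[k] = te[v]; o_ms[k] = ms[v]; o_me[k] = me[v];
    o_sc[k] = sc[v]; o_aq[k] = aq[v]; o_ap[k] = ap[v]; o_at[k] = at_[v];
  }
  return DataFrame::create(
    Named("start") = o_ts, Named("end") = o_te,
    Named("mirna_from") = o_ms, Named("mirna_to") = o_me,
    Named("S") = o_sc,
    Named("aln_mirna") = o_aq, Named("aln_pairs") = o_ap,
    Named("aln_target") = o_at,
    Named("stringsAsFactors") = false);
}
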