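#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Alignment kernels. Sequences arrive as integer code vectors (0-based codes
// into the rows/cols of the scoring matrix); encoding happens in R.

static const double NEG = -1e30;

// Global Needleman-Wunsch with linear gap penalty; returns identity =
// matches / alignment columns along one optimal path (deterministic
// tie-break: diagonal > up > left).
// [[Rcpp::export]]
List nw_identity_cpp(IntegerVector a, IntegerVector b, double match,
                     double mismatch, double gap) {
  const int m = a.size(), n = b.size();
  std::vector<double> prev(n + 1), cur(n + 1);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1)); // 0 diag, 1 up, 2 left
  for (int j = 0; j <= n; ++j) { prev[j] = j * gap; tb[j] = 2; }
  tb[0] = 0;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i * gap;
    tb[(size_t)i * (n + 1)] = 1;
    for (int j = 1; j <= n; ++j) {
      double sd = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double su = prev[j] + gap;
      double sl = cur[j - 1] + gap;
      double best = sd; uint8_t dir = 0;
      if (su > best) { best = su; dir = 1; }
      if (sl > best) { best = sl; dir = 2; }
      cur[j] = best;
      tb[(size_t)i * (n + 1) + j] = dir;
    }
    std::swap(prev, cur);
  }
  // traceback
  int i = m, j = n;
  long matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    uint8_t dir = tb[(size_t)i * (n + 1) + j];
    if (i > 0 && j > 0 && dir == 0) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (i > 0 && dir == 1) {
      --i;
    } else {
      --j;
    }
    ++cols;
  }
  return List::create(_["score"] = prev[n], _["matches"] = matches,
                      _["columns"] = cols,
                      _["identity"] = cols > 0 ? (double) matches / cols : 1.0);
}

// Local Smith-Waterman with affine gaps: a gap of length g costs
// gap_open + g * gap_ext. Returns best score, 0-based half-open spans on both
// sequences, match count and alignment length of the optimal local alignment.
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix smat,
                  double gap_open, double gap_ext) {
  const int m = a.size(), n = b.size();
  if ((double) m * (double) n > 6.4e7)
    stop("sw_align_cpp: DP matrix too large (%d x %d)", m, n);
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Eprev(n + 1, NEG), Ecur(n + 1, NEG); // gap in a (move along b)
  std::vector<double> Fcur(n + 1, NEG);                     // gap in b (move along a)
  // traceback: tbH 0=stop,1=diag,2=fromE,3=fromF ; tbE 0=open,1=extend ; tbF same
  std::vector<uint8_t> tbH((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> tbE((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> tbF((size_t)(m + 1) * (n + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0; Ecur[0] = NEG; Fcur[0] = NEG;
    for (int j = 1; j <= n; ++j) {
      size_t idx = (size_t)i * (n + 1) + j;
      double eo = Hcur[j - 1] - gap_open - gap_ext;
      double ee = Ecur[j - 1] - gap_ext;
      if (eo >= ee) { Ecur[j] = eo; tbE[idx] = 0; } else { Ecur[j] = ee; tbE[idx] = 1; }
      double fo = Hprev[j] - gap_open - gap_ext;
      double fe = Fcur[j] - gap_ext; // Fcur currently holds row i-1 value at j? no:
      // Fcur[j] is from previous i iteration; we overwrite below, so read before write.
      if (fo >= fe) { Fcur[j] = fo; tbF[idx] = 0; } else { Fcur[j] = fe; tbF[idx] = 1; }
      double diag = Hprev[j - 1] + smat(a[i - 1], b[j - 1]);
      double h = 0.0; uint8_t dir = 0;
      if (diag > h) { h = diag; dir = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; dir = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; dir = 3; }
      Hcur[j] = h; tbH[idx] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  // traceback from (bi, bj)
  int i = bi, j = bj;
  long matches = 0, cols = 0;
  int state = 0; // 0 in H, 1 in E, 2 in F
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      uint8_t dir = tbH[idx];
      if (dir == 0) break;
      if (dir == 1) {
        if (a[i - 1] == b[j - 1]) ++matches;
        ++cols; --i; --j;
      } else if (dir == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      uint8_t dir = tbE[idx];
      ++cols; --j;
      state = (dir == 0) ? 0 : 1;
    } else {
      uint8_t dir = tbF[idx];
      ++cols; --i;
      state = (dir == 0) ? 0 : 2;
    }
  }
  return List::create(_["score"] = best,
                      _["a_start"] = i, _["a_end"] = bi,
                      _["b_start"] = j, _["b_end"] = bj,
                      _["matches"] = matches, _["aln_len"] = cols);
}

// Ungapped X-drop extension from a seed match a[qpos..qpos+k) == b[tpos..tpos+k).
// Positions 0-based; returns the best-scoring ungapped extension spans.
// [[Rcpp::export]]
List xdrop_ungapped_cpp(IntegerVector a, IntegerVector b, int qpos, int tpos,
                        int k, NumericMatrix smat, double xdrop) {
  const int m = a.size(), n = b.size();
  double score = 0.0;
  for (int t = 0; t < k; ++t) score += smat(a[qpos + t], b[tpos + t]);
  // extend right
  double cur = score, bestR = score;
  int q1 = qpos + k, t1 = tpos + k, bq1 = q1, bt1 = t1;
  while (q1 < m && t1 < n) {
    cur += smat(a[q1], b[t1]);
    ++q1; ++t1;
    if (cur > bestR) { bestR = cur; bq1 = q1; bt1 = t1; }
    if (cur < bestR - xdrop) break;
  }
  // extend left
  cur = bestR;
  double bestL = bestR;
  int q0 = qpos, t0 = tpos, bq0 = q0, bt0 = t0;
  while (q0 > 0 && t0 > 0) {
    cur += smat(a[q0 - 1], b[t0 - 1]);
    --q0; --t0;
    if (cur > bestL) { bestL = cur; bq0 = q0; bt0 = t0; }
    if (cur < bestL - xdrop) break;
  }
  return List::create(_["score"] = bestL,
                      _["q_start"] = bq0, _["q_end"] = bq1,
                      _["t_start"] = bt0, _["t_end"] = bt1);
}

static inline bool window_ok(const IntegerVector& v, int i, int k, int asz) {
  for (int t = 0; t < k; ++t) if (v[i + t] < 0 || v[i + t] >= asz) return false;
  return true;
}

// Exact k-mer seed matching between query a and target b over an integer
// alphabet of size asz (codes outside [0, asz) act as wildcards that break
// words). Returns a two-column matrix of 0-based (qpos, tpos).
// [[Rcpp::export]]
IntegerMatrix kmer_match_cpp(IntegerVector a, IntegerVector b, int k, int asz) {
  const int m = a.size(), n = b.size();
  std::unordered_map<uint64_t, std::vector<int> > index;
  if (n >= k) {
    uint64_t key = 0, basepow = 1;
    for (int t = 0; t < k - 1; ++t) basepow *= (uint64_t) asz;
    int run = 0; // length of current valid run
    for (int i = 0; i < n; ++i) {
      int c = b[i];
      if (c < 0 || c >= asz) { run = 0; key = 0; continue; }
      key = (run >= k ? (key - (uint64_t) b[i - k] * basepow) : key) * asz + c;
      if (run < k) ++run;
      if (run >= k) index[key].push_back(i - k + 1);
    }
  }
  std::vector<int> qp, tp;
  if (m >= k) {
    uint64_t key = 0, basepow = 1;
    for (int t = 0; t < k - 1; ++t) basepow *= (uint64_t) asz;
    int run = 0;
    for (int i = 0; i < m; ++i) {
      int c = a[i];
      if (c < 0 || c >= asz) { run = 0; key = 0; continue; }
      key = (run >= k ? (key - (uint64_t) a[i - k] * basepow) : key) * asz + c;
      if (run < k) ++run;
      if (run >= k) {
        auto it = index.find(key);
        if (it != index.end()) {
          for (int t : it->second) { qp.push_back(i - k + 1); tp.push_back(t); }
        }
      }
    }
  }
  IntegerMatrix out(qp.size(), 2);
  for (size_t i = 0; i < qp.size(); ++i) { out(i, 0) = qp[i]; out(i, 1) = tp[i]; }
  return out;
}

// Fast approximate occurrence counting by k-mer colinearity: a genomic
// occurrence of a candidate (either strand, ~90%+ identity, few indels) shows
// up as a cluster of shared k-mers on a near-constant (anti)diagonal. Counts
// clusters holding >= max(3, min_frac * n_kmers) shared k-mers within
// +-diag_tol. The candidate's own genomic copy counts as one occurrence.
// [[Rcpp::export]]
IntegerVector colinear_occurrence_counts_cpp(std::string genome,
                                             std::vector<std::string> cands,
                                             int k, double min_frac,
                                             double min_cov, double min_union,
                                             int diag_tol, int max_count,
                                             int max_kmer_hits) {
  const long n = (long) genome.size();
  auto code_of = [](char c) -> int {
    switch (c) {
      case 'A': case 'a': return 0; case 'C': case 'c': return 1;
      case 'G': case 'g': return 2; case 'T': case 't': return 3;
      default: return -1;
    }
  };
  std::unordered_map<uint64_t, std::vector<int> > index;
  index.reserve(n);
  {
    uint64_t key = 0;
    const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int run = 0;
    for (long i = 0; i < n; ++i) {
      int c = code_of(genome[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) c) & mask;
      if (run < k) ++run;
      if (run >= k) {
        auto& v = index[key];
        if ((int) v.size() <= max_kmer_hits) v.push_back((int)(i - k + 1));
      }
    }
  }
  // a cluster only counts as an occurrence when its shared k-mers both are
  // numerous enough and span most of the candidate (coverage >= 80%), so a
  // partial overlap with a repeated region does not count
  // union length of the [cpos, cpos+k) intervals inside hits[i..j)
  auto union_len = [&](std::vector<std::pair<long,long> >& hits, size_t i,
                       size_t j) -> long {
    std::vector<long> cp;
    cp.reserve(j - i);
    for (size_t t = i; t < j; ++t) cp.push_back(hits[t].second);
    std::sort(cp.begin(), cp.end());
    long tot = 0, cur_s = cp[0], cur_e = cp[0] + k;
    for (size_t t = 1; t < cp.size(); ++t) {
      if (cp[t] <= cur_e) cur_e = std::max(cur_e, cp[t] + k);
      else { tot += cur_e - cur_s; cur_s = cp[t]; cur_e = cp[t] + k; }
    }
    tot += cur_e - cur_s;
    return tot;
  };
  auto count_clusters = [&](std::vector<std::pair<long,long> >& hits,
                            long need, long m) -> int {
    if ((long) hits.size() < need) return 0;
    std::sort(hits.begin(), hits.end());
    int clusters = 0;
    size_t i = 0;
    while (i < hits.size()) {
      size_t j = i + 1;
      long cmin = hits[i].second, cmax = hits[i].second;
      while (j < hits.size() && hits[j].first - hits[j - 1].first <= diag_tol) {
        cmin = std::min(cmin, hits[j].second);
        cmax = std::max(cmax, hits[j].second);
        ++j;
      }
      // extent must span the candidate AND the matched k-mers must tile most
      // of it (guards against two-armed matches with an unmatched interior)
      if ((long)(j - i) >= need &&
          (cmax - cmin + k) >= (long) std::ceil(min_cov * m) &&
          union_len(hits, i, j) >= (long) std::ceil(min_union * m)) ++clusters;
      i = j;
    }
    return clusters;
  };
  IntegerVector out(cands.size());
  for (size_t ci = 0; ci < cands.size(); ++ci) {
    const std::string& s = cands[ci];
    const long m = (long) s.size();
    std::vector<std::pair<long,long> > fdiag, rdiag;
    uint64_t fkey = 0, rkey = 0;
    const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    const uint64_t shift = 2 * (k - 1);
    int run = 0;
    long nk = 0;
    for (long i = 0; i < m; ++i) {
      int c = code_of(s[i]);
      if (c < 0) { run = 0; fkey = 0; rkey = 0; continue; }
      fkey = ((fkey << 2) | (uint64_t) c) & mask;
      rkey = (rkey >> 2) | ((uint64_t)(3 - c) << shift);
      if (run < k) ++run;
      if (run < k) continue;
      ++nk;
      long cpos = i - k + 1;
      auto it = index.find(fkey);
      if (it != index.end() && (int) it->second.size() <= max_kmer_hits) {
        for (int g : it->second) fdiag.push_back({(long) g - cpos, cpos});
      }
      it = index.find(rkey);
      if (it != index.end() && (int) it->second.size() <= max_kmer_hits) {
        for (int g : it->second) rdiag.push_back({(long) g + cpos, cpos});
      }
    }
    long need = std::max((long) 3, (long) std::ceil(min_frac * nk));
    int cnt = count_clusters(fdiag, need, m) + count_clusters(rdiag, need, m);
    out[ci] = std::min(cnt, max_count);
  }
  return out;
}

// Locate the colinear occurrences counted by colinear_occurrence_counts_cpp:
// for every qualifying cluster, report the approximate genomic interval
// (derived from the median diagonal) and strand.
// [[Rcpp::export]]
DataFrame colinear_occurrence_locate_cpp(std::string genome,
                                         std::vector<std::string> cands,
                                         int k, double min_frac,
                                         double min_cov, double min_union,
                                         int diag_tol, int max_kmer_hits) {
  const long n = (long) genome.size();
  auto code_of = [](char c) -> int {
    switch (c) {
      case 'A': case 'a': return 0; case 'C': case 'c': return 1;
      case 'G': case 'g': return 2; case 'T': case 't': return 3;
      default: return -1;
    }
  };
  std::unordered_map<uint64_t, std::vector<int> > index;
  index.reserve(n);
  {
    uint64_t key = 0;
    const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int run = 0;
    for (long i = 0; i < n; ++i) {
      int c = code_of(genome[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) c) & mask;
      if (run < k) ++run;
      if (run >= k) {
        auto& v = index[key];
        if ((int) v.size() <= max_kmer_hits) v.push_back((int)(i - k + 1));
      }
    }
  }
  std::vector<int> o_cand, o_start, o_end, o_n;
  std::vector<std::string> o_strand;
  auto emit_clusters = [&](std::vector<std::pair<long,long> >& hits, long need,
                           long m, int ci, bool fwd) {
    if ((long) hits.size() < need) return;
    std::sort(hits.begin(), hits.end());
    size_t i = 0;
    while (i < hits.size()) {
      size_t j = i + 1;
      long cmin = hits[i].second, cmax = hits[i].second;
      while (j < hits.size() && hits[j].first - hits[j - 1].first <= diag_tol) {
        cmin = std::min(cmin, hits[j].second);
        cmax = std::max(cmax, hits[j].second);
        ++j;
      }
      long ul = 0;
      {
        std::vector<long> cp;
        for (size_t t = i; t < j; ++t) cp.push_back(hits[t].second);
        std::sort(cp.begin(), cp.end());
        long cur_s = cp[0], cur_e = cp[0] + k;
        for (size_t t = 1; t < cp.size(); ++t) {
          if (cp[t] <= cur_e) cur_e = std::max(cur_e, cp[t] + k);
          else { ul += cur_e - cur_s; cur_s = cp[t]; cur_e = cp[t] + k; }
        }
        ul += cur_e - cur_s;
      }
      if ((long)(j - i) >= need &&
          (cmax - cmin + k) >= (long) std::ceil(min_cov * m) &&
          ul >= (long) std::ceil(min_union * m)) {
        long diag = hits[i + (j - i) / 2].first;   // median-ish diagonal
        long s = fwd ? diag : diag - m + k;
        o_cand.push_back(ci + 1);
        o_start.push_back((int) std::max(0L, s));
        o_end.push_back((int) std::min(n, s + m));
        o_strand.push_back(fwd ? "+" : "-");
        o_n.push_back((int)(j - i));
      }
      i = j;
    }
  };
  for (size_t ci = 0; ci < cands.size(); ++ci) {
    const std::string& s = cands[ci];
    const long m = (long) s.size();
    std::vector<std::pair<long,long> > fdiag, rdiag;
    uint64_t fkey = 0, rkey = 0;
    const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    const uint64_t shift = 2 * (k - 1);
    int run = 0;
    long nk = 0;
    for (long i = 0; i < m; ++i) {
      int c = code_of(s[i]);
      if (c < 0) { run = 0; fkey = 0; rkey = 0; continue; }
      fkey = ((fkey << 2) | (uint64_t) c) & mask;
      rkey = (rkey >> 2) | ((uint64_t)(3 - c) << shift);
      if (run < k) ++run;
      if (run < k) continue;
      ++nk;
      long cpos = i - k + 1;
      auto it = index.find(fkey);
      if (it != index.end() && (int) it->second.size() <= max_kmer_hits) {
        for (int g : it->second) fdiag.push_back({(long) g - cpos, cpos});
      }
      it = index.find(rkey);
      if (it != index.end() && (int) it->second.size() <= max_kmer_hits) {
        for (int g : it->second) rdiag.push_back({(long) g + cpos, cpos});
      }
    }
    long need = std::max((long) 3, (long) std::ceil(min_frac * nk));
    emit_clusters(fdiag, need, m, (int) ci, true);
    emit_clusters(rdiag, need, m, (int) ci, false);
  }
  return DataFrame::create(_["cand"] = wrap(o_cand), _["start"] = wrap(o_start),
                           _["end"] = wrap(o_end), _["strand"] = wrap(o_strand),
                           _["n_kmers"] = wrap(o_n),
                           _["stringsAsFactors"] = false);
}

// All genome positions where `word` matches ungapped with <= max_mismatch
// substitutions (N never matches). 0-based starts.
// [[Rcpp::export]]
IntegerVector word_occurrences_cpp(IntegerVector genome, IntegerVector word,
                                   int max_mismatch) {
  const int n = genome.size(), k = word.size();
  std::vector<int> pos;
  for (int i = 0; i + k <= n; ++i) {
    int mm = 0;
    for (int t = 0; t < k; ++t) {
      int g = genome[i + t];
      if (g < 0 || g > 3 || g != word[t]) {
        if (++mm > max_mismatch) break;
      }
    }
    if (mm <= max_mismatch) pos.push_back(i);
  }
  return wrap(pos);
}
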