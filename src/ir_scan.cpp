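#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Mismatch-tolerant inverted-repeat pair scanner.
//
// An IR pair is parameterised on the anti-diagonal d = left.start + right.end - 1:
// left-arm position p pairs with genome position q = d - p. Inward extension of a
// pair (arms grow toward each other) and outward extension (arms grow away) both
// preserve d, so each diagonal is an independent 1-D problem: find all maximal
// windows [l, e) on the p axis with <= max_mismatch non-complementary pairs, no N,
// arm length in [min_arm, max_arm] and spacer gap = d + 1 - 2e in [0, max_gap].
// Maximal means neither the inward- nor the outward-extended window is valid.

static inline int nt_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

// [[Rcpp::export]]
DataFrame ir_scan_cpp(std::string seq, int min_arm, int max_arm, int max_gap,
                      int max_mismatch) {
  const long n = (long) seq.size();
  std::vector<int> code(n);
  for (long i = 0; i < n; ++i) code[i] = nt_code(seq[i]);

  std::vector<int> ls, le, rs, re, al, mm;

  const int m = max_mismatch;
  // scratch prefix arrays sized to the widest p window we ever use
  const long wmax = (long) max_gap / 2 + max_arm + 4;
  std::vector<int> pmis(wmax + 2);   // prefix mismatches over window positions
  std::vector<long> lastinv(wmax + 2); // last invalid position index (absolute), -1 if none
  std::vector<int> state(wmax + 2);  // pair state per window position

  for (long d = 1; d <= 2 * n - 3; ++d) {
    // left.end bounds from the gap constraint
    long e_hi = (d + 1) / 2;                       // gap >= 0
    long e_lo = (d + 1 - max_gap + 1) / 2;         // ceil((d+1-max_gap)/2), gap <= max_gap
    if (e_lo < 1) e_lo = 1;
    if (e_hi > n) e_hi = n;
    if (e_hi < e_lo) continue;

    long bound_lo = d + 1 - n;                     // right.end <= n
    if (bound_lo < 0) bound_lo = 0;
    long p_lo = e_lo - max_arm;                    // leftmost arm start we may need
    if (p_lo < bound_lo) p_lo = bound_lo;
    if (p_lo >= e_hi) continue;

    // pair state for positions p in [p_lo, e_hi): 0 match, 1 mismatch, 2 invalid
    const long w = e_hi - p_lo;
    pmis[0] = 0;
    long li = -1;
    for (long t = 0; t < w; ++t) {
      long p = p_lo + t, q = d - p;
      int st;
      if (q <= p || q >= n) st = 2;
      else {
        int a = code[p], b = code[q];
        if (a == 4 || b == 4) st = 2;
        else st = (a + b == 3) ? 0 : 1;            // Watson-Crick complement: codes sum to 3
      }
      state[t] = st;
      pmis[t + 1] = pmis[t] + (st == 1 ? 1 : 0);
      if (st == 2) li = p;
      lastinv[t + 1] = li;
      // lastinv[t+1] = last invalid absolute position among p_lo..p
    }
    lastinv[0] = -1;

    // two monotone pointers over window starts (absolute coordinates)
    long lo_m = p_lo;   // min l with <= m mismatches, no invalid, l >= bound_lo
    long lo_m1 = p_lo;  // same with <= m-1 (only meaningful when m >= 1)

    for (long e = std::max(e_lo, p_lo + 1); e <= e_hi; ++e) {
      long te = e - p_lo;                          // prefix index for end e
      long inv_floor = lastinv[te] + 1;            // starts must be past last invalid
      if (lo_m < inv_floor) lo_m = inv_floor;
      if (lo_m < bound_lo) lo_m = bound_lo;
      while (lo_m < e && pmis[te] - pmis[lo_m - p_lo] > m) ++lo_m;
      if (m >= 1) {
        if (lo_m1 < lo_m) lo_m1 = lo_m;
        while (lo_m1 < e && pmis[te] - pmis[lo_m1 - p_lo] > m - 1) ++lo_m1;
      }

      long gap = d + 1 - 2 * e;

      // (a) full-length windows: both extensions blocked by the arm-length cap
      long l_a = e - max_arm;
      if (l_a >= lo_m) {
        ls.push_back((int) l_a); le.push_back((int) e);
        rs.push_back((int) (d - e + 1)); re.push_back((int) (d - l_a + 1));
        al.push_back(max_arm);
        mm.push_back(pmis[te] - pmis[l_a - p_lo]);
      }

      // state of the inward-extension position p = e (paired with q = d - e)
      int st_e;
      {
        long q = d - e;
        if (e >= n || q <= e || q >= n) st_e = 2;
        else {
          int a = code[e], b = code[q];
          if (a == 4 || b == 4) st_e = 2;
          else st_e = (a + b == 3) ? 0 : 1;
        }
      }

      long len = e - lo_m;
      if (len >= min_arm && len < max_arm) {
        bool inward_blocked;
        if (gap < 2 || st_e == 2) inward_blocked = true;
        else if (st_e == 1) {
          // blocked iff window already carries m mismatches
          inward_blocked = (m == 0) ? true : (lo_m < lo_m1);
        } else inward_blocked = false;
        if (inward_blocked) {
          ls.push_back((int) lo_m); le.push_back((int) e);
          rs.push_back((int) (d - e + 1)); re.push_back((int) (d - lo_m + 1));
          al.push_back((int) len);
          mm.push_back(pmis[te] - pmis[lo_m - p_lo]);
        }
      }
    }
  }

  // deterministic order: left.start, then span length, then arm length, right.start
  const size_t np = ls.size();
  std::vector<size_t> ord(np);
  for (size_t i = 0; i < np; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (ls[a] != ls[b]) return ls[a] < ls[b];
    long spa = re[a] - ls[a], spb = re[b] - ls[b];
    if (spa != spb) return spa < spb;
    if (al[a] != al[b]) return al[a] < al[b];
    return rs[a] < rs[b];
  });
  IntegerVector o_ls(np), o_le(np), o_rs(np), o_re(np), o_al(np), o_mm(np);
  for (size_t i = 0; i < np; ++i) {
    size_t j = ord[i];
    o_ls[i] = ls[j]; o_le[i] = le[j]; o_rs[i] = rs[j];
    o_re[i] = re[j]; o_al[i] = al[j]; o_mm[i] = mm[j];
  }
  return DataFrame::create(
    _["left_start"] = o_ls, _["left_end"] = o_le,
    _["right_start"] = o_rs, _["right_end"] = o_re,
    _["arm_len"] = o_al, _["mismatches"] = o_mm);
}
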