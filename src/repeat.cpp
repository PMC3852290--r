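#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// l-mer seeded greedy repeat-consensus builder.
//
// Copies are anchored gaplessly on a shared l-mer seed; both flanks are grown
// one column at a time. At each step the majority base over live copies is
// appended to the consensus; each copy scores +match for agreement and
// -mismatch_penalty for disagreement, and drops out when its cumulative flank
// score falls max_drop below its own running maximum. A flank stops when fewer
// than min_copies copies remain live (or the max_len cap is hit) and is then
// trimmed back to the point where the aggregate score over live copies peaked.

struct FlankResult {
  std::vector<int> cons;            // consensus codes outward from the seed
  std::vector<int> extent;          // per-copy flank extent (columns kept)
};

// dir = +1 grows consensus rightward, -1 leftward.
static FlankResult grow_flank(const std::vector<int>& g, long n,
                              const std::vector<long>& pos,
                              const std::vector<int>& strand, int l,
                              int dir, int min_copies, long max_steps,
                              double match, double mispen, double max_drop) {
  const size_t nc = pos.size();
  std::vector<double> score(nc, 0.0), bestscore(nc, 0.0);
  std::vector<long> bestc(nc, 0);
  std::vector<bool> live(nc, true);
  FlankResult res;
  res.extent.assign(nc, 0);
  int nlive = (int) nc;
  double agg = 0.0, aggbest = 0.0;
  long cbest = 0;
  std::vector<int> bases(nc);
  for (long step = 1; step <= max_steps; ++step) {
    // consensus coordinate for this step
    long c = (dir > 0) ? (l - 1 + step) : (-step);
    int cnt[4] = {0, 0, 0, 0};
    for (size_t i = 0; i < nc; ++i) {
      if (!live[i]) continue;
      long gi = (strand[i] > 0) ? (pos[i] + c) : (pos[i] + l - 1 - c);
      int b = (gi >= 0 && gi < n) ? g[gi] : -1;
      if (b >= 0 && b <= 3 && strand[i] < 0) b = 3 - b;
      if (b < 0 || b > 3) { live[i] = false; --nlive; agg -= score[i]; b = -1; }
      bases[i] = b;
      if (b >= 0) cnt[b]++;
    }
    if (nlive < min_copies) break;
    int cons = 0;
    for (int b = 1; b < 4; ++b) if (cnt[b] > cnt[cons]) cons = b;
    res.cons.push_back(cons);
    for (size_t i = 0; i < nc; ++i) {
      if (!live[i]) continue;
      double d = (bases[i] == cons) ? match : -mispen;
      agg += d;
      score[i] += d;
      if (score[i] > bestscore[i]) { bestscore[i] = score[i]; bestc[i] = step; }
      else if (score[i] < bestscore[i] - max_drop) {
        live[i] = false; --nlive; agg -= score[i];
      }
    }
    if (nlive < min_copies) { res.cons.pop_back(); break; }
    if (agg > aggbest) { aggbest = agg; cbest = step; }
  }
  if ((long) res.cons.size() > cbest) res.cons.resize(cbest);
  for (size_t i = 0; i < nc; ++i)
    res.extent[i] = (int) std::min(bestc[i], cbest);
  return res;
}

// [[Rcpp::export]]
SEXP build_consensus_cpp(IntegerVector genome, IntegerVector positions,
                         IntegerVector strands, int lmer, int min_copies,
                         int min_len, int max_len, double match,
                         double mismatch_penalty, double max_drop) {
  const long n = genome.size();
  std::vector<int> g(genome.begin(), genome.end());
  const size_t nc = positions.size();
  std::vector<long> pos(nc);
  std::vector<int> strand(nc);
  for (size_t i = 0; i < nc; ++i) { pos[i] = positions[i]; strand[i] = strands[i]; }
  if ((int) nc < min_copies) return R_NilValue;

  long max_steps = (max_len - lmer) / 2;   // per flank, so total stays <= max_len
  if (max_steps < 0) max_steps = 0;
  FlankResult right = grow_flank(g, n, pos, strand, lmer, +1, min_copies,
                                 max_steps, match, mismatch_penalty, max_drop);
  FlankResult left = grow_flank(g, n, pos, strand, lmer, -1, min_copies,
                                max_steps, match, mismatch_penalty, max_drop);

  const long L = (long) left.cons.size();
  const long R = (long) right.cons.size();
  const long clen = L + lmer + R;
  if (clen < min_len) return R_NilValue;

  // consensus codes over coordinates [-L, lmer + R)
  std::vector<int> cons(clen);
  for (long t = 0; t < L; ++t) cons[L - 1 - t] = left.cons[t];
  // seed columns: majority over copies
  for (int c = 0; c < lmer; ++c) {
    int cnt[4] = {0, 0, 0, 0};
    for (size_t i = 0; i < nc; ++i) {
      long gi = (strand[i] > 0) ? (pos[i] + c) : (pos[i] + lmer - 1 - c);
      int b = g[gi];
      if (strand[i] < 0 && b <= 3) b = 3 - b;
      if (b >= 0 && b <= 3) cnt[b]++;
    }
    int cb = 0;
    for (int b = 1; b < 4; ++b) if (cnt[b] > cnt[cb]) cb = b;
    cons[L + c] = cb;
  }
  for (long t = 0; t < R; ++t) cons[L + lmer + t] = right.cons[t];

  // per-copy genome intervals and identity to consensus over the copy extent
  IntegerVector c_start(nc), c_end(nc), c_strand(nc);
  NumericVector c_ident(nc);
  for (size_t i = 0; i < nc; ++i) {
    long le = left.extent[i], re = right.extent[i];
    long gs, ge; // half-open genome interval
    if (strand[i] > 0) { gs = pos[i] - le; ge = pos[i] + lmer + re; }
    else { gs = pos[i] - re; ge = pos[i] + lmer + le; }
    long matches = 0, total = 0;
    for (long c = -le; c < lmer + re; ++c) {
      long gi = (strand[i] > 0) ? (pos[i] + c) : (pos[i] + lmer - 1 - c);
      int b = g[gi];
      if (strand[i] < 0 && b <= 3) b = 3 - b;
      ++total;
      if (b == cons[L + c]) ++matches;
    }
    c_start[i] = (int) gs; c_end[i] = (int) ge; c_strand[i] = strand[i];
    c_ident[i] = total > 0 ? (double) matches / total : 0.0;
  }

  // a seed occurring several times inside one element anchors the same copy
  // in several phases: drop vestigial short extents, then deduplicate
  // overlapping intervals keeping the longest (ties: leftmost)
  std::vector<size_t> ord(nc);
  for (size_t i = 0; i < nc; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    long la = c_end[a] - c_start[a], lb = c_end[b] - c_start[b];
    if (la != lb) return la > lb;
    return c_start[a] < c_start[b];
  });
  std::vector<size_t> kept;
  for (size_t oi = 0; oi < nc; ++oi) {
    size_t i = ord[oi];
    long len_i = c_end[i] - c_start[i];
    if (len_i < 0.8 * clen) continue;   // vestigial phase/fragment anchors
    bool clash = false;
    for (size_t j : kept) {
      long ov = std::min((long) c_end[i], (long) c_end[j]) -
                std::max((long) c_start[i], (long) c_start[j]);
      long shorter = std::min(len_i, (long) c_end[j] - c_start[j]);
      if (ov > shorter / 4) { clash = true; break; }
    }
    if (!clash) kept.push_back(i);
  }
  if ((int) kept.size() < min_copies) return R_NilValue;
  std::sort(kept.begin(), kept.end(), [&](size_t a, size_t b) {
    return c_start[a] < c_start[b];
  });
  IntegerVector k_start(kept.size()), k_end(kept.size()), k_strand(kept.size());
  NumericVector k_ident(kept.size());
  for (size_t i = 0; i < kept.size(); ++i) {
    k_start[i] = c_start[kept[i]]; k_end[i] = c_end[kept[i]];
    k_strand[i] = c_strand[kept[i]]; k_ident[i] = c_ident[kept[i]];
  }

  return List::create(
    _["consensus"] = IntegerVector(cons.begin(), cons.end()),
    _["seed_offset"] = (int) L,
    _["copies"] = DataFrame::create(_["start"] = k_start, _["end"] = k_end,
                                    _["strand"] = k_strand,
                                    _["identity"] = k_ident));
}

static double lmer_entropy(uint64_t key, int l) {
  int cnt[4] = {0, 0, 0, 0};
  for (int t = 0; t < l; ++t) { cnt[key & 3ULL]++; key >>= 2; }
  double h = 0.0;
  for (int b = 0; b < 4; ++b) {
    if (cnt[b] == 0) continue;
    double p = (double) cnt[b] / l;
    h -= p * std::log2(p);
  }
  return h;
}

// Full de novo repeat-family search: canonical l-mer seeding by descending
// occurrence count (ties: lexicographic), greedy consensus building, and
// masking of accepted family copies so each genome position supports at most
// one family.
// [[Rcpp::export]]
List repeat_families_cpp(IntegerVector genome, int lmer, int min_copies,
                         int min_len, int max_len, double match,
                         double mismatch_penalty, double max_drop,
                         double min_entropy) {
  const long n = genome.size();
  std::vector<int> g(genome.begin(), genome.end());

  // canonical l-mer occurrence list
  struct Occ { uint64_t key; long pos; int strand; };
  std::vector<Occ> occs;
  occs.reserve(n > lmer ? n - lmer + 1 : 0);
  uint64_t fwd = 0, rev = 0;
  const uint64_t mask_key = (lmer < 32) ? ((1ULL << (2 * lmer)) - 1) : ~0ULL;
  const uint64_t shift = 2 * (lmer - 1);
  int run = 0;
  for (long i = 0; i < n; ++i) {
    int c = g[i];
    if (c < 0 || c > 3) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t) c) & mask_key;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (run < lmer) ++run;
    if (run >= lmer) {
      long p = i - lmer + 1;
      if (fwd <= rev) occs.push_back({fwd, p, +1});
      else occs.push_back({rev, p, -1});
    }
  }
  std::sort(occs.begin(), occs.end(), [](const Occ& a, const Occ& b) {
    if (a.key != b.key) return a.key < b.key;
    return a.pos < b.pos;
  });

  // group boundaries
  struct Grp { size_t lo, hi; uint64_t key; };
  std::vector<Grp> grps;
  for (size_t i = 0; i < occs.size();) {
    size_t j = i;
    while (j < occs.size() && occs[j].key == occs[i].key) ++j;
    if ((int)(j - i) >= min_copies) grps.push_back({i, j, occs[i].key});
    i = j;
  }
  std::sort(grps.begin(), grps.end(), [](const Grp& a, const Grp& b) {
    size_t ca = a.hi - a.lo, cb = b.hi - b.lo;
    if (ca != cb) return ca > cb;
    return a.key < b.key;
  });

  std::vector<bool> masked(n, false);
  List fams;

  for (const Grp& gr : grps) {
    if (lmer_entropy(gr.key, lmer) < min_entropy) continue;
    // collect unmasked, mutually non-overlapping occurrences
    std::vector<long> pos;
    std::vector<int> strand;
    long lastp = -(long) lmer - 1;
    for (size_t t = gr.lo; t < gr.hi; ++t) {
      long p = occs[t].pos;
      if (p < lastp + lmer) continue;
      bool bad = false;
      for (long u = p; u < p + lmer; ++u) if (masked[u]) { bad = true; break; }
      if (bad) continue;
      pos.push_back(p);
      strand.push_back(occs[t].strand);
      lastp = p;
    }
    if ((int) pos.size() < min_copies) continue;

    RObject famr = build_consensus_cpp(
      IntegerVector(g.begin(), g.end()),
      IntegerVector(pos.begin(), pos.end()),
      IntegerVector(strand.begin(), strand.end()),
      lmer, min_copies, min_len, max_len, match, mismatch_penalty, max_drop);
    if (famr.isNULL()) continue;
    List fam(famr);

    // drop copies that ran into already-masked territory
    DataFrame copies = as<DataFrame>(fam["copies"]);
    IntegerVector cs = copies["start"], ce = copies["end"], cstr = copies["strand"];
    NumericVector cid = copies["identity"];
    std::vector<int> ks, ke, kstr;
    std::vector<double> kid;
    for (int i = 0; i < cs.size(); ++i) {
      bool bad = false;
      for (long u = cs[i]; u < ce[i]; ++u) if (masked[u]) { bad = true; break; }
      if (!bad) { ks.push_back(cs[i]); ke.push_back(ce[i]);
                  kstr.push_back(cstr[i]); kid.push_back(cid[i]); }
    }
    if ((int) ks.size() < min_copies) continue;

    for (size_t i = 0; i < ks.size(); ++i)
      for (long u = ks[i]; u < ke[i]; ++u) masked[u] = true;

    fams.push_back(List::create(
      _["consensus"] = fam["consensus"],
      _["copies"] = DataFrame::create(
        _["start"] = IntegerVector(ks.begin(), ks.end()),
        _["end"] = IntegerVector(ke.begin(), ke.end()),
        _["strand"] = IntegerVector(kstr.begin(), kstr.end()),
        _["identity"] = NumericVector(kid.begin(), kid.end()))));
  }
  return fams;
}
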