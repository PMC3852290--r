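#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Local (match-entry / match-exit) profile HMM scoring in log2-odds space.
// Emission matrices arrive as K x 20 log2-odds (model over background);
// transition vectors arrive in log2 space with -Inf for disallowed moves.
// Residue codes outside [0, 20) (e.g. X) contribute 0 bits in both match and
// insert states.

struct Model {
  int K;
  const double *me, *ie;     // K x 20, column-major from R: me[k + K*a]
  std::vector<double> tmm, tmi, tmd, tim, tii, tdm, tdd, tme, entry; // 1-based
};

static Model parse_model(const List& mod) {
  Model m;
  NumericMatrix me = mod["me_lo"], ie = mod["ie_lo"];
  m.K = me.nrow();
  m.me = REAL(me); m.ie = REAL(ie);
  auto getv = [&](const char* nm) {
    NumericVector v = mod[nm];
    std::vector<double> out(v.size() + 1, -INFINITY);
    for (int i = 0; i < v.size(); ++i) out[i + 1] = v[i];
    return out;
  };
  m.tmm = getv("tmm"); m.tmi = getv("tmi"); m.tmd = getv("tmd");
  m.tim = getv("tim"); m.tii = getv("tii");
  m.tdm = getv("tdm"); m.tdd = getv("tdd");
  m.tme = getv("tme"); m.entry = getv("entry");
  return m;
}

static inline double emit(const double* e, int K, int k, int code) {
  return (code >= 0 && code < 20) ? e[(k - 1) + (size_t) K * code] : 0.0;
}

static const double NEG = -INFINITY;

// core Viterbi; fills score and envelope (1-based residue span)
static void viterbi_core(const Model& m, const std::vector<int>& x,
                         double* out_bits, int* out_s, int* out_e) {
  const int K = m.K, L = (int) x.size();
  std::vector<double> VMp(K + 1, NEG), VIp(K + 1, NEG), VDp(K + 1, NEG);
  std::vector<double> VM(K + 1, NEG), VI(K + 1, NEG), VD(K + 1, NEG);
  std::vector<int> SMp(K + 1, 0), SIp(K + 1, 0), SDp(K + 1, 0);
  std::vector<int> SM(K + 1, 0), SI(K + 1, 0), SD(K + 1, 0);
  double best = NEG; int bs = 0, be = 0;
  for (int i = 1; i <= L; ++i) {
    std::fill(VM.begin(), VM.end(), NEG);
    std::fill(VI.begin(), VI.end(), NEG);
    std::fill(VD.begin(), VD.end(), NEG);
    for (int k = 1; k <= K; ++k) {
      // match
      double v = m.entry[k]; int s = i;
      if (k > 1) {
        double c = VMp[k - 1] + m.tmm[k - 1];
        if (c > v) { v = c; s = SMp[k - 1]; }
        c = VIp[k - 1] + m.tim[k - 1];
        if (c > v) { v = c; s = SIp[k - 1]; }
        c = VDp[k - 1] + m.tdm[k - 1];
        if (c > v) { v = c; s = SDp[k - 1]; }
      }
      VM[k] = v + emit(m.me, K, k, x[i - 1]); SM[k] = s;
      // insert (I_k exists for k < K)
      if (k < K) {
        double vi = VMp[k] + m.tmi[k]; int si = SMp[k];
        double c = VIp[k] + m.tii[k];
        if (c > vi) { vi = c; si = SIp[k]; }
        VI[k] = vi + emit(m.ie, K, k, x[i - 1]); SI[k] = si;
      }
      // delete (silent, same i)
      if (k > 1) {
        double vd = VM[k - 1] + m.tmd[k - 1]; int sd = SM[k - 1];
        double c = VD[k - 1] + m.tdd[k - 1];
        if (c > vd) { vd = c; sd = SD[k - 1]; }
        VD[k] = vd; SD[k] = sd;
      }
      double fin = VM[k] + m.tme[k];
      if (fin > best) { best = fin; bs = SM[k]; be = i; }
    }
    std::swap(VM, VMp); std::swap(VI, VIp); std::swap(VD, VDp);
    std::swap(SM, SMp); std::swap(SI, SIp); std::swap(SD, SDp);
  }
  *out_bits = best; *out_s = bs; *out_e = be;
}

static inline double lse2(double a, double b) {
  if (a == NEG) return b;
  if (b == NEG) return a;
  double hi = a > b ? a : b, lo = a > b ? b : a;
  return hi + std::log2(1.0 + std::exp2(lo - hi));
}

// [[Rcpp::export]]
List viterbi_cpp(List mod, IntegerVector pep) {
  Model m = parse_model(mod);
  std::vector<int> x(pep.begin(), pep.end());
  double bits; int s, e;
  viterbi_core(m, x, &bits, &s, &e);
  return List::create(_["bits"] = bits, _["env_start"] = s, _["env_end"] = e);
}

// [[Rcpp::export]]
double forward_cpp(List mod, IntegerVector pep) {
  Model m = parse_model(mod);
  const int K = m.K, L = pep.size();
  std::vector<int> x(pep.begin(), pep.end());
  std::vector<double> VMp(K + 1, NEG), VIp(K + 1, NEG), VDp(K + 1, NEG);
  std::vector<double> VM(K + 1, NEG), VI(K + 1, NEG), VD(K + 1, NEG);
  double total = NEG;
  for (int i = 1; i <= L; ++i) {
    std::fill(VM.begin(), VM.end(), NEG);
    std::fill(VI.begin(), VI.end(), NEG);
    std::fill(VD.begin(), VD.end(), NEG);
    for (int k = 1; k <= K; ++k) {
      double v = m.entry[k];
      if (k > 1) {
        v = lse2(v, VMp[k - 1] + m.tmm[k - 1]);
        v = lse2(v, VIp[k - 1] + m.tim[k - 1]);
        v = lse2(v, VDp[k - 1] + m.tdm[k - 1]);
      }
      VM[k] = v + emit(m.me, K, k, x[i - 1]);
      if (k < K) {
        double vi = lse2(VMp[k] + m.tmi[k], VIp[k] + m.tii[k]);
        VI[k] = vi + emit(m.ie, K, k, x[i - 1]);
      }
      if (k > 1) {
        VD[k] = lse2(VM[k - 1] + m.tmd[k - 1], VD[k - 1] + m.tdd[k - 1]);
      }
      total = lse2(total, VM[k] + m.tme[k]);
    }
    std::swap(VM, VMp); std::swap(VI, VIp); std::swap(VD, VDp);
  }
  return total;
}

// Batch Viterbi scores for calibration / search (no envelopes needed).
// [[Rcpp::export]]
NumericVector viterbi_batch_cpp(List mod, List peps) {
  Model m = parse_model(mod);
  const int np = peps.size();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    IntegerVector pv = peps[p];
    std::vector<int> x(pv.begin(), pv.end());
    double bits; int s, e;
    viterbi_core(m, x, &bits, &s, &e);
    out[p] = bits;
  }
  return out;
}
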