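#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Sequences are integer-coded: A=0, C=1, G=2, T=3; anything negative is a
// masked/ambiguous base and no window may cover it.

struct WindowIndex {
  std::vector<const int*> seq;   // base pointer per input sequence
  std::vector<int> len;
  std::vector<int> win_seq;      // 0-based sequence index per window
  std::vector<int> win_pos;      // 0-based start offset per window
};

static void collect_windows(const List& seqs, int w, WindowIndex& wi) {
  int n = seqs.size();
  wi.seq.resize(n);
  wi.len.resize(n);
  for (int s = 0; s < n; ++s) {
    SEXP el = seqs[s];
    wi.seq[s] = INTEGER(el);
    wi.len[s] = Rf_length(el);
  }
  for (int s = 0; s < n; ++s) {
    const int* x = wi.seq[s];
    int L = wi.len[s];
    if (L < w) continue;
    int bad = 0;
    for (int i = 0; i < w; ++i) if (x[i] < 0) ++bad;
    if (bad == 0) { wi.win_seq.push_back(s); wi.win_pos.push_back(0); }
    for (int i = 1; i + w <= L; ++i) {
      if (x[i - 1] < 0) --bad;
      if (x[i + w - 1] < 0) ++bad;
      if (bad == 0) { wi.win_seq.push_back(s); wi.win_pos.push_back(i); }
    }
  }
}

// Two-component mixture EM over all width-w windows (both strands when
// both_strands is true): each oriented window is either a motif occurrence
// (probability gamma) or background.  M-step is a MAP update with Dirichlet
// pseudocounts, so the penalised log-likelihood-ratio objective is
// non-decreasing across iterations.
// [[Rcpp::export]]
List cpp_em_anr(List seqs, int w, NumericMatrix p0, NumericVector bg,
                double gamma0, int maxit, double tol, NumericVector pseudo,
                bool both_strands) {
  if (w < 1) stop("motif width must be positive");
  if (p0.nrow() != w || p0.ncol() != 4) stop("initial matrix must be width x 4");
  WindowIndex wi;
  collect_windows(seqs, w, wi);
  const size_t nw = wi.win_seq.size();
  if (nw == 0) stop("no scannable windows of width ", w);

  std::vector<double> pbf(nw), pbr(nw);
  for (size_t k = 0; k < nw; ++k) {
    const int* x = wi.seq[wi.win_seq[k]] + wi.win_pos[k];
    double f = 1.0, r = 1.0;
    for (int j = 0; j < w; ++j) { f *= bg[x[j]]; r *= bg[3 - x[j]]; }
    pbf[k] = f; pbr[k] = r;
  }

  std::vector<double> P(4 * (size_t)w);
  for (int j = 0; j < w; ++j)
    for (int b = 0; b < 4; ++b) P[4 * j + b] = p0(j, b);

  const double n_data = both_strands ? 2.0 * nw : (double)nw;
  double g = std::min(std::max(gamma0, 1e-8), 0.5);
  std::vector<double> zf(nw, 0.0), zr(nw, 0.0), C(4 * (size_t)w, 0.0);
  std::vector<double> traj;
  double prev = R_NegInf, obj = R_NegInf, zsum = 0.0;

  for (int it = 0; ; ++it) {
    obj = 0.0;
    zsum = 0.0;
    std::fill(C.begin(), C.end(), 0.0);
    for (size_t k = 0; k < nw; ++k) {
      const int* x = wi.seq[wi.win_seq[k]] + wi.win_pos[k];
      double pmf = 1.0, pmr = 1.0;
      for (int j = 0; j < w; ++j) {
        pmf *= P[4 * j + x[j]];
        if (both_strands) pmr *= P[4 * (w - 1 - j) + (3 - x[j])];
      }
      double af = g * pmf + (1.0 - g) * pbf[k];
      obj += std::log(af / pbf[k]);
      double zfk = g * pmf / af;
      zf[k] = zfk;
      zsum += zfk;
      for (int j = 0; j < w; ++j) C[4 * j + x[j]] += zfk;
      if (both_strands) {
        double ar = g * pmr + (1.0 - g) * pbr[k];
        obj += std::log(ar / pbr[k]);
        double zrk = g * pmr / ar;
        zr[k] = zrk;
        zsum += zrk;
        for (int j = 0; j < w; ++j) C[4 * (w - 1 - j) + (3 - x[j])] += zrk;
      }
    }
    for (int j = 0; j < w; ++j)
      for (int b = 0; b < 4; ++b) obj += pseudo[b] * std::log(P[4 * j + b]);
    traj.push_back(obj);
    if (it >= maxit) break;
    if (it > 0 && obj - prev < tol) break;
    prev = obj;
    // M-step (MAP with Dirichlet pseudocounts)
    for (int j = 0; j < w; ++j) {
      double rs = 0.0;
      double row[4];
      for (int b = 0; b < 4; ++b) { row[b] = C[4 * j + b] + pseudo[b]; rs += row[b]; }
      for (int b = 0; b < 4; ++b) P[4 * j + b] = row[b] / rs;
    }
    g = std::min(std::max(zsum / n_data, 1e-8), 0.5);
  }

  NumericMatrix probs(w, 4), counts(w, 4);
  for (int j = 0; j < w; ++j)
    for (int b = 0; b < 4; ++b) {
      probs(j, b) = P[4 * j + b];
      counts(j, b) = C[4 * j + b];
    }
  return List::create(
    _["probs"] = probs,
    _["counts"] = counts,
    _["nsites"] = zsum,
    _["gamma"] = g,
    _["objective"] = obj,
    _["trajectory"] = NumericVector(traj.begin(), traj.end()),
    _["win_seq"] = IntegerVector(wi.win_seq.begin(), wi.win_seq.end()),
    _["win_pos"] = IntegerVector(wi.win_pos.begin(), wi.win_pos.end()),
    _["zf"] = NumericVector(zf.begin(), zf.end()),
    _["zr"] = NumericVector(zr.begin(), zr.end()),
    _["n_windows"] = (double)nw);
}

// w-mers are packed 2 bits per base into a (hi, lo) pair of 64-bit words:
// hi holds the first min(w, 32) bases, lo the remainder, so numeric order of
// the pair equals lexicographic order of the w-mer (A < C < G < T).
typedef std::pair<uint64_t, uint64_t> Kmer;

static Kmer revcomp_key(const Kmer& key, int w) {
  int w1 = w > 32 ? 32 : w;
  int w2 = w - w1;
  // unpack, complement, reverse, repack
  int base[64];
  for (int j = 0; j < w1; ++j)
    base[j] = (int)((key.first >> (2 * (w1 - 1 - j))) & 3ULL);
  for (int j = 0; j < w2; ++j)
    base[w1 + j] = (int)((key.second >> (2 * (w2 - 1 - j))) & 3ULL);
  uint64_t hi = 0, lo = 0;
  for (int j = 0; j < w1; ++j) hi = (hi << 2) | (uint64_t)(3 - base[w - 1 - j]);
  for (int j = 0; j < w2; ++j)
    lo = (lo << 2) | (uint64_t)(3 - base[w - 1 - (w1 + j)]);
  return Kmer(hi, lo);
}

static std::string decode_key(const Kmer& key, int w) {
  static const char alpha[] = "ACGT";
  int w1 = w > 32 ? 32 : w;
  int w2 = w - w1;
  std::string s(w, 'A');
  for (int j = 0; j < w1; ++j)
    s[j] = alpha[(key.first >> (2 * (w1 - 1 - j))) & 3ULL];
  for (int j = 0; j < w2; ++j)
    s[w1 + j] = alpha[(key.second >> (2 * (w2 - 1 - j))) & 3ULL];
  return s;
}

// Highest background-corrected-frequency w-mers over all valid windows (both
// strands when both_strands is true).  Ties in the score are broken by
// lexicographic order so seeding is fully deterministic.
// [[Rcpp::export]]
CharacterVector cpp_top_seeds(List seqs, int w, NumericVector bg, int k,
                              bool both_strands) {
  if (w < 1 || w > 64) stop("seed width must be in 1..64");
  const int w1 = w > 32 ? 32 : w;
  const int w2 = w - w1;
  const uint64_t mask1 = (w1 == 32) ? ~0ULL : ((1ULL << (2 * w1)) - 1ULL);
  const uint64_t mask2 = (w2 == 0) ? 0ULL : ((1ULL << (2 * w2)) - 1ULL);

  std::vector<Kmer> keys;  // numeric order == lexicographic order
  int n_seqs = seqs.size();
  for (int s = 0; s < n_seqs; ++s) {
    SEXP el = seqs[s];
    const int* x = INTEGER(el);
    int L = Rf_length(el);
    if (keys.capacity() < keys.size() + (size_t)L)
      keys.reserve(keys.size() + (size_t)L);
    uint64_t hi = 0, lo = 0;
    int run = 0;  // consecutive valid bases ending at current position
    for (int i = 0; i < L; ++i) {
      int b = x[i];
      if (b < 0) { run = 0; hi = 0; lo = 0; continue; }
      if (w2 > 0) {
        // a window is only emitted once run >= w, at which point the carry
        // chain has filled hi/lo with exactly the window's bases
        int carry = (int)((lo >> (2 * (w2 - 1))) & 3ULL);
        hi = ((hi << 2) | (uint64_t)carry) & mask1;
        lo = ((lo << 2) | (uint64_t)b) & mask2;
      } else {
        hi = ((hi << 2) | (uint64_t)b) & mask1;
      }
      ++run;
      if (run >= w) keys.push_back(Kmer(hi, lo));
    }
  }
  if (keys.empty()) return CharacterVector(0);
  std::sort(keys.begin(), keys.end());

  double lb[4];
  for (int b = 0; b < 4; ++b) lb[b] = std::log(bg[b]);
  std::vector<std::pair<double, Kmer> > scored;
  size_t i0 = 0;
  while (i0 < keys.size()) {
    size_t i1 = i0;
    while (i1 < keys.size() && keys[i1] == keys[i0]) ++i1;
    long c = (long)(i1 - i0);
    if (both_strands) {
      std::pair<std::vector<Kmer>::iterator, std::vector<Kmer>::iterator> er =
        std::equal_range(keys.begin(), keys.end(), revcomp_key(keys[i0], w));
      c += er.second - er.first;
    }
    std::string s = decode_key(keys[i0], w);
    double sc = std::log((double)c);
    for (int j = 0; j < w; ++j) {
      switch (s[j]) {
        case 'A': sc -= lb[0]; break;
        case 'C': sc -= lb[1]; break;
        case 'G': sc -= lb[2]; break;
        default:  sc -= lb[3];
      }
    }
    scored.push_back(std::make_pair(sc, keys[i0]));
    i0 = i1;
  }
  std::sort(scored.begin(), scored.end(),
            [](const std::pair<double, Kmer>& a,
               const std::pair<double, Kmer>& b) {
              if (a.first != b.first) return a.first > b.first;
              return a.second < b.second;
            });
  int n_out = std::min((size_t)k, scored.size());
  CharacterVector out(n_out);
  for (int i = 0; i < n_out; ++i) out[i] = decode_key(scored[i].second, w);
  return out;
}
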