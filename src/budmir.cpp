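#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Per-pair pseudo-energies (positive magnitudes, kcal/mol): GC 3, AU 2, GU 1.
// Shared by the hairpin folder and the duplex scorer so energy ratios are
// engine-consistent.
static inline int pair_energy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

static inline int can_pair(char a, char b) {
  return pair_energy(a, b) > 0 ? 1 : 0;
}

// Base-pair-maximization folder (Nussinov-style DP) over Watson-Crick and
// G:U pairs, with a minimum hairpin loop of `min_loop` unpaired bases.
//
// The primary objective is the pair count; ties are broken by a strict
// secondary objective (base-specific pair weights plus a helix-stacking
// bonus) so that long contiguous helices are preferred over count-equal
// fragmented restructurings. Because the secondary terms are bounded below
// the per-pair primary weight, every optimum still attains the maximum
// pair count. Two matrices are used: F (best over a segment) and P (best
// given the segment ends are paired), the latter carrying the stacking
// recursion. Returns the dot-bracket structure and the maximum pair count;
// the caller converts the count to an MFE via a fixed per-pair
// pseudo-energy.
// [[Rcpp::export(name = ".nussinov_fold_cpp")]]
List nussinov_fold_cpp(std::string seq, int min_loop = 3) {
  const long long BIG = 1 << 12;  // primary per-pair weight
  const long long STACK = 8;      // secondary: stacking bonus
  int n = seq.size();
  if (n == 0) return List::create(_["structure"] = "", _["score"] = 0);
  const long long NEG = -(1LL << 40);
  std::vector<long long> F((size_t)n * n, 0), P((size_t)n * n, NEG);
#define IDX(i, j) ((size_t)(i)*n + (j))
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      if (can_pair(seq[i], seq[j])) {
        long long w = BIG + pair_energy(seq[i], seq[j]);
        long long inner = 0;
        if (j - i - 2 > min_loop) {
          inner = F[IDX(i + 1, j - 1)];
          if (P[IDX(i + 1, j - 1)] > NEG)
            inner = std::max(inner, P[IDX(i + 1, j - 1)] + STACK);
        }
        P[IDX(i, j)] = w + inner;
      }
      long long best = F[IDX(i + 1, j)]; // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (P[IDX(i, k)] == NEG) continue;
        long long right = (k < j) ? F[IDX(k + 1, j)] : 0;
        long long cand = P[IDX(i, k)] + right;
        if (cand > best) best = cand;
      }
      F[IDX(i, j)] = best;
    }
  }
  // iterative traceback over (i, j, mode): mode 0 = F, 1 = P
  std::string db(n, '.');
  struct Seg { int i, j, mode; };
  std::vector<Seg> stack;
  stack.push_back(Seg{0, n - 1, 0});
  while (!stack.empty()) {
    Seg s = stack.back();
    stack.pop_back();
    int i = s.i, j = s.j;
    if (i >= j || j - i <= min_loop) continue;
    if (s.mode == 1) {
      // (i, j) is paired
      db[i] = '(';
      db[j] = ')';
      if (j - i - 2 > min_loop) {
        long long cur = P[IDX(i, j)] - (BIG + pair_energy(seq[i], seq[j]));
        if (P[IDX(i + 1, j - 1)] > NEG &&
            cur == P[IDX(i + 1, j - 1)] + STACK)
          stack.push_back(Seg{i + 1, j - 1, 1});
        else
          stack.push_back(Seg{i + 1, j - 1, 0});
      }
      continue;
    }
    long long cur = F[IDX(i, j)];
    if (cur == F[IDX(i + 1, j)]) {
      stack.push_back(Seg{i + 1, j, 0});
      continue;
    }
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (P[IDX(i, k)] == NEG) continue;
      long long right = (k < j) ? F[IDX(k + 1, j)] : 0;
      if (cur == P[IDX(i, k)] + right) {
        stack.push_back(Seg{i, k, 1});
        if (k < j) stack.push_back(Seg{k + 1, j, 0});
        break;
      }
    }
  }
#undef IDX
  int npairs = 0;
  for (int i = 0; i < n; ++i)
    if (db[i] == '(') ++npairs;
  return List::create(_["structure"] = db, _["score"] = npairs);
}

static inline char dna_complement(char b) {
  switch (b) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
  }
  return 'N';
}

// Weighted mismatch of one alignment column: miRNA base m vs target base t.
// match 0, G:U wobble 0.5 (stored doubled as 1), mismatch 1 (doubled 2).
static inline int col_weight2(char m, char t) {
  if (t == dna_complement(m)) return 0;
  if ((m == 'G' && t == 'T') || (m == 'T' && t == 'G')) return 1;
  return 2;
}

struct Cand {
  int start, end, gap_type, gap_pos, total2, mfe;
  std::string states;
  int cleavage;
};

// Build one alignment candidate. miRNA position p (1-based from 5' end)
// pairs the target base at transcript coordinate (end-1) - (p-1) + shift,
// reading the site 3'->5'. gap_type: 0 none, 1 target bulge at alignment
// position gap_pos, 2 miRNA bulge (miRNA base gap_pos unpaired).
static bool build_cand(const std::string &mir, const std::string &tx,
                       int start, int end, int gap_type, int gap_pos,
                       int max_total2, Cand &out) {
  int m = mir.size();
  std::string states;
  states.reserve(m + 1);
  int total2 = 0, mfe = 0, cleave = -1;
  int ti = end - 1; // transcript coordinate paired with current column
  int p = 1;        // miRNA position
  int col = 1;
  int ncols = (gap_type == 1) ? m + 1 : m;
  for (; col <= ncols; ++col) {
    if (gap_type == 1 && col == gap_pos) {
      states.push_back('B'); // bulged target base, unpaired
      total2 += 2;
      --ti;
      continue;
    }
    if (gap_type == 2 && col == gap_pos) {
      states.push_back('b'); // bulged miRNA base, no target base consumed
      total2 += 2;
      ++p;
      continue;
    }
    if (ti < start || p > m) return false;
    char mb = mir[p - 1], tb = tx[ti];
    int w2 = col_weight2(mb, tb);
    total2 += w2;
    if (total2 > max_total2) return false;
    if (w2 == 0) {
      states.push_back('M');
      mfe += pair_energy(mb, dna_complement(mb));
    } else if (w2 == 1) {
      states.push_back('G');
      mfe += 1;
    } else {
      states.push_back('X');
    }
    if (p == 10) cleave = ti;
    --ti;
    ++p;
  }
  if (p != m + 1) return false;
  out.start = start;
  out.end = end;
  out.gap_type = gap_type;
  out.gap_pos = gap_pos;
  out.total2 = total2;
  out.mfe = mfe;
  out.states = states;
  out.cleavage = cleave;
  return true;
}

// Enumerate candidate miRNA/target duplexes along a transcript.
// Windows are read 3'->5' against the miRNA 5'->3'; at most one 1-nt bulge
// on either strand. Candidates with weighted mismatch total <= max_total
// are returned; rule checking happens in R. A cheap seed prefilter on
// miRNA positions 1..13 (allowing a +/-1 register shift) skips hopeless
// windows.
// [[Rcpp::export(name = ".duplex_scan_cpp")]]
DataFrame duplex_scan_cpp(std::string mir, std::string tx,
                          double max_total = 4.0) {
  int m = mir.size(), L = tx.size();
  int max_total2 = (int)(2.0 * max_total + 0.5);
  std::vector<Cand> keep;
  int seedlen = std::min(13, m);
  // alignment right edge e (exclusive): miRNA pos1 pairs tx[e-1]
  for (int e = seedlen; e <= L; ++e) {
    // seed prefilter at registers 0, +1, -1
    int best_seed = 1 << 30;
    for (int shift = -1; shift <= 1; ++shift) {
      int s2 = 0;
      for (int p = 1; p <= seedlen; ++p) {
        int ti = e - 1 - (p - 1) + shift;
        if (ti < 0 || ti >= L) { s2 += 2; continue; }
        s2 += col_weight2(mir[p - 1], tx[ti]);
      }
      if (s2 < best_seed) best_seed = s2;
    }
    if (best_seed > max_total2 + 3) continue;
    Cand c;
    // ungapped
    if (e - m >= 0 &&
        build_cand(mir, tx, e - m, e, 0, 0, max_total2, c))
      keep.push_back(c);
    // one target bulge (window m+1 long)
    if (e - m - 1 >= 0)
      for (int g = 2; g <= m; ++g)
        if (build_cand(mir, tx, e - m - 1, e, 1, g, max_total2, c))
          keep.push_back(c);
    // one miRNA bulge (window m-1 long)
    if (e - m + 1 >= 0)
      for (int g = 2; g <= m - 1; ++g)
        if (build_cand(mir, tx, e - m + 1, e, 2, g, max_total2, c))
          keep.push_back(c);
  }
  int n = keep.size();
  IntegerVector start(n), end(n), gap_type(n), gap_pos(n), cleavage(n);
  NumericVector total(n), mfe(n);
  CharacterVector states(n);
  for (int i = 0; i < n; ++i) {
    start[i] = keep[i].start;
    end[i] = keep[i].end;
    gap_type[i] = keep[i].gap_type;
    gap_pos[i] = keep[i].gap_pos;
    total[i] = keep[i].total2 / 2.0;
    mfe[i] = -(double)keep[i].mfe;
    states[i] = keep[i].states;
    cleavage[i] = keep[i].cleavage;
  }
  return DataFrame::create(
      _["site_start"] = start, _["site_end"] = end, _["gap_type"] = gap_type,
      _["gap_pos"] = gap_pos, _["mismatch_total"] = total,
      _["duplex_mfe"] = mfe, _["states"] = states, _["cleavage"] = cleavage,
      _["stringsAsFactors"] = false);
}

// Locate the 3' adapter in each read: leftmost position whose suffix
// matches an adapter prefix of length >= min_overlap with <= 1 mismatch
// ("longest prefix match"). Returns 0-based insert length, or -1 when no
// adapter is found.
// [[Rcpp::export(name = ".locate_adapter3_cpp")]]
IntegerVector locate_adapter3_cpp(CharacterVector reads, std::string adapter,
                                  int min_overlap = 5) {
  int n = reads.size(), alen = adapter.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int rlen = std::strlen(s);
    int pos = -1;
    for (int i = 0; i <= rlen - min_overlap; ++i) {
      int L = std::min(alen, rlen - i);
      int mm = 0;
      bool ok = true;
      for (int k = 0; k < L; ++k) {
        if (s[i + k] != adapter[k] && ++mm > 1) { ok = false; break; }
      }
      if (ok) { pos = i; break; }
    }
    out[r] = pos;
  }
  return out;
}

// Mean Phred (Sanger, offset 33) per quality string.
// [[Rcpp::export(name = ".mean_phred_cpp")]]
NumericVector mean_phred_cpp(CharacterVector quals) {
  int n = quals.size();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    const char *q = CHAR(STRING_ELT(quals, r));
    int len = std::strlen(q);
    double s = 0;
    for (int k = 0; k < len; ++k) s += (double)(q[k] - 33);
    out[r] = len ? s / len : NA_REAL;
  }
  return out;
}
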