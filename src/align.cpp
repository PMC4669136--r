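#include <Rcpp.h>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// Pointer codes for traceback.
enum Move : unsigned char { STOP = 0, DIAG = 1, UP = 2, LEFT = 3, WRAP = 4 };

// Linear-gap dynamic-programming alignment of a (rows) against b (cols).
//
// Modes:
//   global     - Needleman-Wunsch, both sequences end to end.
//   semiglobal - end gaps of b are free: overhangs of a at either end cost
//                nothing (b must be fully covered).
//   wraparound - b is treated as circular/tandemly repeated: the path may
//                start at any column, traverse the origin (col m -> col 0)
//                any number of times at no cost, and end at any column.
//                a is consumed end to end.
//
// Ties are broken deterministically: diagonal > up (gap in b) > left (gap
// in a); a wrap is taken only when strictly better than the vertical entry.

static inline double subscore(char x, char y, double match, double mismatch) {
  return x == y ? match : mismatch;
}

// [[Rcpp::export]]
List cpp_align(std::string a, std::string b, std::string mode,
               double match, double mismatch, double gap) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence passed to aligner");
  const bool wrap = (mode == "wraparound");
  const bool semi = (mode == "semiglobal");
  const bool glob = (mode == "global");
  if (!wrap && !semi && !glob) stop("unknown alignment mode: %s", mode);
  if (wrap && gap >= 0)
    stop("wraparound alignment requires a negative gap penalty");

  std::vector<double> S((size_t)(n + 1) * (m + 1),
                        -std::numeric_limits<double>::infinity());
  std::vector<unsigned char> P((size_t)(n + 1) * (m + 1), STOP);
  auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  // row 0
  S[idx(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) {
    if (wrap) { S[idx(0, j)] = 0.0; P[idx(0, j)] = STOP; }
    else      { S[idx(0, j)] = j * gap; P[idx(0, j)] = LEFT; }
  }
  for (int i = 1; i <= n; ++i) {
    if (glob)      { S[idx(i, 0)] = i * gap; P[idx(i, 0)] = UP; }
    else if (semi) { S[idx(i, 0)] = 0.0;     P[idx(i, 0)] = STOP; }
    else           { S[idx(i, 0)] = S[idx(i - 1, 0)] + gap; P[idx(i, 0)] = UP; }

    for (int j = 1; j <= m; ++j) {
      double best = S[idx(i - 1, j - 1)] +
                    subscore(a[i - 1], b[j - 1], match, mismatch);
      unsigned char p = DIAG;
      double up = S[idx(i - 1, j)] + gap;
      if (up > best) { best = up; p = UP; }
      double left = S[idx(i, j - 1)] + gap;
      if (left > best) { best = left; p = LEFT; }
      S[idx(i, j)] = best; P[idx(i, j)] = p;
    }

    if (wrap) {
      // origin traversal: col m feeds col 0 within the row, then one extra
      // left-to-right pass propagates the improvement (gap < 0 makes a
      // second wrap in the same row strictly worse, so one pass suffices).
      if (S[idx(i, m)] > S[idx(i, 0)]) {
        S[idx(i, 0)] = S[idx(i, m)];
        P[idx(i, 0)] = WRAP;
      }
      for (int j = 1; j <= m; ++j) {
        double left = S[idx(i, j - 1)] + gap;
        if (left > S[idx(i, j)]) { S[idx(i, j)] = left; P[idx(i, j)] = LEFT; }
      }
    }
  }

  // locate alignment end
  int ei = n, ej = m;
  if (wrap) {
    double best = S[idx(n, 0)]; ej = 0;
    for (int j = 1; j <= m; ++j)  // prefer the largest j on ties so that a
      if (S[idx(n, j)] >= best) { best = S[idx(n, j)]; ej = j; }  // complete
    // trailing unit ends at col m rather than wrapping to col 0
  } else if (semi) {
    double best = S[idx(n, m)]; ei = n;
    for (int i = n - 1; i >= 0; --i)
      if (S[idx(i, m)] > best) { best = S[idx(i, m)]; ei = i; }
  }
  const double score = S[idx(ei, ej)];

  // traceback
  std::string ra, rb;           // reversed aligned strings
  ra.reserve(n + m); rb.reserve(n + m);
  int i = ei, j = ej;
  if (semi && ei < n)           // free trailing overhang of a
    for (int t = n; t > ei; --t) { ra.push_back(a[t - 1]); rb.push_back('-'); }
  while (!(i == 0 && j == 0)) {
    unsigned char p = P[idx(i, j)];
    if (p == STOP) break;
    if (p == DIAG)      { ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j; }
    else if (p == UP)   { ra.push_back(a[i - 1]); rb.push_back('-');      --i; }
    else if (p == LEFT) { ra.push_back('-');      rb.push_back(b[j - 1]); --j; }
    else /* WRAP */     { j = m; }                  // col 0 <- col m, no column
  }
  const int start_i = i, start_j = j;
  if (semi && start_i > 0)      // free leading overhang of a
    for (int t = start_i; t > 0; --t) { ra.push_back(a[t - 1]); rb.push_back('-'); }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  int matches = 0, mismatches = 0, gapcols = 0;
  for (size_t c = 0; c < ra.size(); ++c) {
    if (ra[c] == '-' || rb[c] == '-') ++gapcols;
    else if (ra[c] == rb[c]) ++matches;
    else ++mismatches;
  }

  return List::create(
    _["score"] = score, _["aligned_a"] = ra, _["aligned_b"] = rb,
    _["matches"] = matches, _["mismatches"] = mismatches,
    _["gap_columns"] = gapcols,
    _["start_j"] = (semi ? 0 : start_j), _["end_j"] = ej, _["mode"] = mode);
}

// Global-alignment match/compare counts for every pair of sequences.
// Returns matches (identical non-gap columns), compared (non-gap columns)
// and alen (full alignment length) as symmetric integer matrices.
// [[Rcpp::export]]
List cpp_identity_matrix(CharacterVector seqs,
                         double match, double mismatch, double gap) {
  const int ns = seqs.size();
  IntegerMatrix M(ns, ns), C(ns, ns), L(ns, ns);
  std::vector<std::string> ss(ns);
  for (int i = 0; i < ns; ++i) ss[i] = as<std::string>(seqs[i]);

  std::vector<double> Sprev, Scur;
  std::vector<unsigned char> P;
  for (int x = 0; x < ns; ++x) {
    const std::string &a = ss[x];
    const int n = (int)a.size();
    for (int y = x + 1; y < ns; ++y) {
      const std::string &b = ss[y];
      const int m = (int)b.size();
      Sprev.resize(m + 1); Scur.resize(m + 1);
      P.resize((size_t)(n + 1) * (m + 1));
      for (int j = 0; j <= m; ++j) {
        Sprev[j] = j * gap;
        P[j] = j ? LEFT : STOP;
      }
      for (int i = 1; i <= n; ++i) {
        unsigned char *Pi = &P[(size_t)i * (m + 1)];
        const char ai = a[i - 1];
        Scur[0] = i * gap; Pi[0] = UP;
        for (int j = 1; j <= m; ++j) {
          double best = Sprev[j - 1] + (ai == b[j - 1] ? match : mismatch);
          unsigned char p = DIAG;
          double up = Sprev[j] + gap;
          if (up > best) { best = up; p = UP; }
          double left = Scur[j - 1] + gap;
          if (left > best) { best = left; p = LEFT; }
          Scur[j] = best; Pi[j] = p;
        }
        std::swap(Sprev, Scur);
      }
      int i = n, j = m, mt = 0, cm = 0, al = 0;
      while (i > 0 || j > 0) {
        unsigned char p = P[(size_t)i * (m + 1) + j];
        ++al;
        if (p == DIAG) { ++cm; if (a[i - 1] == b[j - 1]) ++mt; --i; --j; }
        else if (p == UP) --i;
        else --j;
      }
      M(x, y) = M(y, x) = mt;
      C(x, y) = C(y, x) = cm;
      L(x, y) = L(y, x) = al;
    }
    M(x, x) = C(x, x) = L(x, x) = (int)ss[x].size();
  }
  return List::create(_["matches"] = M, _["compared"] = C, _["alen"] = L);
}

// Column-wise match/compare counts between already-aligned (gapped,
// equal-length) rows; pairwise deletion (columns with a gap in either row
// are not compared).
// [[Rcpp::export]]
List cpp_msa_identity(CharacterVector rows) {
  const int ns = rows.size();
  std::vector<std::string> ss(ns);
  for (int i = 0; i < ns; ++i) ss[i] = as<std::string>(rows[i]);
  const size_t w = ns ? ss[0].size() : 0;
  for (int i = 1; i < ns; ++i)
    if (ss[i].size() != w) stop("alignment rows differ in length");
  IntegerMatrix M(ns, ns), C(ns, ns);
  for (int x = 0; x < ns; ++x) {
    for (int y = x + 1; y < ns; ++y) {
      int mt = 0, cm = 0;
      const std::string &a = ss[x], &b = ss[y];
      for (size_t c = 0; c < w; ++c) {
        if (a[c] == '-' || b[c] == '-') continue;
        ++cm;
        if (a[c] == b[c]) ++mt;
      }
      M(x, y) = M(y, x) = mt;
      C(x, y) = C(y, x) = cm;
    }
  }
  return List::create(_["matches"] = M, _["compared"] = C);
}

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Number of k-mers of each read present in the reference k-mer set.
// References should already include reverse complements / doubled circular
// sequences as needed. k <= 31. k-mers containing non-ACGT are skipped.
// [[Rcpp::export]]
IntegerVector cpp_kmer_hits(CharacterVector reads, CharacterVector refs, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::unordered_set<uint64_t> table;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int r = 0; r < refs.size(); ++r) {
    std::string s = as<std::string>(refs[r]);
    uint64_t key = 0; int run = 0;
    for (char c : s) {
      int b = base2bits(c);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) table.insert(key);
    }
  }
  IntegerVector out(reads.size());
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    uint64_t key = 0; int run = 0, hits = 0;
    for (char c : s) {
      int b = base2bits(c);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k && table.count(key)) ++hits;
    }
    out[r] = hits;
  }
  return out;
}

// Per-read k-mer repetitiveness ingredients: total k-mers and distinct
// k-mers (non-ACGT positions break k-mers and are not counted).
// [[Rcpp::export]]
List cpp_kmer_distinct(CharacterVector reads, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  IntegerVector total(reads.size()), distinct(reads.size());
  std::unordered_set<uint64_t> seen;
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    seen.clear();
    uint64_t key = 0; int run = 0, tot = 0;
    for (char c : s) {
      int b = base2bits(c);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) { ++tot; seen.insert(key); }
    }
    total[r] = tot;
    distinct[r] = (int)seen.size();
  }
  return List::create(_["total"] = total, _["distinct"] = distinct);
}

// Self-match score profile: score(p) = fraction of positions where
// s[i] == s[i + p], over the overlap of length n - p.
// [[Rcpp::export]]
NumericVector cpp_self_match_profile(std::string s, int pmin, int pmax) {
  const int n = (int)s.size();
  if (pmin < 1 || pmax < pmin) stop("invalid period range");
  NumericVector out(pmax - pmin + 1);
  for (int p = pmin; p <= pmax; ++p) {
    int ov = n - p;
    if (ov <= 0) { out[p - pmin] = NA_REAL; continue; }
    int mt = 0;
    for (int i = 0; i < ov; ++i) if (s[i] == s[i + p]) ++mt;
    out[p - pmin] = (double)mt / ov;
  }
  return out;
}
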