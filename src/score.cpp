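// Ungapped read-vs-target scoring used by read assignment, plus canonical
// k-mer extraction used by the quantification equivalence classes.
//
// Score of a placement = number of matching bases; bases overhanging the
// target contribute nothing; non-ACGT bases never match.  The seeded scorer
// finds candidate diagonals through shared seed k-mers and rescores them
// exactly; the exhaustive scorer enumerates every diagonal of every target
// and is kept deliberately simple so it can serve as an independent
// reference in tests.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int code_of(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::vector<int8_t> encode_sexp(SEXP s) {
  const char *p = CHAR(s);
  R_xlen_t n = LENGTH(s);
  std::vector<int8_t> v((size_t) n);
  for (R_xlen_t i = 0; i < n; ++i) v[(size_t) i] = (int8_t) code_of(p[i]);
  return v;
}

static std::vector<int8_t> revcomp_codes(const std::vector<int8_t> &v) {
  size_t n = v.size();
  std::vector<int8_t> out(n);
  for (size_t i = 0; i < n; ++i) {
    int8_t b = v[n - 1 - i];
    out[i] = (b < 0) ? (int8_t) -1 : (int8_t) (3 - b);
  }
  return out;
}

// matching bases when read position 0 sits at target position d (d may be
// negative or beyond the end: overhanging positions score 0)
static inline int score_at(const std::vector<int8_t> &r,
                           const std::vector<int8_t> &t, long d) {
  long L = (long) r.size(), n = (long) t.size();
  long i0 = d < 0 ? -d : 0;
  long i1 = std::min(L, n - d);
  int s = 0;
  for (long i = i0; i < i1; ++i)
    if (r[i] >= 0 && r[i] == t[d + i]) ++s;
  return s;
}

// best score of one read (given orientation) against one target
static int best_pair(const std::vector<int8_t> &r,
                     const std::vector<int8_t> &t) {
  long L = (long) r.size(), n = (long) t.size();
  int best = 0;
  for (long d = -(L - 1); d < n; ++d) {
    int s = score_at(r, t, d);
    if (s > best) best = s;
  }
  return best;
}

// [[Rcpp::export]]
int cpp_score_pair(CharacterVector read, CharacterVector target) {
  std::vector<int8_t> r = encode_sexp(STRING_ELT(read, 0));
  std::vector<int8_t> t = encode_sexp(STRING_ELT(target, 0));
  if (r.empty() || t.empty()) return 0;
  std::vector<int8_t> rrc = revcomp_codes(r);
  return std::max(best_pair(r, t), best_pair(rrc, t));
}

// Exhaustive best score per (read, group): every target, both orientations,
// every diagonal.  Reference implementation for validation.
// [[Rcpp::export]]
IntegerMatrix cpp_scores_exhaustive(CharacterVector reads,
                                    CharacterVector targets,
                                    IntegerVector target_group,
                                    int n_groups) {
  int nt = targets.size();
  R_xlen_t nr = reads.size();
  std::vector<std::vector<int8_t>> T((size_t) nt);
  for (int j = 0; j < nt; ++j) T[(size_t) j] = encode_sexp(STRING_ELT(targets, j));

  IntegerMatrix out((int) nr, n_groups);
  for (R_xlen_t i = 0; i < nr; ++i) {
    std::vector<int8_t> r = encode_sexp(STRING_ELT(reads, i));
    std::vector<int8_t> rrc = revcomp_codes(r);
    for (int j = 0; j < nt; ++j) {
      if (T[(size_t) j].empty() || r.empty()) continue;
      int s = std::max(best_pair(r, T[(size_t) j]),
                       best_pair(rrc, T[(size_t) j]));
      int g = target_group[j] - 1;
      if (s > out(i, g)) out(i, g) = s;
    }
  }
  return out;
}

// Seeded best score per (read, group).  Seed k-mers of length k_seed shared
// between a read orientation and a target propose diagonals, which are then
// rescored exactly.  Any placement whose score s satisfies
// s >= k_seed * (L - s + 1) contains an intact seed, so choosing
// k_seed <= ceiling(min_score / (L - min_score + 1)) makes the seeded result
// identical to the exhaustive one for every score at or above min_score.
// [[Rcpp::export]]
IntegerMatrix cpp_scores_seeded(CharacterVector reads,
                                CharacterVector targets,
                                IntegerVector target_group,
                                int n_groups, int k_seed) {
  if (k_seed < 1 || k_seed > 31) stop("k_seed must be in [1, 31]");
  int nt = targets.size();
  R_xlen_t nr = reads.size();
  std::vector<std::vector<int8_t>> T((size_t) nt);
  for (int j = 0; j < nt; ++j) T[(size_t) j] = encode_sexp(STRING_ELT(targets, j));

  const uint64_t maskbits = (1ULL << (2 * k_seed)) - 1;

  // seed index over target forward strands
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> idx;
  for (int j = 0; j < nt; ++j) {
    const std::vector<int8_t> &t = T[(size_t) j];
    if ((int) t.size() < k_seed) continue;
    uint64_t key = 0;
    int valid = 0;
    for (size_t p = 0; p < t.size(); ++p) {
      if (t[p] < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) t[p]) & maskbits;
      if (++valid >= k_seed)
        idx[key].push_back(std::make_pair(j, (int) p - k_seed + 1));
    }
  }

  IntegerMatrix out((int) nr, n_groups);
  std::vector<std::pair<int64_t, long>> cands;
  for (R_xlen_t i = 0; i < nr; ++i) {
    std::vector<int8_t> orient[2];
    orient[0] = encode_sexp(STRING_ELT(reads, i));
    if (orient[0].empty()) continue;
    orient[1] = revcomp_codes(orient[0]);
    cands.clear();
    for (int o = 0; o < 2; ++o) {
      const std::vector<int8_t> &r = orient[o];
      if ((int) r.size() < k_seed) continue;
      uint64_t key = 0;
      int valid = 0;
      for (size_t p = 0; p < r.size(); ++p) {
        if (r[p] < 0) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t) r[p]) & maskbits;
        if (++valid >= k_seed) {
          std::unordered_map<uint64_t, std::vector<std::pair<int, int>>>::const_iterator
            it = idx.find(key);
          if (it == idx.end()) continue;
          long rpos = (long) p - k_seed + 1;
          for (size_t h = 0; h < it->second.size(); ++h) {
            long diag = (long) it->second[h].second - rpos;
            cands.push_back(std::make_pair(
              (int64_t) it->second[h].first * 2 + o, diag));
          }
        }
      }
    }
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
    for (size_t c = 0; c < cands.size(); ++c) {
      int j = (int) (cands[c].first / 2);
      int o = (int) (cands[c].first % 2);
      int s = score_at(orient[o], T[(size_t) j], cands[c].second);
      int g = target_group[j] - 1;
      if (s > out(i, g)) out(i, g) = s;
    }
  }
  return out;
}

// Canonical k-mer values of every length-k window (with multiplicity).
// Windows containing non-ACGT bases are skipped; with poly_a_filter the
// all-A and all-T windows are skipped.  The canonical value is the smaller
// of the forward and reverse-complement 2-bit encodings, returned as a
// double (exact for k <= 26).
// [[Rcpp::export]]
List cpp_kmer_windows(CharacterVector seqs, int k, bool poly_a_filter) {
  if (k < 1 || k > 26) stop("k must be in [1, 26]");
  const uint64_t maskbits = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const uint64_t all_a = 0;                               // A^k
  uint64_t all_t = 0;                                     // T^k
  for (int i = 0; i < k; ++i) all_t = (all_t << 2) | 3ULL;
  const int shift_rc = 2 * (k - 1);

  R_xlen_t n = seqs.size();
  List out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::vector<int8_t> s = encode_sexp(STRING_ELT(seqs, i));
    std::vector<double> vals;
    if ((int) s.size() >= k) {
      uint64_t fwd = 0, rc = 0;
      int valid = 0;
      for (size_t p = 0; p < s.size(); ++p) {
        if (s[p] < 0) { valid = 0; fwd = 0; rc = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t) s[p]) & maskbits;
        rc = (rc >> 2) | ((uint64_t) (3 - s[p]) << shift_rc);
        if (++valid >= k) {
          if (poly_a_filter && (fwd == all_a || fwd == all_t)) continue;
          uint64_t can = fwd < rc ? fwd : rc;
          vals.push_back((double) can);
        }
      }
    }
    out[i] = NumericVector(vals.begin(), vals.end());
  }
  return out;
}
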