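#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// N is never counted as a match, on either side of a pair.
static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 0;  // N or anything else: complements nothing
  }
}

static inline bool comp_match(char a, char b) {
  char ca = comp_base(a);
  return ca != 0 && ca == b;
}

static inline int base2bits(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// ---------------------------------------------------------------------------
// Interrupted inverted repeat scan.
//
// An IIR is a maximal run of complementary base pairs (p, q) along an
// anti-diagonal p + q = const of the sequence-vs-itself comparison, with the
// innermost pair defining the spacer s = q - p - 1 >= 0. Walking each
// diagonal from the innermost admissible pair outward visits every run once;
// a run is inner-maximal by construction (it starts either where the arms
// would touch or just outside a mismatching pair) and outer-maximal because
// it is closed only at a mismatch or the sequence boundary.
//
// Coordinates are 0-based half-open: left arm [l1, l2), right arm [r1, r2).
// Runs longer than any arm cap are reported with their true arm length;
// filtering on max_arm happens in R.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
DataFrame cpp_scan_iirs(std::string seq, int min_arm, int max_spacer) {
  const long n = (long) seq.size();
  std::vector<int> L1, L2, R1, R2, ARM, SPC;

  for (long c = 1; c <= 2 * n - 3; ++c) {
    long p_hi = (c - 1) / 2;              // innermost pair with q > p
    long p_lo = c - n + 1; if (p_lo < 0) p_lo = 0;
    if (p_hi < p_lo) continue;

    bool in_run = false;
    long ri = 0, rq = 0, rl = 0;          // innermost pair + length of run

    for (long p = p_hi; p >= p_lo; --p) {
      long q = c - p;
      long s_here = q - p - 1;
      if (!in_run && s_here > max_spacer) break;
      if (comp_match(seq[(size_t)p], seq[(size_t)q])) {
        if (!in_run) { in_run = true; ri = p; rq = q; rl = 1; }
        else ++rl;
      } else if (in_run) {
        long s = rq - ri - 1;
        if (s <= max_spacer && rl >= min_arm) {
          L1.push_back((int)(ri - rl + 1)); L2.push_back((int)(ri + 1));
          R1.push_back((int)rq);            R2.push_back((int)(rq + rl));
          ARM.push_back((int)rl);           SPC.push_back((int)s);
        }
        in_run = false;
      }
    }
    if (in_run) {
      long s = rq - ri - 1;
      if (s <= max_spacer && rl >= min_arm) {
        L1.push_back((int)(ri - rl + 1)); L2.push_back((int)(ri + 1));
        R1.push_back((int)rq);            R2.push_back((int)(rq + rl));
        ARM.push_back((int)rl);           SPC.push_back((int)s);
      }
    }
  }

  return DataFrame::create(
    _["l1"] = L1, _["l2"] = L2, _["r1"] = R1, _["r2"] = R2,
    _["arm_len"] = ARM, _["spacer_len"] = SPC);
}

// ---------------------------------------------------------------------------
// Exact-match anchor-and-extend read mapping.
//
// The reference is indexed by its forward-strand k-mers. For each read we
// find the maximal exact prefix match and the maximal exact suffix match,
// on either strand of any contig, seeded by the first/last k-mer of the
// read. Ties in maximal extension are broken toward the lower
// (contig, coordinate, strand) so that identical junctions from different
// reads canonicalize identically.
// ---------------------------------------------------------------------------

struct SideHit {
  int  len;      // matched read bases (0 = unmapped)
  int  contig;   // 0-based contig index, -1 if unmapped
  int  strand;   // +1 / -1
  long lo, hi;   // reference interval, 0-based half-open
  int  nhit;     // number of candidate placements achieving len
  SideHit() : len(0), contig(-1), strand(0), lo(0), hi(0), nhit(0) {}
};

static inline bool lower_placement(int c1, long lo1, int s1,
                                   int c2, long lo2, int s2) {
  if (c1 != c2) return c1 < c2;
  if (lo1 != lo2) return lo1 < lo2;
  return s1 < s2;
}

static inline void consider(SideHit &best, int len, int contig, int strand,
                            long lo, long hi) {
  if (len > best.len) {
    best.len = len; best.contig = contig; best.strand = strand;
    best.lo = lo; best.hi = hi; best.nhit = 1;
  } else if (len == best.len && len > 0) {
    best.nhit++;
    if (lower_placement(contig, lo, strand, best.contig, best.lo, best.strand)) {
      best.contig = contig; best.strand = strand; best.lo = lo; best.hi = hi;
    }
  }
}

typedef std::unordered_map<uint64_t, std::vector<uint64_t> > KmerIndex;

static bool encode_kmer(const char *s, int k, uint64_t &out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t) b;
  }
  out = v;
  return true;
}

static bool encode_kmer_rc(const char *s, int k, uint64_t &out) {
  uint64_t v = 0;
  for (int i = k - 1; i >= 0; --i) {
    int b = base2bits(s[i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t) (3 - b);
  }
  out = v;
  return true;
}

static void build_index(const std::vector<std::string> &refs, int k,
                        KmerIndex &idx) {
  for (size_t c = 0; c < refs.size(); ++c) {
    const std::string &R = refs[c];
    if ((long) R.size() < k) continue;
    uint64_t v = 0;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int valid = 0;
    for (long i = 0; i < (long) R.size(); ++i) {
      int b = base2bits(R[(size_t)i]);
      if (b < 0) { valid = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t) b) & mask;
      if (++valid >= k) {
        long pos = i - k + 1;
        idx[v].push_back(((uint64_t) c << 40) | (uint64_t) pos);
      }
    }
  }
}

// maximal exact prefix match of `read`, both strands
static SideHit prefix_match(const std::string &read, int k,
                            const std::vector<std::string> &refs,
                            const KmerIndex &idx) {
  SideHit best;
  const long L = (long) read.size();
  uint64_t fwd, rc;
  // plus strand: read[0..k) occurs at ref[pos..pos+k), extend rightward
  if (encode_kmer(read.c_str(), k, fwd)) {
    KmerIndex::const_iterator it = idx.find(fwd);
    if (it != idx.end()) {
      for (size_t h = 0; h < it->second.size(); ++h) {
        int c = (int) (it->second[h] >> 40);
        long pos = (long) (it->second[h] & ((1ULL << 40) - 1));
        const std::string &R = refs[(size_t)c];
        long i = k;
        while (i < L && pos + i < (long) R.size() &&
               read[(size_t)i] == R[(size_t)(pos + i)] &&
               base2bits(read[(size_t)i]) >= 0) ++i;
        consider(best, (int) i, c, +1, pos, pos + i);
      }
    }
  }
  // minus strand: revcomp(read[0..k)) occurs at ref[pos..pos+k);
  // read[i] pairs with ref[pos + k - 1 - i], extension walks leftward
  if (encode_kmer_rc(read.c_str(), k, rc)) {
    KmerIndex::const_iterator it = idx.find(rc);
    if (it != idx.end()) {
      for (size_t h = 0; h < it->second.size(); ++h) {
        int c = (int) (it->second[h] >> 40);
        long pos = (long) (it->second[h] & ((1ULL << 40) - 1));
        const std::string &R = refs[(size_t)c];
        long i = k;
        while (i < L && pos + k - 1 - i >= 0 &&
               comp_match(read[(size_t)i], R[(size_t)(pos + k - 1 - i)])) ++i;
        consider(best, (int) i, c, -1, pos + k - i, pos + k);
      }
    }
  }
  return best;
}

// maximal exact suffix match of `read`, both strands
static SideHit suffix_match(const std::string &read, int k,
                            const std::vector<std::string> &refs,
                            const KmerIndex &idx) {
  SideHit best;
  const long L = (long) read.size();
  const char *tail = read.c_str() + (L - k);
  uint64_t fwd, rc;
  // plus strand: read[L-k..L) at ref[pos..pos+k), extend leftward
  if (encode_kmer(tail, k, fwd)) {
    KmerIndex::const_iterator it = idx.find(fwd);
    if (it != idx.end()) {
      for (size_t h = 0; h < it->second.size(); ++h) {
        int c = (int) (it->second[h] >> 40);
        long pos = (long) (it->second[h] & ((1ULL << 40) - 1));
        const std::string &R = refs[(size_t)c];
        long j = 0;
        while (L - k - 1 - j >= 0 && pos - 1 - j >= 0 &&
               read[(size_t)(L - k - 1 - j)] == R[(size_t)(pos - 1 - j)] &&
               base2bits(read[(size_t)(L - k - 1 - j)]) >= 0) ++j;
        consider(best, (int) (k + j), c, +1, pos - j, pos + k);
      }
    }
  }
  // minus strand: revcomp(read[L-k..L)) at ref[pos..pos+k);
  // read[L-1-j] pairs with ref[pos + j], extension walks rightward in ref
  if (encode_kmer_rc(tail, k, rc)) {
    KmerIndex::const_iterator it = idx.find(rc);
    if (it != idx.end()) {
      for (size_t h = 0; h < it->second.size(); ++h) {
        int c = (int) (it->second[h] >> 40);
        long pos = (long) (it->second[h] & ((1ULL << 40) - 1));
        const std::string &R = refs[(size_t)c];
        long j = k;
        while (L - 1 - j >= 0 && pos + j < (long) R.size() &&
               comp_match(read[(size_t)(L - 1 - j)], R[(size_t)(pos + j)])) ++j;
        consider(best, (int) j, c, -1, pos, pos + j);
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector ref, int k) {
  const int nr = reads.size();
  std::vector<std::string> refs(ref.size());
  for (int i = 0; i < ref.size(); ++i) refs[(size_t)i] = as<std::string>(ref[i]);

  KmerIndex idx;
  build_index(refs, k, idx);

  IntegerVector p_len(nr), p_contig(nr), p_strand(nr), p_nhit(nr);
  NumericVector p_lo(nr), p_hi(nr);
  IntegerVector s_len(nr), s_contig(nr), s_strand(nr), s_nhit(nr);
  NumericVector s_lo(nr), s_hi(nr);

  for (int i = 0; i < nr; ++i) {
    std::string rd = as<std::string>(reads[i]);
    if ((int) rd.size() < k)
      stop("read shorter than k");
    SideHit P = prefix_match(rd, k, refs, idx);
    SideHit S = suffix_match(rd, k, refs, idx);
    p_len[i] = P.len; p_nhit[i] = P.nhit;
    if (P.len > 0) {
      p_contig[i] = P.contig + 1; p_strand[i] = P.strand;
      p_lo[i] = (double) P.lo; p_hi[i] = (double) P.hi;
    } else {
      p_contig[i] = NA_INTEGER; p_strand[i] = NA_INTEGER;
      p_lo[i] = NA_REAL; p_hi[i] = NA_REAL;
    }
    s_len[i] = S.len; s_nhit[i] = S.nhit;
    if (S.len > 0) {
      s_contig[i] = S.contig + 1; s_strand[i] = S.strand;
      s_lo[i] = (double) S.lo; s_hi[i] = (double) S.hi;
    } else {
      s_contig[i] = NA_INTEGER; s_strand[i] = NA_INTEGER;
      s_lo[i] = NA_REAL; s_hi[i] = NA_REAL;
    }
  }

  return List::create(
    _["p_len"] = p_len, _["p_contig"] = p_contig, _["p_strand"] = p_strand,
    _["p_lo"] = p_lo, _["p_hi"] = p_hi, _["p_nhit"] = p_nhit,
    _["s_len"] = s_len, _["s_contig"] = s_contig, _["s_strand"] = s_strand,
    _["s_lo"] = s_lo, _["s_hi"] = s_hi, _["s_nhit"] = s_nhit);
}
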