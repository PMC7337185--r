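#include <Rcpp.h>
using namespace Rcpp;

// End-to-end (ungapped, full-length) read matching against a set of reference
// sequences, both strands, with a mismatch cap. Naive scan with early exit;
// adequate at the scales this package targets and exactly checkable against a
// brute-force R oracle.

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
  return r;
}

// Count mismatches between read and ref starting at pos; bail out once count
// exceeds cap. 'N' never matches.
static inline int mm_count(const std::string& read, const std::string& ref,
                           size_t pos, int cap) {
  int mm = 0;
  for (size_t i = 0; i < read.size(); ++i) {
    char a = read[i], b = ref[pos + i];
    if (a != b || a == 'N') {
      if (++mm > cap) return mm;
    }
  }
  return mm;
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

// k-mer index over the forward reference set: kmer -> packed (ref, pos).
struct KmerIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<uint64_t>> map;
  void build(const std::vector<std::string>& refs, int k_) {
    k = k_;
    for (size_t r = 0; r < refs.size(); ++r) {
      const std::string& s = refs[r];
      if ((int)s.size() < k) continue;
      uint64_t code = 0, mask = (1ULL << (2 * k)) - 1;
      int valid = 0;
      for (size_t p = 0; p < s.size(); ++p) {
        int b = base2bits(s[p]);
        if (b < 0) { valid = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t)b) & mask;
        if (++valid >= k) {
          map[code].push_back(((uint64_t)r << 32) | (p - k + 1));
        }
      }
    }
  }
};

struct Hit { int ref, start, mm, strand; };

// [[Rcpp::export]]
DataFrame match_reads_cpp(CharacterVector reads, CharacterVector refs,
                          int max_mismatch, bool best_stratum_only) {
  int n_reads = reads.size(), n_refs = refs.size();
  std::vector<std::string> ref_seq(n_refs);
  for (int r = 0; r < n_refs; ++r) ref_seq[r] = as<std::string>(refs[r]);

  // Pigeonhole seeding: with max_mismatch mismatches, one of max_mismatch+1
  // disjoint seed chunks is exact. Worth it only when seeds are long enough
  // to be selective; otherwise scan naively.
  size_t min_len = SIZE_MAX;
  for (int i = 0; i < n_reads; ++i) {
    size_t l = strlen(CHAR(STRING_ELT(reads, i)));
    if (l < min_len) min_len = l;
  }
  int n_chunks = max_mismatch + 1;
  int seed_k = (n_reads == 0) ? 0 : (int)(min_len / n_chunks);
  bool use_index = n_reads > 0 && seed_k >= 10;
  KmerIndex index;
  if (use_index) {
    if (seed_k > 31) seed_k = 31;
    index.build(ref_seq, seed_k);
  }

  std::vector<int> out_read, out_ref, out_start, out_mm, out_strand;

  for (int i = 0; i < n_reads; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    std::string rev = revcomp(fwd);
    int best = max_mismatch;
    std::vector<Hit> hits;

    for (int strand = 1; strand >= 0; --strand) {
      const std::string& rd = strand ? fwd : rev;
      if (use_index) {
        for (int ci = 0; ci < n_chunks; ++ci) {
          size_t off = (size_t)ci * seed_k;
          uint64_t code = 0;
          bool ok = true;
          for (int j = 0; j < seed_k; ++j) {
            int b = base2bits(rd[off + j]);
            if (b < 0) { ok = false; break; }
            code = (code << 2) | (uint64_t)b;
          }
          if (!ok) continue;
          auto it = index.map.find(code);
          if (it == index.map.end()) continue;
          for (uint64_t packed : it->second) {
            int r = (int)(packed >> 32);
            long pos = (long)(packed & 0xffffffffULL) - (long)off;
            const std::string& rf = ref_seq[r];
            if (pos < 0 || pos + rd.size() > rf.size()) continue;
            bool seen = false;  // same placement reachable via several seeds
            for (const Hit& h : hits) {
              if (h.ref == r + 1 && h.start == (int)pos &&
                  h.strand == strand) { seen = true; break; }
            }
            if (seen) continue;
            int cap = best_stratum_only ? best : max_mismatch;
            int mm = mm_count(rd, rf, (size_t)pos, cap);
            if (mm <= cap) {
              if (best_stratum_only && mm < best) best = mm;
              hits.push_back({r + 1, (int)pos, mm, strand});
            }
          }
        }
      } else {
        for (int r = 0; r < n_refs; ++r) {
          const std::string& rf = ref_seq[r];
          if (rd.size() > rf.size()) continue;
          size_t last = rf.size() - rd.size();
          for (size_t pos = 0; pos <= last; ++pos) {
            int cap = best_stratum_only ? best : max_mismatch;
            int mm = mm_count(rd, rf, pos, cap);
            if (mm <= cap) {
              if (best_stratum_only && mm < best) best = mm;
              hits.push_back({r + 1, (int)pos, mm, strand});
            }
          }
        }
      }
    }
    for (const Hit& h : hits) {
      if (best_stratum_only && h.mm != best) continue;
      out_read.push_back(i + 1);
      out_ref.push_back(h.ref);
      out_start.push_back(h.start);
      out_mm.push_back(h.mm);
      out_strand.push_back(h.strand);
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }

  int n = out_read.size();
  CharacterVector strand_chr(n);
  for (int k = 0; k < n; ++k) strand_chr[k] = out_strand[k] ? "+" : "-";
  return DataFrame::create(
    _["read"] = wrap(out_read), _["ref"] = wrap(out_ref),
    _["start"] = wrap(out_start), _["strand"] = strand_chr,
    _["mismatches"] = wrap(out_mm), _["stringsAsFactors"] = false);
}

// Best ungapped placement of a (possibly truncated) copy along its consensus:
// returns c(best 0-based offset, mismatch count at that offset). Leftmost
// offset wins ties.
// [[Rcpp::export]]
IntegerVector best_offset_cpp(std::string copy, std::string cons) {
  if (copy.size() > cons.size())
    stop("copy is longer than the consensus");
  size_t last = cons.size() - copy.size();
  int best_mm = (int)copy.size() + 1, best_pos = 0;
  for (size_t pos = 0; pos <= last; ++pos) {
    int mm = mm_count(copy, cons, pos, best_mm - 1);
    if (mm < best_mm) { best_mm = mm; best_pos = (int)pos; }
    if (best_mm == 0) break;
  }
  return IntegerVector::create(best_pos, best_mm);
}
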