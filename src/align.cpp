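#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Ungapped alignment of short reads against a single repeat-genome sequence.
// Semantics: a read maps iff some offset (forward or reverse-complement
// orientation) has <= max_mismatches mismatches, where any N in read or
// reference counts as a mismatch. Best hit = minimal mismatch count, ties by
// smaller offset, then forward orientation.

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = comp(c);
  return r;
}

// mismatches between pattern and ref at offset, early-abandon above cap
static inline int mm_at(const std::string& ref, const std::string& pat,
                        size_t off, int cap) {
  int mm = 0;
  const size_t l = pat.size();
  for (size_t i = 0; i < l; ++i) {
    char a = pat[i], b = ref[off + i];
    if (a != b || a == 'N') {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

struct Hit {
  bool mapped = false;
  int offset = NA_INTEGER;
  int mismatches = NA_INTEGER;
  bool forward = true;
};

// candidate better than current best? order: mm, offset, forward-first
static inline bool better(const Hit& cand, const Hit& best) {
  if (!best.mapped) return true;
  if (cand.mismatches != best.mismatches)
    return cand.mismatches < best.mismatches;
  if (cand.offset != best.offset) return cand.offset < best.offset;
  return cand.forward && !best.forward;
}

static Hit align_scan(const std::string& ref, const std::string& fwd,
                      const std::string& rev, int max_mm) {
  Hit best;
  const size_t L = ref.size(), l = fwd.size();
  if (l > L) return best;
  for (size_t off = 0; off + l <= L; ++off) {
    int cap = best.mapped ? best.mismatches : max_mm;
    int m = mm_at(ref, fwd, off, cap);
    if (m <= cap) {
      Hit h; h.mapped = true; h.offset = (int)off; h.mismatches = m;
      h.forward = true;
      if (better(h, best)) best = h;
    }
    cap = best.mapped ? best.mismatches : max_mm;
    m = mm_at(ref, rev, off, cap);
    if (m <= cap) {
      Hit h; h.mapped = true; h.offset = (int)off; h.mismatches = m;
      h.forward = false;
      if (better(h, best)) best = h;
    }
  }
  if (best.mapped && best.mismatches > max_mm) best.mapped = false;
  return best;
}

// --- seeded exact search ---------------------------------------------------
// Pigeonhole: split the read into (max_mm + 1) non-overlapping chunks and
// take one seed k-mer from the start of each chunk. Any alignment with
// <= max_mm mismatches leaves at least one chunk mismatch-free, so its seed
// matches the reference exactly and is found in the k-mer index. Seeds or
// reference k-mers containing N can never participate in an exact match and
// are handled by exclusion (reads containing N fall back to the full scan in
// the R wrapper).

struct SeedIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<int>> pos;
};

static inline int base2bits(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1;
  case 'G': return 2; case 'T': return 3;
  default: return -1;
  }
}

static bool encode_kmer(const std::string& s, size_t at, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[at + i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

static SeedIndex build_index(const std::string& ref, int k) {
  SeedIndex idx;
  idx.k = k;
  if ((int)ref.size() < k) return idx;
  for (size_t i = 0; i + k <= ref.size(); ++i) {
    uint64_t v;
    if (encode_kmer(ref, i, k, v)) idx.pos[v].push_back((int)i);
  }
  return idx;
}

static void seed_candidates(const SeedIndex& idx, const std::string& pat,
                            int max_mm, size_t ref_len,
                            std::vector<int>& cand) {
  const int l = (int)pat.size();
  const int nseed = max_mm + 1;
  const int chunk = l / nseed;
  for (int s = 0; s < nseed; ++s) {
    int at = s * chunk;
    uint64_t v;
    if (!encode_kmer(pat, at, idx.k, v)) continue;
    auto it = idx.pos.find(v);
    if (it == idx.pos.end()) continue;
    for (int p : it->second) {
      int off = p - at;
      if (off >= 0 && (size_t)(off + l) <= ref_len) cand.push_back(off);
    }
  }
}

static Hit align_seeded(const std::string& ref, const SeedIndex& idx,
                        const std::string& fwd, const std::string& rev,
                        int max_mm) {
  Hit best;
  std::vector<int> cand;
  for (int ori = 0; ori < 2; ++ori) {
    const std::string& pat = ori == 0 ? fwd : rev;
    cand.clear();
    seed_candidates(idx, pat, max_mm, ref.size(), cand);
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    for (int off : cand) {
      int m = mm_at(ref, pat, (size_t)off, max_mm);
      if (m <= max_mm) {
        Hit h; h.mapped = true; h.offset = off; h.mismatches = m;
        h.forward = (ori == 0);
        if (better(h, best)) best = h;
      }
    }
  }
  return best;
}

// [[Rcpp::export(name = ".cpp_align_reads")]]
DataFrame cpp_align_reads(CharacterVector reads, std::string ref,
                          int max_mismatches, bool use_seed, int min_seed_len) {
  const int n = reads.size();
  LogicalVector mapped(n);
  IntegerVector offset(n), mism(n);
  CharacterVector strand(n);
  SeedIndex idx;
  int indexed_k = -1;
  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    std::string rev = revcomp(fwd);
    const int l = (int)fwd.size();
    bool has_n = fwd.find('N') != std::string::npos;
    int k = l / (max_mismatches + 1);
    if (k > 31) k = 31;
    Hit h;
    if (use_seed && !has_n && k >= min_seed_len) {
      if (k != indexed_k) { idx = build_index(ref, k); indexed_k = k; }
      h = align_seeded(ref, idx, fwd, rev, max_mismatches);
    } else {
      h = align_scan(ref, fwd, rev, max_mismatches);
    }
    mapped[i] = h.mapped;
    offset[i] = h.mapped ? h.offset : NA_INTEGER;
    mism[i] = h.mapped ? h.mismatches : NA_INTEGER;
    if (h.mapped) strand[i] = h.forward ? "+" : "-";
    else strand[i] = NA_STRING;
  }
  return DataFrame::create(_["mapped"] = mapped, _["offset"] = offset,
                           _["strand"] = strand, _["mismatches"] = mism,
                           _["stringsAsFactors"] = false);
}

// --- 8-connected component labeling ---------------------------------------

// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(LogicalMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int,int>> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!img(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.emplace_back(i, j);
      lab(i, j) = next;
      while (!stack.empty()) {
        auto [r, c] = stack.back();
        stack.pop_back();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (!dr && !dc) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (img(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.emplace_back(rr, cc);
            }
          }
        }
      }
    }
  }
  return lab;
}

// --- read assembly for the simulator ---------------------------------------
// Builds read strings from a genome, 0-based start positions, strands and a
// sparse list of substitution errors. err_read/err_pos are 0-based; err_sub
// in 1..3 picks the substituted base by cycling the alphabet, which
// guarantees the base actually changes.

// [[Rcpp::export(name = ".cpp_make_reads")]]
CharacterVector cpp_make_reads(std::string genome, IntegerVector starts,
                               LogicalVector minus, int read_length,
                               IntegerVector err_read, IntegerVector err_pos,
                               IntegerVector err_sub) {
  const int n = starts.size();
  static const char* bases = "ACGT";
  std::vector<std::string> out(n);
  for (int i = 0; i < n; ++i)
    out[i] = genome.substr(starts[i], read_length);
  for (int e = 0; e < err_read.size(); ++e) {
    std::string& r = out[err_read[e]];
    char& c = r[err_pos[e]];
    int b = base2bits(c);
    if (b < 0) continue;  // leave N untouched
    c = bases[(b + err_sub[e]) & 3];
  }
  CharacterVector res(n);
  for (int i = 0; i < n; ++i)
    res[i] = minus[i] ? revcomp(out[i]) : out[i];
  return res;
}
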