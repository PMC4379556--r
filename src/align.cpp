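#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit base codes; anything outside ACGT (incl. N) is 4 and never matches,
// so N counts as a mismatch even against N.
static inline uint8_t enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

struct CatIndex {
  std::vector<std::vector<uint8_t> > seqs;   // forward strand, encoded
  int seed_len;
  std::unordered_multimap<uint64_t, uint64_t> kmers; // key -> (elem<<32)|pos
};

static void encode_str(const std::string& s, std::vector<uint8_t>& out) {
  out.resize(s.size());
  for (size_t i = 0; i < s.size(); ++i) out[i] = enc(s[i]);
}

static void revcomp_enc(const std::vector<uint8_t>& q, std::vector<uint8_t>& out) {
  size_t n = q.size();
  out.resize(n);
  for (size_t i = 0; i < n; ++i) {
    uint8_t b = q[n - 1 - i];
    out[i] = (b <= 3) ? (uint8_t)(3 - b) : (uint8_t)4;
  }
}

static void finalize_index(CatIndex* idx) {
  int k = idx->seed_len;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t e = 0; e < idx->seqs.size(); ++e) {
    const std::vector<uint8_t>& v = idx->seqs[e];
    int n = (int)v.size();
    if (n < k) continue;
    uint64_t key = 0;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      if (v[i] > 3) { valid = 0; key = 0; continue; }
      key = ((key << 2) | v[i]) & mask;
      if (++valid >= k) {
        int pos = i - k + 1;
        idx->kmers.insert(std::make_pair(key, ((uint64_t)e << 32) | (uint64_t)pos));
      }
    }
  }
}

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector seqs, int seed_len) {
  if (seed_len < 12 || seed_len > 31) stop("seed_len must be in [12, 31]");
  CatIndex* idx = new CatIndex();
  idx->seed_len = seed_len;
  idx->seqs.resize(seqs.size());
  for (int e = 0; e < seqs.size(); ++e) {
    std::string s = as<std::string>(seqs[e]);
    encode_str(s, idx->seqs[e]);
  }
  finalize_index(idx);
  XPtr<CatIndex> p(idx, true);
  return p;
}

struct Hit { int elem; int pos; int mm; };

// Pigeonhole seeded search: p = max_mm + 1 disjoint seeds; if the read has
// <= max_mm mismatching positions, at least one seed is exact. Candidate
// diagonals are then verified ungapped over the full read.
static void find_hits(const CatIndex& idx, const std::vector<uint8_t>& q,
                      int max_mm, std::vector<Hit>& out) {
  int L = (int)q.size();
  int k = idx.seed_len;
  int p = max_mm + 1;
  if (k > L / p)
    stop("seed length %d too long for read length %d with mismatch budget %d",
         k, L, max_mm);
  std::unordered_map<uint64_t, char> seen;
  int step = L / p;
  for (int s = 0; s < p; ++s) {
    int off = s * step;
    uint64_t key = 0;
    bool ok = true;
    for (int i = 0; i < k; ++i) {
      uint8_t b = q[off + i];
      if (b > 3) { ok = false; break; }
      key = (key << 2) | b;
    }
    if (!ok) continue;   // seed contains N; another seed must be clean
    auto range = idx.kmers.equal_range(key);
    for (auto it = range.first; it != range.second; ++it) {
      int e = (int)(it->second >> 32);
      long pos = (long)(it->second & 0xffffffffULL);
      long start = pos - off;
      const std::vector<uint8_t>& ref = idx.seqs[e];
      if (start < 0 || start + L > (long)ref.size()) continue;
      uint64_t ck = ((uint64_t)e << 32) | (uint64_t)start;
      if (seen.count(ck)) continue;
      seen[ck] = 1;
      int mm = 0;
      const uint8_t* rp = &ref[start];
      for (int i = 0; i < L; ++i) {
        uint8_t a = q[i], b = rp[i];
        if (a > 3 || b > 3 || a != b) { if (++mm > max_mm) break; }
      }
      if (mm <= max_mm) {
        Hit h; h.elem = e; h.pos = (int)start; h.mm = mm;
        out.push_back(h);
      }
    }
  }
}

// All hits for single-end reads on both strands. pos is 1-based leftmost on
// the element's forward strand; strand +1/-1.
// [[Rcpp::export]]
DataFrame cpp_align_single(SEXP xp, CharacterVector reads, int max_mm) {
  XPtr<CatIndex> idx(xp);
  std::vector<int> o_read, o_elem, o_pos, o_strand, o_mm;
  std::vector<uint8_t> q, qrc;
  std::vector<Hit> hits;
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    encode_str(s, q);
    revcomp_enc(q, qrc);
    hits.clear();
    find_hits(*idx, q, max_mm, hits);
    size_t nfwd = hits.size();
    find_hits(*idx, qrc, max_mm, hits);
    for (size_t i = 0; i < hits.size(); ++i) {
      o_read.push_back(r + 1);
      o_elem.push_back(hits[i].elem + 1);
      o_pos.push_back(hits[i].pos + 1);
      o_strand.push_back(i < nfwd ? 1 : -1);
      o_mm.push_back(hits[i].mm);
    }
  }
  return DataFrame::create(_["read"] = o_read, _["elem"] = o_elem,
                           _["pos"] = o_pos, _["strand"] = o_strand,
                           _["mm"] = o_mm);
}

// Concordant paired alignment: same element, opposite strands, FR
// orientation (plus-strand mate leftmost), implied insert within bounds.
// [[Rcpp::export]]
DataFrame cpp_align_pairs(SEXP xp, CharacterVector reads1, CharacterVector reads2,
                          int max_mm, int insert_min, int insert_max) {
  XPtr<CatIndex> idx(xp);
  if (reads1.size() != reads2.size()) stop("mate vectors differ in length");
  std::vector<int> o_read, o_elem, o_pos1, o_strand1, o_pos2, o_mm1, o_mm2;
  std::vector<uint8_t> q1, q1rc, q2, q2rc;
  std::vector<Hit> h1, h2;
  std::vector<int> st1, st2;
  for (int r = 0; r < reads1.size(); ++r) {
    std::string s1 = as<std::string>(reads1[r]);
    std::string s2 = as<std::string>(reads2[r]);
    int L1 = (int)s1.size(), L2 = (int)s2.size();
    encode_str(s1, q1); revcomp_enc(q1, q1rc);
    encode_str(s2, q2); revcomp_enc(q2, q2rc);
    h1.clear(); st1.clear();
    find_hits(*idx, q1, max_mm, h1);
    size_t n = h1.size();
    find_hits(*idx, q1rc, max_mm, h1);
    st1.assign(h1.size(), -1);
    for (size_t i = 0; i < n; ++i) st1[i] = 1;
    h2.clear(); st2.clear();
    find_hits(*idx, q2, max_mm, h2);
    n = h2.size();
    find_hits(*idx, q2rc, max_mm, h2);
    st2.assign(h2.size(), -1);
    for (size_t i = 0; i < n; ++i) st2[i] = 1;
    for (size_t i = 0; i < h1.size(); ++i) {
      for (size_t j = 0; j < h2.size(); ++j) {
        if (h1[i].elem != h2[j].elem) continue;
        if (st1[i] == st2[j]) continue;
        int plus_start, minus_start, minus_len;
        if (st1[i] == 1) {
          plus_start = h1[i].pos; minus_start = h2[j].pos; minus_len = L2;
        } else {
          plus_start = h2[j].pos; minus_start = h1[i].pos; minus_len = L1;
        }
        if (plus_start > minus_start) continue;
        int insert = minus_start + minus_len - plus_start;
        if (insert < insert_min || insert > insert_max) continue;
        o_read.push_back(r + 1);
        o_elem.push_back(h1[i].elem + 1);
        o_pos1.push_back(h1[i].pos + 1);
        o_strand1.push_back(st1[i]);
        o_pos2.push_back(h2[j].pos + 1);
        o_mm1.push_back(h1[i].mm);
        o_mm2.push_back(h2[j].mm);
      }
    }
  }
  return DataFrame::create(_["read"] = o_read, _["elem"] = o_elem,
                           _["pos1"] = o_pos1, _["strand1"] = o_strand1,
                           _["pos2"] = o_pos2, _["mm1"] = o_mm1,
                           _["mm2"] = o_mm2);
}

// Best ungapped placement of query on subject's forward strand (leftmost on
// ties). Used for anchor placement in pol-env type classification.
// [[Rcpp::export]]
IntegerVector cpp_best_match(std::string query, std::string subject) {
  std::vector<uint8_t> q, s;
  encode_str(query, q);
  encode_str(subject, s);
  int L = (int)q.size(), n = (int)s.size();
  int best_pos = NA_INTEGER, best_mm = L + 1;
  for (int start = 0; start + L <= n; ++start) {
    int mm = 0;
    for (int i = 0; i < L; ++i) {
      uint8_t a = q[i], b = s[start + i];
      if (a > 3 || b > 3 || a != b) { if (++mm >= best_mm) break; }
    }
    if (mm < best_mm) { best_mm = mm; best_pos = start + 1; }
    if (best_mm == 0) break;
  }
  return IntegerVector::create(best_pos, best_mm == L + 1 ? NA_INTEGER : best_mm);
}

// Sliding-window quality trim: returns kept length per read (truncate at the
// start of the first window whose mean Phred quality drops below threshold).
// [[Rcpp::export]]
IntegerVector cpp_window_trim(CharacterVector quals, int window, double threshold) {
  IntegerVector out(quals.size());
  for (int r = 0; r < quals.size(); ++r) {
    std::string q = as<std::string>(quals[r]);
    int L = (int)q.size();
    int keep = L;
    if (L >= window) {
      int sum = 0;
      for (int i = 0; i < window; ++i) sum += q[i] - 33;
      for (int i = 0; ; ++i) {
        if ((double)sum / window < threshold) { keep = i; break; }
        if (i + window >= L) break;
        sum += (q[i + window] - 33) - (q[i] - 33);
      }
    }
    out[r] = keep;
  }
  return out;
}
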