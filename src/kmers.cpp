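#include <Rcpp.h>
#include <functional>
#include <unordered_set>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int b2i(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}
static const char I2B[4] = {'A', 'C', 'G', 'T'};

// canonical = lexicographic min of forward and reverse complement; under
// 2-bit A<C<G<T encoding numeric order equals lexicographic order
static inline uint64_t revcomp_code(uint64_t h, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (h & 3ULL));
    h >>= 2;
  }
  return r;
}

template <typename F>
static void for_each_canon(const std::string& s, int k, F f) {
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t h = 0; int valid = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int b = b2i(s[i]);
    if (b < 0) { valid = 0; h = 0; continue; }  // N breaks k-mers
    h = ((h << 2) | (uint64_t)b) & mask;
    if (++valid >= k) {
      uint64_t rc = revcomp_code(h, k);
      f(h < rc ? h : rc);
    }
  }
}

static std::string decode_kmer(uint64_t h, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = I2B[h & 3ULL]; h >>= 2; }
  return s;
}

// Unique canonical k-mers of a set of sequences, as strings.
// [[Rcpp::export(name = ".canon_kmers_cpp")]]
CharacterVector canon_kmers_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_set<uint64_t> set;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    std::string str = as<std::string>(seqs[s]);
    for_each_canon(str, k, [&](uint64_t h) { set.insert(h); });
  }
  std::vector<uint64_t> v(set.begin(), set.end());
  std::sort(v.begin(), v.end());
  CharacterVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = decode_kmer(v[i], k);
  return out;
}

static std::unordered_set<uint64_t> encode_set(CharacterVector kmers, int k) {
  std::unordered_set<uint64_t> set;
  set.reserve(kmers.size() * 2 + 1);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != k) stop("k-mer of wrong length in set");
    uint64_t h = 0;
    bool ok = true;
    for (char c : s) { int b = b2i(c); if (b < 0) { ok = false; break; } h = (h << 2) | (uint64_t)b; }
    if (!ok) continue;
    uint64_t rc = revcomp_code(h, k);
    set.insert(h < rc ? h : rc);
  }
  return set;
}

// Per-read canonical k-mer hit counts against two hap-mer sets.
// [[Rcpp::export(name = ".count_hapmer_hits_cpp")]]
DataFrame count_hapmer_hits_cpp(CharacterVector reads, CharacterVector setA,
                                CharacterVector setB, int k) {
  std::unordered_set<uint64_t> A = encode_set(setA, k), B = encode_set(setB, k);
  const R_xlen_t n = reads.size();
  IntegerVector ca(n), cb(n), len(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    len[i] = (int)s.size();
    int a = 0, b = 0;
    for_each_canon(s, k, [&](uint64_t h) {
      if (A.count(h)) ++a;
      if (B.count(h)) ++b;
    });
    ca[i] = a; cb[i] = b;
  }
  return DataFrame::create(_["length"] = len, _["countA"] = ca, _["countB"] = cb);
}

// Best ungapped hit of each tag on the target (both strands): seed with exact
// forward k-mers, score each candidate diagonal by the maximum-scoring
// contiguous segment (Kadane), ties broken to the smallest target coordinate.
// Returns the left coordinate of the best-scoring segment.
// [[Rcpp::export(name = ".map_tags_cpp")]]
DataFrame map_tags_cpp(CharacterVector tags, std::string target, int k,
                       int match, int mismatch, int max_seeds_per_tag) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  // target k-mer index: sorted (kmer, pos) pairs, forward strand only;
  // tag reverse complement is scanned instead of the target's minus strand
  std::vector<std::pair<uint64_t, int>> idx;
  idx.reserve(target.size());
  {
    uint64_t h = 0; int valid = 0;
    for (size_t i = 0; i < target.size(); ++i) {
      int b = b2i(target[i]);
      if (b < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++valid >= k) idx.emplace_back(h, (int)(i - k + 1));
    }
  }
  std::sort(idx.begin(), idx.end());

  auto revcomp_str = [](const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (char& c : r) {
      switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      case 'a': c = 't'; break; case 't': c = 'a'; break;
      case 'c': c = 'g'; break; case 'g': c = 'c'; break;
      }
    }
    return r;
  };

  const R_xlen_t n = tags.size();
  std::vector<int> out_idx; std::vector<int> out_pos, out_score;
  std::vector<std::string> out_strand;
  for (R_xlen_t t = 0; t < n; ++t) {
    std::string fwd = as<std::string>(tags[t]);
    int best_score = 0, best_pos = -1;
    std::string best_strand = "+";
    for (int strand = 0; strand < 2; ++strand) {
      std::string tag = strand == 0 ? fwd : revcomp_str(fwd);
      const int m = (int)tag.size();
      if (m < k) continue;
      // candidate alignment offsets (target pos of tag base 0)
      std::unordered_set<int> cands;
      uint64_t h = 0; int valid = 0;
      for (int i = 0; i < m && (int)cands.size() < max_seeds_per_tag; ++i) {
        int b = b2i(tag[(size_t)i]);
        if (b < 0) { valid = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)b) & mask;
        if (++valid >= k) {
          int off = i - k + 1;
          auto lo = std::lower_bound(idx.begin(), idx.end(),
                                     std::make_pair(h, (int)-2147483648LL));
          for (auto it = lo; it != idx.end() && it->first == h; ++it) {
            cands.insert(it->second - off);
            if ((int)cands.size() >= max_seeds_per_tag) break;
          }
        }
      }
      std::vector<int> cv(cands.begin(), cands.end());
      std::sort(cv.begin(), cv.end());
      for (int off : cv) {
        // Kadane along the diagonal, restricted to tag/target overlap
        int i0 = std::max(0, -off);
        int i1 = std::min(m, (int)target.size() - off);
        int cur = 0, cur_start = i0, seg_best = 0, seg_pos = -1;
        for (int i = i0; i < i1; ++i) {
          int s = (tag[(size_t)i] == target[(size_t)(off + i)]) ? match : mismatch;
          if (cur <= 0) { cur = s; cur_start = i; }
          else cur += s;
          if (cur > seg_best) { seg_best = cur; seg_pos = off + cur_start; }
        }
        if (seg_best > best_score ||
            (seg_best == best_score && seg_pos >= 0 &&
             (best_pos < 0 || seg_pos < best_pos))) {
          best_score = seg_best; best_pos = seg_pos;
          best_strand = strand == 0 ? "+" : "-";
        }
      }
    }
    if (best_pos >= 0) {
      out_idx.push_back((int)t + 1);
      out_pos.push_back(best_pos);
      out_score.push_back(best_score);
      out_strand.push_back(best_strand);
    }
  }
  return DataFrame::create(_["tag_index"] = IntegerVector(out_idx.begin(), out_idx.end()),
                           _["t_pos"] = IntegerVector(out_pos.begin(), out_pos.end()),
                           _["score"] = IntegerVector(out_score.begin(), out_score.end()),
                           _["strand"] = CharacterVector(out_strand.begin(), out_strand.end()),
                           _["stringsAsFactors"] = false);
}

// Single-linkage clustering of equal-length sequences at <= max_mm mismatches.
// [[Rcpp::export(name = ".hamming_cluster_cpp")]]
IntegerVector hamming_cluster_cpp(CharacterVector seqs, int max_mm) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (s[i].size() != s[j].size()) continue;
      int mm = 0; bool ok = true;
      for (size_t p = 0; p < s[i].size(); ++p) {
        if (s[i][p] != s[j][p] && ++mm > max_mm) { ok = false; break; }
      }
      if (ok) {
        int ri = find(i), rj = find(j);
        if (ri != rj) parent[std::max(ri, rj)] = std::min(ri, rj);
      }
    }
  }
  IntegerVector comp(n);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap.emplace(r, ++next); comp[i] = next; }
    else comp[i] = it->second;
  }
  return comp;
}
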