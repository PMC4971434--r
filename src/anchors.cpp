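// Unique k-mer anchoring between a reference genome and query contigs.
// A seed is an anchor iff its canonical k-mer occurs exactly once in the
// whole reference (both strands) and exactly once in the contig.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

struct KmerIndex {
  int k;
  std::vector<std::string> names;
  // canonical kmer -> packed (chrom<<34 | pos<<1 | fwd_is_canonical); -1 = multi
  std::unordered_map<uint64_t, int64_t> map;
};

// enumerate (canonical hash, fwd_is_canonical) over valid windows of s,
// calling f(pos0, canon, fwdIsCanon)
template <typename F>
static void scan_kmers(const std::string& s, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fh = 0, rh = 0;
  int valid = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; fh = rh = 0; continue; }
    fh = ((fh << 2) | (uint64_t)c) & mask;
    rh = (rh >> 2) | ((uint64_t)(3 - c) << shift);
    if (++valid >= k) {
      bool fwd = fh <= rh;
      f((long)(i + 1 - k), fwd ? fh : rh, fwd);
    }
  }
}

// [[Rcpp::export]]
SEXP cpp_build_kmer_index(CharacterVector seqs, int k) {
  if (k < 11 || k > 31) stop("k must be in [11, 31]");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  CharacterVector nm = seqs.names();
  for (int ci = 0; ci < seqs.size(); ++ci) {
    idx->names.push_back(as<std::string>(nm[ci]));
    std::string s = as<std::string>(seqs[ci]);
    scan_kmers(s, k, [&](long pos0, uint64_t canon, bool fwd) {
      auto it = idx->map.find(canon);
      if (it == idx->map.end()) {
        idx->map[canon] = ((int64_t)ci << 34) | ((int64_t)pos0 << 1) |
                          (fwd ? 1 : 0);
      } else {
        it->second = -1;  // repeated in reference: not a usable seed
      }
    });
  }
  XPtr<KmerIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
List cpp_find_anchors(SEXP idx_ptr, std::string contig) {
  XPtr<KmerIndex> idx(idx_ptr);
  const int k = idx->k;
  // first pass: contig-internal canonical k-mer counts
  std::unordered_map<uint64_t, int> ccount;
  scan_kmers(contig, k, [&](long, uint64_t canon, bool) { ccount[canon]++; });
  std::vector<int> chrom_i, ref_pos, ctg_pos, strand;
  scan_kmers(contig, k, [&](long pos0, uint64_t canon, bool fwd) {
    auto it = idx->map.find(canon);
    if (it == idx->map.end() || it->second < 0) return;
    if (ccount[canon] != 1) return;
    int64_t v = it->second;
    bool ref_fwd = v & 1;
    chrom_i.push_back((int)(v >> 34) + 1);
    ref_pos.push_back((int)((v >> 1) & ((1LL << 33) - 1)) + 1);
    ctg_pos.push_back((int)pos0 + 1);
    strand.push_back(fwd == ref_fwd ? 1 : -1);
  });
  return List::create(_["chrom_idx"] = wrap(chrom_i),
                      _["ref_pos"] = wrap(ref_pos),
                      _["contig_pos"] = wrap(ctg_pos),
                      _["strand"] = wrap(strand));
}

// [[Rcpp::export]]
CharacterVector cpp_index_chroms(SEXP idx_ptr) {
  XPtr<KmerIndex> idx(idx_ptr);
  return wrap(idx->names);
}

// [[Rcpp::export]]
int cpp_index_k(SEXP idx_ptr) {
  XPtr<KmerIndex> idx(idx_ptr);
  return idx->k;
}
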