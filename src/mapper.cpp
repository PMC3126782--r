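// Mismatch-tolerant seed-and-verify read mapper over a gene-condensed
// transcriptome.  Exactness rests on the pigeonhole principle: a read is
// split into (max_mismatches + 1) non-overlapping exact seeds of length k;
// any placement with <= max_mismatches mismatches leaves at least one seed
// error-free (an 'N' counts as a mismatch at every position, so seeds
// containing non-ACGT characters can be skipped without losing placements).
// Verification of reads up to 32 nt uses 2-bit-packed XOR + popcount (one
// word per read); longer reads fall back to a per-character scan.
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

static const uint64_t PAIR_LO = 0x5555555555555555ULL;

struct PackedSeq {
  // 2 bits per base, little-endian within words; one zero guard word
  std::vector<uint64_t> code;
  std::vector<uint64_t> bad;   // 11 in the 2-bit slot of every non-ACGT base
  int len;
};

static inline uint64_t get_bits(const std::vector<uint64_t>& v, long bitpos) {
  long w = bitpos >> 6; int off = (int)(bitpos & 63);
  uint64_t lo = v[w] >> off;
  if (off) lo |= v[w + 1] << (64 - off);
  return lo;
}

static void pack_seq(const std::string& s, PackedSeq& p) {
  p.len = (int)s.size();
  size_t nw = ((size_t)p.len * 2 + 63) / 64 + 1;
  p.code.assign(nw, 0ULL);
  p.bad.assign(nw, 0ULL);
  for (int i = 0; i < p.len; ++i) {
    long b = 2L * i;
    int c = base_code(s[i]);
    if (c < 0) p.bad[b >> 6] |= 3ULL << (b & 63);
    else p.code[b >> 6] |= (uint64_t)c << (b & 63);
    if ((b & 63) > 62) { /* unreachable: pairs are 2-aligned */ }
  }
}

struct SeqIndex {
  std::vector<std::string> seqs;     // isoform sequences
  std::vector<PackedSeq> packed;
  std::vector<int> gene;             // 0-based gene index per isoform
  int k;
  int n_genes;
  long n_seed_positions;
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> seeds;
};

// [[Rcpp::export(name = ".cs_build_index")]]
SEXP cs_build_index(CharacterVector seqs, IntegerVector gene, int k,
                    int n_genes) {
  if (seqs.size() == 0) stop("empty transcriptome");
  if (k < 1 || k > 31) stop("seed length must be in 1..31");
  SeqIndex* idx = new SeqIndex();
  idx->k = k;
  idx->n_genes = n_genes;
  idx->n_seed_positions = 0;
  idx->seqs.reserve(seqs.size());
  idx->packed.resize(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    idx->seqs.push_back(as<std::string>(seqs[i]));
    idx->gene.push_back(gene[i] - 1);
    pack_seq(idx->seqs.back(), idx->packed[i]);
  }
  for (size_t s = 0; s < idx->seqs.size(); ++s) {
    const std::string& t = idx->seqs[s];
    int L = (int)t.size();
    for (int p = 0; p + k <= L; ++p) {
      uint64_t key = 0;
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        int c = base_code(t[p + j]);
        if (c < 0) { ok = false; break; }
        key = (key << 2) | (uint64_t)c;
      }
      if (!ok) continue;
      idx->seeds[key].push_back(std::make_pair((int)s, p));
      idx->n_seed_positions++;
    }
  }
  XPtr<SeqIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".cs_index_stats")]]
List cs_index_stats(SEXP xp) {
  XPtr<SeqIndex> idx(xp);
  return List::create(_["n_isoforms"] = (int)idx->seqs.size(),
                      _["seed_length"] = idx->k,
                      _["n_seed_positions"] = (double)idx->n_seed_positions);
}

struct Hit { int iso, start, strand, mm; };

static void search_strand(const SeqIndex* idx, const std::string& q,
                          int max_mm, int strand, std::vector<Hit>& hits) {
  int k = idx->k, L = (int)q.size();
  int nseeds = max_mm + 1;
  bool fast = (L <= 32);
  uint64_t rk = 0, rbad = 0, lenmask = 0;
  if (fast) {
    for (int i = 0; i < L; ++i) {
      int c = base_code(q[i]);
      if (c < 0) rbad |= 3ULL << (2 * i);
      else rk |= (uint64_t)c << (2 * i);
    }
    lenmask = (2 * L == 64) ? ~0ULL : ((1ULL << (2 * L)) - 1);
  }
  for (int j = 0; j < nseeds; ++j) {
    int off = j * k;
    if (off + k > L) break;
    uint64_t key = 0; bool ok = true;
    for (int m = 0; m < k; ++m) {
      int c = base_code(q[off + m]);
      if (c < 0) { ok = false; break; }
      key = (key << 2) | (uint64_t)c;
    }
    if (!ok) continue;
    auto it = idx->seeds.find(key);
    if (it == idx->seeds.end()) continue;
    for (auto& pr : it->second) {
      int iso = pr.first;
      int start = pr.second - off;
      if (start < 0) continue;
      if (start + L > (int)idx->seqs[iso].size()) continue;
      bool dup = false;   // same placement reachable through several seeds
      for (auto& h : hits)
        if (h.strand == strand && h.iso == iso && h.start == start) { dup = true; break; }
      if (dup) continue;
      int mm;
      if (fast) {
        const PackedSeq& p = idx->packed[iso];
        long b = 2L * start;
        uint64_t tk = get_bits(p.code, b);
        uint64_t tbad = get_bits(p.bad, b);
        uint64_t diff = ((rk ^ tk) | rbad | tbad) & lenmask;
        mm = __builtin_popcountll((diff | (diff >> 1)) & PAIR_LO);
      } else {
        const std::string& t = idx->seqs[iso];
        mm = 0;
        for (int m = 0; m < L; ++m) {
          int ca = base_code(q[m]), cb = base_code(t[start + m]);
          if (ca < 0 || cb < 0 || ca != cb) { if (++mm > max_mm) break; }
        }
      }
      if (mm <= max_mm) hits.push_back({iso, start, strand, mm});
    }
  }
}

// [[Rcpp::export(name = ".cs_map_reads")]]
List cs_map_reads(SEXP xp, CharacterVector reads, int max_mm,
                  bool best_stratum, bool detail) {
  XPtr<SeqIndex> idx(xp);
  int n = reads.size();
  std::vector<int> g_read, g_gene, g_mm;                     // per (read, gene)
  std::vector<int> p_read, p_iso, p_start, p_strand, p_mm;   // placements
  std::vector<Hit> hits;
  std::vector<int> gene_min(idx->n_genes, -1);
  std::vector<int> touched;
  int n_mapped = 0;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    hits.clear();
    search_strand(idx, s, max_mm, 0, hits);
    std::string rc(s.rbegin(), s.rend());
    for (auto& ch : rc) ch = comp_base(ch);
    search_strand(idx, rc, max_mm, 1, hits);
    if (hits.empty()) continue;
    int keep_mm = max_mm;
    if (best_stratum) {
      keep_mm = max_mm + 1;
      for (auto& h : hits) if (h.mm < keep_mm) keep_mm = h.mm;
    }
    touched.clear();
    bool any = false;
    for (auto& h : hits) {
      if (h.mm > keep_mm) continue;
      any = true;
      if (detail) {
        p_read.push_back(i + 1); p_iso.push_back(h.iso + 1);
        p_start.push_back(h.start); p_strand.push_back(h.strand);
        p_mm.push_back(h.mm);
      }
      int g = idx->gene[h.iso];
      if (gene_min[g] < 0) { gene_min[g] = h.mm; touched.push_back(g); }
      else if (h.mm < gene_min[g]) gene_min[g] = h.mm;
    }
    if (any) {
      ++n_mapped;
      std::sort(touched.begin(), touched.end());
      for (int g : touched) {
        g_read.push_back(i + 1); g_gene.push_back(g + 1);
        g_mm.push_back(gene_min[g]);
        gene_min[g] = -1;
      }
    }
  }
  List out = List::create(
    _["read"] = wrap(g_read), _["gene"] = wrap(g_gene),
    _["min_mismatches"] = wrap(g_mm), _["n_mapped"] = n_mapped);
  if (detail) {
    out["placements"] = List::create(
      _["read"] = wrap(p_read), _["isoform"] = wrap(p_iso),
      _["start"] = wrap(p_start), _["strand"] = wrap(p_strand),
      _["mismatches"] = wrap(p_mm));
  }
  return out;
}
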