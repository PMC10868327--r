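#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// De Bruijn graph construction from short reads.
// Vertices are (k-1)-mers, edges are maximal unbranched sequences; the heavy
// lifting (k-mer counting and compaction) lives here, everything downstream
// (pruning, subgraphs, path extraction) is plain R on the compacted table.

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_base(c);
  return r;
}

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

struct VertexInfo {
  uint8_t out_mask = 0;  // bit per base A,C,G,T with an outgoing k-mer
  uint8_t in_mask  = 0;
};

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    default:  return 3;
  }
}
static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline int popcount4(uint8_t m) {
  return ((m >> 0) & 1) + ((m >> 1) & 1) + ((m >> 2) & 1) + ((m >> 3) & 1);
}

// [[Rcpp::export(name = ".dbg_build_cpp")]]
List dbg_build_cpp(CharacterVector reads, int k, bool double_stranded) {
  std::unordered_map<std::string, double> counts;
  bool any_kmer = false;

  auto add_read = [&](const std::string &s) {
    int n = (int)s.size();
    if (n < k) return;
    // run-length of valid bases ending at i, to skip windows containing N
    int run = 0;
    for (int i = 0; i < n; ++i) {
      run = valid_base(s[i]) ? run + 1 : 0;
      if (run >= k) {
        counts[s.substr(i - k + 1, k)] += 1.0;
        any_kmer = true;
      }
    }
  };

  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    add_read(s);
    if (double_stranded) add_read(revcomp(s));
  }

  if (reads.size() > 0 && !any_kmer)
    stop("no k-mers extracted");

  // vertex adjacency masks
  std::unordered_map<std::string, VertexInfo> verts;
  verts.reserve(counts.size() * 2);
  for (auto &kv : counts) {
    const std::string &km = kv.first;
    verts[km.substr(0, k - 1)].out_mask |= (1 << base_idx(km[k - 1]));
    verts[km.substr(1)].in_mask        |= (1 << base_idx(km[0]));
  }

  auto is_branch = [&](const std::string &v) {
    const VertexInfo &vi = verts[v];
    return popcount4(vi.out_mask) != 1 || popcount4(vi.in_mask) != 1;
  };

  std::unordered_set<std::string> used;
  used.reserve(counts.size() * 2);
  std::vector<std::string> eseq, efrom, eto;
  std::vector<double> ecov;

  auto walk_from = [&](const std::string &start_kmer) {
    // extend an unbranched path starting with start_kmer
    std::string seq = start_kmer;
    std::string km = start_kmer;
    double sum = counts[km];
    int nk = 1;
    used.insert(km);
    while (true) {
      std::string v = km.substr(1);  // suffix vertex
      if (is_branch(v)) break;
      const VertexInfo &vi = verts[v];
      char b = 'A';
      for (int j = 0; j < 4; ++j)
        if (vi.out_mask & (1 << j)) { b = BASES[j]; break; }
      std::string nxt = v + b;
      if (used.count(nxt)) break;  // guards cycles re-entering
      seq.push_back(b);
      km = nxt;
      used.insert(km);
      sum += counts[km];
      ++nk;
    }
    eseq.push_back(seq);
    efrom.push_back(seq.substr(0, k - 1));
    eto.push_back(seq.substr(seq.size() - (k - 1)));
    ecov.push_back(sum / nk);
  };

  // edges starting at branch vertices
  for (auto &kv : counts) {
    const std::string &km = kv.first;
    if (used.count(km)) continue;
    std::string pre = km.substr(0, k - 1);
    if (is_branch(pre)) walk_from(km);
  }

  // leftover k-mers belong to isolated cycles; start each at its smallest
  // k-mer for determinism
  std::vector<std::string> leftover;
  for (auto &kv : counts)
    if (!used.count(kv.first)) leftover.push_back(kv.first);
  std::sort(leftover.begin(), leftover.end());
  for (auto &km : leftover)
    if (!used.count(km)) walk_from(km);

  return List::create(_["seq"] = wrap(eseq),
                      _["from"] = wrap(efrom),
                      _["to"] = wrap(eto),
                      _["cov"] = wrap(ecov));
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  out.names() = x.names();
  return out;
}
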