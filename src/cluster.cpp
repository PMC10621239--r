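#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path compression
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Single-linkage clustering of SV calls of one (chrom, svtype) group.
// Calls must be sorted by start. Two interval calls link iff
// |start1-start2| <= max_dist AND |end1-end2| <= max_dist AND
// |len1-len2| <= max_size. TRA calls (is_tra) link iff their primary
// breakends are within max_dist and their mate breakends share a chromosome
// (mate_key) and are within max_dist; the size test is skipped.
// Returns 1-based component labels in input order.
// [[Rcpp::export(name = ".cluster_group")]]
IntegerVector cluster_group(NumericVector start, NumericVector end,
                            NumericVector len, IntegerVector mate_key,
                            NumericVector mate_pos, bool is_tra,
                            double max_dist, double max_size) {
  int n = start.size();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n && start[j] - start[i] <= max_dist; ++j) {
      if (is_tra) {
        if (mate_key[i] == mate_key[j] &&
            std::abs(mate_pos[i] - mate_pos[j]) <= max_dist)
          uf_union(parent, i, j);
      } else {
        if (std::abs(end[i] - end[j]) <= max_dist &&
            std::abs(len[i] - len[j]) <= max_size)
          uf_union(parent, i, j);
      }
    }
  }
  IntegerVector lab(n);
  std::map<int, int> relabel;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf_find(parent, i);
    auto it = relabel.find(r);
    if (it == relabel.end()) { relabel[r] = ++next; lab[i] = next; }
    else lab[i] = it->second;
  }
  return lab;
}
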