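#include <Rcpp.h>
using namespace Rcpp;

// B block permutations of 1..N (one per column), drawn with R's RNG.
// blocks: per-cluster 1-based measurement index vectors (contiguous rows);
// groups: per exchangeable group, 1-based cluster indices (clusters within
// a group share a size, and in slope mode also a time vector);
// within: additionally shuffle positions within every cluster (intercept
// mode).
// [[Rcpp::export]]
IntegerMatrix draw_permutations_cpp(List blocks, List groups, bool within,
                                    int N, int B) {
  IntegerMatrix out(N, B);
  int ncl = blocks.size();
  std::vector<std::vector<int>> blk(ncl);
  for (int c = 0; c < ncl; ++c) blk[c] = as<std::vector<int>>(blocks[c]);
  int ng = groups.size();
  std::vector<std::vector<int>> grp(ng);
  for (int g = 0; g < ng; ++g) grp[g] = as<std::vector<int>>(groups[g]);

  std::vector<int> sig;
  for (int b = 0; b < B; ++b) {
    int *col = &out(0, b);
    for (int g = 0; g < ng; ++g) {
      const std::vector<int> &cl = grp[g];
      const int k = (int)cl.size();
      sig.resize(k);
      for (int i = 0; i < k; ++i) sig[i] = i;
      for (int i = k - 1; i > 0; --i) {           // Fisher-Yates
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(sig[i], sig[j]);
      }
      for (int a = 0; a < k; ++a) {
        const std::vector<int> &dst = blk[cl[a] - 1];
        const std::vector<int> &src = blk[cl[sig[a]] - 1];
        for (size_t t = 0; t < dst.size(); ++t) col[dst[t] - 1] = src[t];
      }
    }
    if (within) {
      for (int c = 0; c < ncl; ++c) {
        const std::vector<int> &pos = blk[c];
        const int m = (int)pos.size();
        for (int i = m - 1; i > 0; --i) {
          int j = (int)(unif_rand() * (i + 1));
          if (j > i) j = i;
          std::swap(col[pos[i] - 1], col[pos[j] - 1]);
        }
      }
    }
  }
  return out;
}
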