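#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sparse row structure: indices and values of nonzero entries per row.
struct SparseRows {
  std::vector<std::vector<int>> idx;
  std::vector<std::vector<double>> val;
};

// rows of a dense matrix (N x p)
static SparseRows sparse_rows(const NumericMatrix &C) {
  const int N = C.nrow(), p = C.ncol();
  SparseRows S;
  S.idx.resize(N);
  S.val.resize(N);
  for (int j = 0; j < p; ++j) {
    const double *col = &C(0, j);
    for (int i = 0; i < N; ++i) {
      if (col[i] != 0.0) {
        S.idx[i].push_back(j);
        S.val[i].push_back(col[i]);
      }
    }
  }
  return S;
}

// Binary Jaccard and Bray-Curtis dissimilarities on a count matrix, using
// sorted-index intersection merges (counts are typically very sparse).
// [[Rcpp::export(rng = false)]]
List count_distances_cpp(NumericMatrix C, bool do_jac, bool do_bray) {
  const int N = C.nrow();
  SparseRows S = sparse_rows(C);
  std::vector<double> rowtot(N, 0.0);
  for (int i = 0; i < N; ++i)
    for (size_t t = 0; t < S.val[i].size(); ++t) rowtot[i] += S.val[i][t];

  NumericMatrix Dj(do_jac ? N : 0, do_jac ? N : 0);
  NumericMatrix Db(do_bray ? N : 0, do_bray ? N : 0);
  for (int a = 0; a < N; ++a) {
    const std::vector<int> &ia = S.idx[a];
    const std::vector<double> &va = S.val[a];
    for (int b = a + 1; b < N; ++b) {
      const std::vector<int> &ib = S.idx[b];
      const std::vector<double> &vb = S.val[b];
      size_t u = 0, v = 0;
      int common = 0;
      double summin = 0.0;
      while (u < ia.size() && v < ib.size()) {
        if (ia[u] < ib[v]) ++u;
        else if (ia[u] > ib[v]) ++v;
        else {
          ++common;
          summin += std::min(va[u], vb[v]);
          ++u; ++v;
        }
      }
      if (do_jac) {
        const double uni = (double)(ia.size() + ib.size() - common);
        Dj(a, b) = Dj(b, a) = uni > 0 ? 1.0 - common / uni : 0.0;
      }
      if (do_bray) {
        Db(a, b) = Db(b, a) = 1.0 - 2.0 * summin / (rowtot[a] + rowtot[b]);
      }
    }
  }
  return List::create(_["jaccard"] = Dj, _["bray"] = Db);
}

// UniFrac distances from per-edge cumulative relative abundances
// (Et: edges x measurements). Pairwise sums are decomposed into
// per-measurement totals plus intersection corrections, so each pair costs
// O(common nonzero edges):
//   unweighted: d = (ua + ub - 2c) / (ua + ub - c),  c = sum_both b
//   weighted:   d = (sa + sb - 2 sum_both b min(x,y)) / (sa + sb)
//   generalized: with q = sum b x^theta per measurement,
//     num = qa + qb + sum_both b [S^theta |x-y|/S - x^theta - y^theta]
//     den = qa + qb + sum_both b [S^theta - x^theta - y^theta]
// Edges absent from both measurements never contribute.
// [[Rcpp::export(rng = false)]]
List unifrac_sparse_cpp(NumericMatrix Et, NumericVector blen, double theta,
                        bool do_uw, bool do_gen, bool do_w) {
  const int M = Et.nrow(), N = Et.ncol();
  SparseRows S;
  S.idx.resize(N);
  S.val.resize(N);
  for (int i = 0; i < N; ++i) {
    const double *col = &Et(0, i);
    for (int e = 0; e < M; ++e) {
      if (col[e] != 0.0) {
        S.idx[i].push_back(e);
        S.val[i].push_back(col[e]);
      }
    }
  }
  const double *b = &blen[0];
  auto powt = [theta](double x) {
    if (theta == 0.5) return std::sqrt(x);
    if (theta == 1.0) return x;
    if (theta == 0.0) return 1.0;
    return std::pow(x, theta);
  };
  std::vector<double> usum(N, 0.0), ssum(N, 0.0), qsum(N, 0.0);
  for (int i = 0; i < N; ++i) {
    for (size_t t = 0; t < S.idx[i].size(); ++t) {
      const double bl = b[S.idx[i][t]], x = S.val[i][t];
      usum[i] += bl;
      if (do_w) ssum[i] += bl * x;
      if (do_gen) qsum[i] += bl * powt(x);
    }
  }
  NumericMatrix Duw(do_uw ? N : 0, do_uw ? N : 0);
  NumericMatrix Dg(do_gen ? N : 0, do_gen ? N : 0);
  NumericMatrix Dw(do_w ? N : 0, do_w ? N : 0);
  for (int a = 0; a < N; ++a) {
    const std::vector<int> &ia = S.idx[a];
    const std::vector<double> &va = S.val[a];
    for (int bb = a + 1; bb < N; ++bb) {
      const std::vector<int> &ib = S.idx[bb];
      const std::vector<double> &vb = S.val[bb];
      size_t u = 0, v = 0;
      double c = 0.0, wmin = 0.0, gnum_c = 0.0, gden_c = 0.0;
      while (u < ia.size() && v < ib.size()) {
        if (ia[u] < ib[v]) ++u;
        else if (ia[u] > ib[v]) ++v;
        else {
          const double bl = b[ia[u]], x = va[u], y = vb[v];
          c += bl;
          if (do_w) wmin += bl * std::min(x, y);
          if (do_gen) {
            const double Ssum = x + y;
            const double st = powt(Ssum), xt = powt(x), yt = powt(y);
            gnum_c += bl * (st * std::fabs(x - y) / Ssum - xt - yt);
            gden_c += bl * (st - xt - yt);
          }
          ++u; ++v;
        }
      }
      if (do_uw) {
        const double den = usum[a] + usum[bb] - c;
        Duw(a, bb) = Duw(bb, a) = den > 0 ? (usum[a] + usum[bb] - 2.0 * c) / den : 0.0;
      }
      if (do_w) {
        const double den = ssum[a] + ssum[bb];
        Dw(a, bb) = Dw(bb, a) = den > 0 ? (den - 2.0 * wmin) / den : 0.0;
      }
      if (do_gen) {
        const double den = qsum[a] + qsum[bb] + gden_c;
        const double num = qsum[a] + qsum[bb] + gnum_c;
        Dg(a, bb) = Dg(bb, a) = den > 0 ? num / den : 0.0;
      }
    }
  }
  return List::create(_["unweighted"] = Duw, _["generalized"] = Dg,
                      _["weighted"] = Dw);
}
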