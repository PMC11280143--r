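#include <Rcpp.h>
using namespace Rcpp;

// Grayscale erosion/dilation with an offset (non-flat) structuring element.
// Out-of-image pixels are handled by edge replication so that a ramp stays a
// ramp at the boundary. Offsets and heights describe the structuring function;
// erosion(x) = min_d I(x+d) - h(d), dilation(x) = max_d I(x+d) + h(d).
// [[Rcpp::export]]
NumericMatrix cpp_gray_morph(const NumericMatrix& img,
                             const IntegerVector& dx,
                             const IntegerVector& dy,
                             const NumericVector& h,
                             const bool erode) {
  const int nr = img.nrow(), nc = img.ncol(), m = dx.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double best = erode ? R_PosInf : R_NegInf;
      for (int k = 0; k < m; ++k) {
        int ii = i + dy[k];
        int jj = j + dx[k];
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        double v = erode ? img(ii, jj) - h[k] : img(ii, jj) + h[k];
        if (erode) { if (v < best) best = v; } else { if (v > best) best = v; }
      }
      out(i, j) = best;
    }
  }
  return out;
}

// Column means of a matrix whose rows have each been independently permuted,
// repeated n_shuffles times. Uses R's RNG so results follow set.seed().
// Rows are pairwise-difference traces; columns are AP bins.
// [[Rcpp::export]]
NumericMatrix cpp_row_permuted_means(const NumericMatrix& M, const int n_shuffles) {
  const int p = M.nrow(), b = M.ncol();
  NumericMatrix out(n_shuffles, b);
  std::vector<int> idx(b);
  for (int s = 0; s < n_shuffles; ++s) {
    for (int i = 0; i < p; ++i) {
      for (int j = 0; j < b; ++j) idx[j] = j;
      // Fisher-Yates using R's uniform RNG
      for (int j = b - 1; j > 0; --j) {
        int k = (int)std::floor(unif_rand() * (j + 1));
        if (k > j) k = j;
        std::swap(idx[j], idx[k]);
      }
      for (int j = 0; j < b; ++j) out(s, j) += M(i, idx[j]);
    }
    for (int j = 0; j < b; ++j) out(s, j) /= p;
  }
  return out;
}
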