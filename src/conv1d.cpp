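// Gather/scatter kernels for same-padded one-dimensional convolution.
// The patch ("im2col") matrix has one row per (sample, position) and one
// column per (kernel offset, channel); the scatter is its exact adjoint,
// accumulating gradients back onto the input array (B, L, C).
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(rng = false)]]
NumericMatrix im2col_1d(NumericVector X, int B, int L, int C, int k) {
  int pad = (k - 1) / 2;
  NumericMatrix M(B * L, k * C);
  for (int j = 0; j < k; ++j) {
    for (int c = 0; c < C; ++c) {
      int col = j * C + c;
      for (int l = 0; l < L; ++l) {
        int pos = l + j - pad;
        if (pos < 0 || pos >= L) continue;
        int src = (c * L + pos) * B;
        int dst = col * (B * L) + l * B;
        for (int b = 0; b < B; ++b) M[dst + b] = X[src + b];
      }
    }
  }
  return M;
}

// [[Rcpp::export(rng = false)]]
NumericVector col2im_1d(NumericMatrix dM, int B, int L, int C, int k) {
  int pad = (k - 1) / 2;
  NumericVector dX(B * L * C);
  for (int j = 0; j < k; ++j) {
    for (int c = 0; c < C; ++c) {
      int col = j * C + c;
      for (int l = 0; l < L; ++l) {
        int pos = l + j - pad;
        if (pos < 0 || pos >= L) continue;
        int dst = (c * L + pos) * B;
        int src = col * (B * L) + l * B;
        for (int b = 0; b < B; ++b) dX[dst + b] += dM[src + b];
      }
    }
  }
  dX.attr("dim") = IntegerVector::create(B, L, C);
  return dX;
}

// tanh(Z + b[col]) in one pass
// [[Rcpp::export(rng = false)]]
NumericMatrix tanh_bias(NumericMatrix Z, NumericVector b) {
  int nr = Z.nrow(), nc = Z.ncol();
  NumericMatrix A(nr, nc);
  for (int c = 0; c < nc; ++c) {
    double bc = b[c];
    for (int r = 0; r < nr; ++r) A(r, c) = std::tanh(Z(r, c) + bc);
  }
  return A;
}

// (dA + l1 * sign(A)) * (1 - A^2): tanh backprop with the L1 activity
// penalty gradient folded in (l1 already scaled by 1/batch)
// [[Rcpp::export(rng = false)]]
NumericMatrix backprop_tanh(NumericMatrix dA, NumericMatrix A, double l1) {
  int n = dA.size();
  NumericMatrix dZ(dA.nrow(), dA.ncol());
  for (int i = 0; i < n; ++i) {
    double a = A[i];
    double g = dA[i];
    if (l1 != 0.0) g += l1 * ((a > 0) - (a < 0));
    dZ[i] = g * (1.0 - a * a);
  }
  return dZ;
}

// fused in-place Adam update of one parameter tensor
// [[Rcpp::export(rng = false)]]
void adam_step(NumericVector p, NumericVector g, NumericVector m,
               NumericVector v, double lr_corr, double b1, double b2,
               double eps) {
  int n = p.size();
  for (int i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1.0 - b1) * g[i];
    v[i] = b2 * v[i] + (1.0 - b2) * g[i] * g[i];
    p[i] -= lr_corr * m[i] / (std::sqrt(v[i]) + eps);
  }
}
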