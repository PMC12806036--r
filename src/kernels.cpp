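// Compiled kernels for the inner training loops: the multi-head attention
// per-sample score/softmax/context computation and the im2col gather /
// scatter of the multi-width text convolutions. Shapes follow the R side:
// batched sequence tensors are (B*n) x d matrices in sample-major order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Multi-head self-attention core. Q, K, V: (B*n) x d. mask: B x n (1 =
// real token). Returns ctx ((B*n) x d) and the attention tensors stacked
// as one (B*heads*n) x n matrix (sample-major, head within sample).
// [[Rcpp::export(name = ".attn_fwd_cpp")]]
List attn_fwd_cpp(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                  const arma::imat& mask, int heads) {
  const int B = mask.n_rows, n = mask.n_cols, d = Q.n_cols;
  const int dh = d / heads;
  const double scale = 1.0 / std::sqrt((double) dh);
  arma::mat ctx(B * n, d, arma::fill::zeros);
  arma::mat A(B * heads * n, n, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * n;
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * dh;
      arma::mat Qb = Q.submat(r0, c0, r0 + n - 1, c0 + dh - 1);
      arma::mat Kb = K.submat(r0, c0, r0 + n - 1, c0 + dh - 1);
      arma::mat S = Qb * Kb.t() * scale;                 // n x n
      for (int j = 0; j < n; ++j)
        if (!mask(b, j)) S.col(j).fill(-arma::datum::inf);
      // row-wise stable softmax
      for (int i = 0; i < n; ++i) {
        arma::rowvec row = S.row(i);
        double m = row.max();
        row = arma::exp(row - m);
        S.row(i) = row / arma::accu(row);
      }
      A.rows((b * heads + h) * n, (b * heads + h) * n + n - 1) = S;
      ctx.submat(r0, c0, r0 + n - 1, c0 + dh - 1) =
        S * V.submat(r0, c0, r0 + n - 1, c0 + dh - 1);
    }
  }
  return List::create(Named("ctx") = ctx, Named("A") = A);
}

// Backward of the attention core: given dctx and cached A, Q, K, V,
// produce dQ, dK, dV.
// [[Rcpp::export(name = ".attn_bwd_cpp")]]
List attn_bwd_cpp(const arma::mat& dctx, const arma::mat& A,
                  const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                  int B, int n, int heads) {
  const int d = Q.n_cols, dh = d / heads;
  const double scale = 1.0 / std::sqrt((double) dh);
  arma::mat dQ(B * n, d, arma::fill::zeros);
  arma::mat dK(B * n, d, arma::fill::zeros);
  arma::mat dV(B * n, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * n;
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * dh;
      arma::mat P = A.rows((b * heads + h) * n, (b * heads + h) * n + n - 1);
      arma::mat dC = dctx.submat(r0, c0, r0 + n - 1, c0 + dh - 1);
      arma::mat Vb = V.submat(r0, c0, r0 + n - 1, c0 + dh - 1);
      arma::mat dP = dC * Vb.t();                        // n x n
      dV.submat(r0, c0, r0 + n - 1, c0 + dh - 1) = P.t() * dC;
      // softmax backward per row, then scale
      arma::mat dS(n, n);
      for (int i = 0; i < n; ++i) {
        arma::rowvec p = P.row(i);
        arma::rowvec dp = dP.row(i);
        dS.row(i) = p % (dp - arma::dot(dp, p));
      }
      dS *= scale;
      dQ.submat(r0, c0, r0 + n - 1, c0 + dh - 1) =
        dS * K.submat(r0, c0, r0 + n - 1, c0 + dh - 1);
      dK.submat(r0, c0, r0 + n - 1, c0 + dh - 1) =
        dS.t() * Q.submat(r0, c0, r0 + n - 1, c0 + dh - 1);
    }
  }
  return List::create(Named("dQ") = dQ, Named("dK") = dK, Named("dV") = dV);
}

// im2col gather for width-w convolution windows: rows of the output are
// the concatenated w consecutive rows of X starting at starts[r] (1-based).
// Column-major friendly: one strided gather per output column.
// [[Rcpp::export(name = ".im2col_cpp")]]
arma::mat im2col_cpp(const arma::mat& X, const arma::ivec& starts, int w) {
  const int m = starts.n_elem, d = X.n_cols;
  arma::mat out(m, w * d);
  for (int j = 0; j < w; ++j) {
    for (int c = 0; c < d; ++c) {
      const double* src = X.colptr(c);
      double* dst = out.colptr(j * d + c);
      for (int r = 0; r < m; ++r) dst[r] = src[starts[r] - 1 + j];
    }
  }
  return out;
}

// Scatter-add transpose of im2col: accumulate window-gradient rows back
// onto the n_rows source rows of X.
// [[Rcpp::export(name = ".col2im_cpp")]]
arma::mat col2im_cpp(const arma::mat& dXc, const arma::ivec& starts, int w,
                     int n_rows) {
  const int m = starts.n_elem;
  const int d = dXc.n_cols / w;
  arma::mat dX(n_rows, d, arma::fill::zeros);
  for (int j = 0; j < w; ++j) {
    for (int c = 0; c < d; ++c) {
      const double* src = dXc.colptr(j * d + c);
      double* dst = dX.colptr(c);
      for (int r = 0; r < m; ++r) dst[starts[r] - 1 + j] += src[r];
    }
  }
  return dX;
}

// Fused hypergraph attention update. Given transformed neighbor features
// Tn (rows indexed by `n_idx`, the side being aggregated) and transformed
// center features Tc (rows indexed by `c_idx`, the side being updated),
// per-incidence weights wgt (all 1 for the node update), computes
//   raw  = <Tn[n_idx], Tc[c_idx]>          (per incidence)
//   s    = leakyrelu(raw) * wgt
//   att  = softmax of s grouped by c_idx   (over each center's neighbors)
//   out  = elu( sum_{incidence} att * Tn[n_idx] )  (rows = centers)
// For the edge update: Tn = Tv (nodes), Tc = Te_prev (edges), c_idx = edge.
// For the node update: Tn = Te (edges), Tc = Tv (nodes), c_idx = node.
// [[Rcpp::export(name = ".hgat_update_fwd_cpp")]]
List hgat_update_fwd_cpp(const arma::mat& Tn, const arma::mat& Tc,
                         const arma::ivec& n_idx, const arma::ivec& c_idx,
                         const arma::vec& wgt, int n_centers, double slope) {
  const int m = n_idx.n_elem, d = Tn.n_cols;
  arma::mat TnT = Tn.t(), TcT = Tc.t();       // d x rows: contiguous columns
  arma::vec raw(m), s(m);
  for (int r = 0; r < m; ++r) {
    const double* pa = TnT.colptr(n_idx[r] - 1);
    const double* pb = TcT.colptr(c_idx[r] - 1);
    double acc = 0;
    for (int c = 0; c < d; ++c) acc += pa[c] * pb[c];
    raw[r] = acc;
    s[r] = (acc > 0 ? acc : slope * acc) * wgt[r];
  }
  // grouped softmax over centers (exact per-group max)
  arma::vec gmax(n_centers); gmax.fill(-arma::datum::inf);
  for (int r = 0; r < m; ++r) {
    const int b = c_idx[r] - 1;
    if (s[r] > gmax[b]) gmax[b] = s[r];
  }
  arma::vec att(m), gsum(n_centers, arma::fill::zeros);
  for (int r = 0; r < m; ++r) {
    att[r] = std::exp(s[r] - gmax[c_idx[r] - 1]);
    gsum[c_idx[r] - 1] += att[r];
  }
  for (int r = 0; r < m; ++r) att[r] /= gsum[c_idx[r] - 1];
  arma::mat aggT(d, n_centers, arma::fill::zeros);
  for (int r = 0; r < m; ++r) {
    const double* pa = TnT.colptr(n_idx[r] - 1);
    double* pb = aggT.colptr(c_idx[r] - 1);
    for (int c = 0; c < d; ++c) pb[c] += att[r] * pa[c];
  }
  arma::mat out = aggT.t();
  out.transform([](double x) { return x > 0 ? x : std::exp(x) - 1; });
  return List::create(Named("out") = out, Named("att") = att,
                      Named("raw") = raw);
}

// Backward of the fused update. Returns gradients for Tn and Tc.
// [[Rcpp::export(name = ".hgat_update_bwd_cpp")]]
List hgat_update_bwd_cpp(const arma::mat& dout, const arma::mat& out,
                         const arma::mat& Tn, const arma::mat& Tc,
                         const arma::ivec& n_idx, const arma::ivec& c_idx,
                         const arma::vec& wgt, const arma::vec& att,
                         const arma::vec& raw, double slope) {
  const int m = n_idx.n_elem, d = Tn.n_cols;
  const int nc = out.n_rows, nn = Tn.n_rows;
  arma::mat TnT = Tn.t(), TcT = Tc.t();
  // elu backward on the aggregated centers, transposed layout
  arma::mat daggT(d, nc);
  for (int b = 0; b < nc; ++b)
    for (int c = 0; c < d; ++c)
      daggT(c, b) = dout(b, c) * (out(b, c) > 0 ? 1.0 : out(b, c) + 1.0);
  arma::vec datt(m);
  arma::mat dTnT(d, nn, arma::fill::zeros);
  for (int r = 0; r < m; ++r) {
    const int a = n_idx[r] - 1, b = c_idx[r] - 1;
    const double* pa = TnT.colptr(a);
    const double* pg = daggT.colptr(b);
    double* pda = dTnT.colptr(a);
    double acc = 0;
    for (int c = 0; c < d; ++c) {
      acc += pa[c] * pg[c];
      pda[c] += att[r] * pg[c];
    }
    datt[r] = acc;
  }
  // softmax backward grouped by center
  arma::vec inner(nc, arma::fill::zeros);
  for (int r = 0; r < m; ++r) inner[c_idx[r] - 1] += datt[r] * att[r];
  arma::mat dTcT(d, Tc.n_rows, arma::fill::zeros);
  for (int r = 0; r < m; ++r) {
    const int a = n_idx[r] - 1, b = c_idx[r] - 1;
    double ds = att[r] * (datt[r] - inner[b]);
    double draw = ds * wgt[r] * (raw[r] > 0 ? 1.0 : slope);
    const double* pa = TnT.colptr(a);
    const double* pb = TcT.colptr(b);
    double* pda = dTnT.colptr(a);
    double* pdb = dTcT.colptr(b);
    for (int c = 0; c < d; ++c) {
      pda[c] += draw * pb[c];
      pdb[c] += draw * pa[c];
    }
  }
  return List::create(Named("dTn") = dTnT.t(), Named("dTc") = dTcT.t());
}

// Grouped column sums: out[g[r], ] += X[r, ] with groups 1..ng.
// [[Rcpp::export(name = ".group_sum_mat_cpp")]]
arma::mat group_sum_mat_cpp(const arma::mat& X, const arma::ivec& g, int ng) {
  const int m = X.n_rows, d = X.n_cols;
  arma::mat out(ng, d, arma::fill::zeros);
  for (int c = 0; c < d; ++c) {
    const double* src = X.colptr(c);
    double* dst = out.colptr(c);
    for (int r = 0; r < m; ++r) dst[g[r] - 1] += src[r];
  }
  return out;
}

// [[Rcpp::export(name = ".group_sum_vec_cpp")]]
arma::vec group_sum_vec_cpp(const arma::vec& x, const arma::ivec& g, int ng) {
  arma::vec out(ng, arma::fill::zeros);
  for (arma::uword r = 0; r < x.n_elem; ++r) out[g[r] - 1] += x[r];
  return out;
}

// Row gather: out[r, ] = X[idx[r], ] (1-based idx). Faster than R's
// X[idx, ] for the large index vectors of the hypergraph incidence.
// [[Rcpp::export(name = ".row_gather_cpp")]]
arma::mat row_gather_cpp(const arma::mat& X, const arma::ivec& idx) {
  const int m = idx.n_elem, d = X.n_cols;
  arma::mat out(m, d);
  for (int c = 0; c < d; ++c) {
    const double* src = X.colptr(c);
    double* dst = out.colptr(c);
    for (int r = 0; r < m; ++r) dst[r] = src[idx[r] - 1];
  }
  return out;
}
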