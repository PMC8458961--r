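#include <Rcpp.h>
using namespace Rcpp;

// Generic gather: out[j] = x[idx[j]] (1-based). Used by the pooling layers.
// [[Rcpp::export]]
NumericVector nc_gather(NumericVector x, IntegerVector idx) {
  R_xlen_t n = idx.size();
  NumericVector out(no_init(n));
  for (R_xlen_t j = 0; j < n; ++j) out[j] = x[idx[j] - 1];
  return out;
}

// Structured im2col for the convolution forward pass. The input x is a
// (Pin*N) x Cin matrix (spatial index fastest, then sample); base gives the
// 1-based input spatial index of each output position's window origin and
// offlin the linear offset of each kernel tap. The output is the
// (Pout*N) x (K*Cin) im2col matrix with taps fastest, then channels, in its
// column order.
// [[Rcpp::export]]
NumericVector nc_im2col(NumericVector x, IntegerVector base,
                        IntegerVector offlin, int Pin, int N, int Cin) {
  int Pout = base.size(), K = offlin.size();
  R_xlen_t PoutN = (R_xlen_t)Pout * N;
  NumericVector out(no_init(PoutN * K * Cin));
  const double *xp = x.begin();
  const int *bp = base.begin();
  double *op = out.begin();
  for (int ci = 0; ci < Cin; ++ci) {
    for (int t = 0; t < K; ++t) {
      R_xlen_t col = (R_xlen_t)(t + ci * K) * PoutN;
      for (int n = 0; n < N; ++n) {
        const double *src = xp + (R_xlen_t)ci * Pin * N + (R_xlen_t)n * Pin +
                            offlin[t] - 1;
        double *dst = op + col + (R_xlen_t)n * Pout;
        for (int p = 0; p < Pout; ++p) dst[p] = src[bp[p]];
      }
    }
  }
  return out;
}

// col2im scatter-add, the adjoint of nc_im2col: accumulates the im2col
// gradient back onto the (Pin*N) x Cin input layout.
// [[Rcpp::export]]
NumericVector nc_col2im(NumericVector dxc, IntegerVector base,
                        IntegerVector offlin, int Pin, int N, int Cin) {
  int Pout = base.size(), K = offlin.size();
  R_xlen_t PoutN = (R_xlen_t)Pout * N;
  NumericVector out((R_xlen_t)Pin * N * Cin);  // zero-initialised
  const double *dp = dxc.begin();
  const int *bp = base.begin();
  double *op = out.begin();
  for (int ci = 0; ci < Cin; ++ci) {
    for (int t = 0; t < K; ++t) {
      R_xlen_t col = (R_xlen_t)(t + ci * K) * PoutN;
      for (int n = 0; n < N; ++n) {
        double *dst = op + (R_xlen_t)ci * Pin * N + (R_xlen_t)n * Pin +
                      offlin[t] - 1;
        const double *src = dp + col + (R_xlen_t)n * Pout;
        for (int p = 0; p < Pout; ++p) dst[bp[p]] += src[p];
      }
    }
  }
  return out;
}

// Max pooling over precomputed window membership. rows is a (Pout x K)
// 1-based spatial index matrix (NA = window member clipped at the border);
// x is (Pin*N) x C. Returns the pooled (Pout*N) x C matrix and, via argmax,
// the winning input row of each output element (1-based within Pin*N,
// per column), for the backward routing.
// [[Rcpp::export]]
List nc_maxpool(NumericMatrix x, IntegerMatrix rows, int Pin, int N) {
  int Pout = rows.nrow(), K = rows.ncol(), C = x.ncol();
  R_xlen_t PoutN = (R_xlen_t)Pout * N;
  NumericMatrix out(no_init(PoutN, C));
  IntegerMatrix arg(no_init(PoutN, C));
  for (int c = 0; c < C; ++c) {
    const double *xc = &x(0, c);
    double *oc = &out(0, c);
    int *ac = &arg(0, c);
    for (int n = 0; n < N; ++n) {
      R_xlen_t off = (R_xlen_t)n * Pin;
      for (int p = 0; p < Pout; ++p) {
        double best = R_NegInf; int bi = -1;
        for (int t = 0; t < K; ++t) {
          int r = rows(p, t);
          if (r == NA_INTEGER) continue;
          double v = xc[off + r - 1];
          if (v > best) { best = v; bi = r; }
        }
        oc[(R_xlen_t)n * Pout + p] = best;
        ac[(R_xlen_t)n * Pout + p] = (int)off + bi;
      }
    }
  }
  return List::create(_["m"] = out, _["arg"] = arg);
}

// Backward of nc_maxpool: route each output gradient to its argmax input.
// [[Rcpp::export]]
NumericMatrix nc_maxpool_backward(NumericMatrix dy, IntegerMatrix arg,
                                  int PinN) {
  int C = dy.ncol();
  R_xlen_t n = dy.nrow();
  NumericMatrix out(PinN, C);
  for (int c = 0; c < C; ++c) {
    const double *dc = &dy(0, c);
    const int *ac = &arg(0, c);
    double *oc = &out(0, c);
    for (R_xlen_t j = 0; j < n; ++j) oc[ac[j] - 1] += dc[j];
  }
  return out;
}
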