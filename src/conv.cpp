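// Grouped multi-channel "same" 2-D convolution (correlation convention), its
// adjoint, and the kernel gradient. These are the hot loops of the analysis
// operators and of the unrolled training graph; everything else lives in R.
//
// Layout conventions (match the R side):
//  - a batched field is an array (H, W, C*B); slice index = c + C*b
//  - a kernel bank is a 4-D array (ks, ks, Cout, Cin/G) flattened column-major
//  - grouped semantics: group g couples input channels [g*Cin/G, ...) with
//    output channels [g*Cout/G, ...); G = Cout means depthwise, G = 1 dense.
//
// Zero padding runs through raw-pointer tap loops (the per-image working set
// fits in cache, and the contiguous inner loops vectorize); the circular path
// uses shifted copies and is only exercised by small exactness tests.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// O(i, j) += w * I(i + di, j + dj), zero outside; column-major H x W pages
static inline void axpy_tap(double* O, const double* I, double w, int H,
                            int W, int di, int dj) {
  if (w == 0.0) return;
  const int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
  const int j0 = std::max(0, -dj), j1 = W - 1 - std::max(0, dj);
  const int n = i1 - i0 + 1;
  if (n <= 0) return;
  for (int j = j0; j <= j1; ++j) {
    double* o = O + (size_t)j * H + i0;
    const double* p = I + (size_t)(j + dj) * H + (i0 + di);
    for (int i = 0; i < n; ++i) o[i] += w * p[i];
  }
}

// sum_{i,j} A(i, j) * B(i + di, j + dj), zero outside
static inline double dot_tap(const double* A, const double* Bp, int H, int W,
                             int di, int dj) {
  const int i0 = std::max(0, -di), i1 = H - 1 - std::max(0, di);
  const int j0 = std::max(0, -dj), j1 = W - 1 - std::max(0, dj);
  const int n = i1 - i0 + 1;
  if (n <= 0 || j0 > j1) return 0.0;
  double s = 0.0;
  for (int j = j0; j <= j1; ++j) {
    const double* a = A + (size_t)j * H + i0;
    const double* b = Bp + (size_t)(j + dj) * H + (i0 + di);
    for (int i = 0; i < n; ++i) s += a[i] * b[i];
  }
  return s;
}

static inline void tap_axpy_circ(mat& Out, const mat& In, double w, int di,
                                 int dj) {
  if (w == 0.0) return;
  Out += w * shift(shift(In, -di, 0), -dj, 1);
}

static inline double tap_dot_circ(const mat& A, const mat& Bm, int di,
                                  int dj) {
  return accu(A % shift(shift(Bm, -di, 0), -dj, 1));
}

// out(i,j,co) = sum_{ci in group(co)} sum_{di,dj} k(di,dj,co,ciL) x(i+di, j+dj, ci)
// adjoint = TRUE applies the transpose (x then has Cout*B slices, result Cin*B).
// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const Rcpp::NumericVector& kern,
                      int ks, int Cin, int Cout, int G, int B, int pad,
                      bool adjoint) {
  const int H = x.n_rows, W = x.n_cols;
  const int CinG = Cin / G, CoutG = Cout / G, r = (ks - 1) / 2;
  const int Cres = adjoint ? Cin : Cout;
  cube out(H, W, (uword)(Cres * B), fill::zeros);
  const double* K = kern.begin();
  auto kval = [&](int di, int dj, int co, int ciL) {
    return K[(di + r) + ks * ((dj + r) + ks * (co + Cout * ciL))];
  };
  for (int b = 0; b < B; ++b) {
    for (int g = 0; g < G; ++g) {
      for (int coL = 0; coL < CoutG; ++coL) {
        const int co = g * CoutG + coL;
        for (int ciL = 0; ciL < CinG; ++ciL) {
          const int ci = g * CinG + ciL;
          const int so = adjoint ? (ci + Cin * b) : (co + Cout * b);
          const int si = adjoint ? (co + Cout * b) : (ci + Cin * b);
          if (pad == 0) {
            double* O = out.slice_memptr(so);
            const double* I = x.slice_memptr(si);
            for (int dj = -r; dj <= r; ++dj)
              for (int di = -r; di <= r; ++di)
                axpy_tap(O, I, kval(di, dj, co, ciL), H, W,
                         adjoint ? -di : di, adjoint ? -dj : dj);
          } else {
            mat& O = out.slice(so);
            const mat& I = x.slice(si);
            for (int dj = -r; dj <= r; ++dj)
              for (int di = -r; di <= r; ++di)
                tap_axpy_circ(O, I, kval(di, dj, co, ciL),
                              adjoint ? -di : di, adjoint ? -dj : dj);
          }
        }
      }
    }
  }
  return out;
}

// Gradient of sum(gout * op(xin)) with respect to the kernel bank, for the
// forward (adjoint = FALSE) or transposed (adjoint = TRUE) operator above.
// Both cases reduce to tap correlations between the Cin-side and Cout-side
// tensors.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_conv2d_kgrad(const arma::cube& xin,
                                     const arma::cube& gout, int ks, int Cin,
                                     int Cout, int G, int B, int pad,
                                     bool adjoint) {
  const int H = xin.n_rows, W = xin.n_cols;
  const int CinG = Cin / G, CoutG = Cout / G, r = (ks - 1) / 2;
  Rcpp::NumericVector grad(ks * ks * Cout * CinG);
  grad.attr("dim") = Rcpp::IntegerVector::create(ks, ks, Cout, CinG);
  double* Gr = grad.begin();
  auto gref = [&](int di, int dj, int co, int ciL) -> double& {
    return Gr[(di + r) + ks * ((dj + r) + ks * (co + Cout * ciL))];
  };
  for (int b = 0; b < B; ++b) {
    for (int g = 0; g < G; ++g) {
      for (int coL = 0; coL < CoutG; ++coL) {
        const int co = g * CoutG + coL;
        for (int ciL = 0; ciL < CinG; ++ciL) {
          const int ci = g * CinG + ciL;
          if (pad == 0) {
            // forward: grad = sum gout_co(i,j) xin_ci(i+di, j+dj)
            // adjoint: grad = sum xin_co(i,j) gout_ci(i+di, j+dj)
            const double* A = adjoint ? xin.slice_memptr(co + Cout * b)
                                      : gout.slice_memptr(co + Cout * b);
            const double* Bp = adjoint ? gout.slice_memptr(ci + Cin * b)
                                       : xin.slice_memptr(ci + Cin * b);
            for (int dj = -r; dj <= r; ++dj)
              for (int di = -r; di <= r; ++di)
                gref(di, dj, co, ciL) += dot_tap(A, Bp, H, W, di, dj);
          } else {
            if (!adjoint)
              for (int dj = -r; dj <= r; ++dj)
                for (int di = -r; di <= r; ++di)
                  gref(di, dj, co, ciL) +=
                      tap_dot_circ(gout.slice(co + Cout * b),
                                   xin.slice(ci + Cin * b), di, dj);
            else
              for (int dj = -r; dj <= r; ++dj)
                for (int di = -r; di <= r; ++di)
                  gref(di, dj, co, ciL) +=
                      tap_dot_circ(gout.slice(ci + Cin * b),
                                   xin.slice(co + Cout * b), -di, -dj);
          }
        }
      }
    }
  }
  return grad;
}
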