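// Thin in-place LU wrappers around R's LAPACK, so one large BEM matrix can
// be assembled, deflated and factorised without a second N x N allocation.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Factorise A (n x n) in place; returns the pivot vector. A is modified!
// [[Rcpp::export(name = ".lu_factor_inplace_cpp")]]
IntegerVector lu_factor_inplace_cpp(NumericMatrix A) {
  int n = A.nrow();
  if (A.ncol() != n) stop("lu_factor: matrix must be square");
  IntegerVector ipiv(n);
  int info = 0;
  F77_CALL(dgetrf)(&n, &n, A.begin(), &n, ipiv.begin(), &info);
  if (info < 0) stop("lu_factor: illegal argument %d", -info);
  if (info > 0) stop("lu_factor: matrix singular at pivot %d", info);
  return ipiv;
}

// Solve op(A) X = B for X given the in-place LU factors; trans = 0 for A,
// 1 for A^T. B is not modified.
// [[Rcpp::export(name = ".lu_solve_cpp")]]
NumericMatrix lu_solve_cpp(NumericMatrix LU, IntegerVector ipiv,
                           NumericMatrix B, int trans) {
  int n = LU.nrow();
  int nrhs = B.ncol();
  if (B.nrow() != n) stop("lu_solve: dimension mismatch");
  NumericMatrix X = clone(B);
  int info = 0;
  char tr = trans ? 'T' : 'N';
  F77_CALL(dgetrs)(&tr, &n, &nrhs, LU.begin(), &n,
                   (int*) ipiv.begin(), X.begin(), &n, &info FCONE);
  if (info != 0) stop("lu_solve: LAPACK error %d", info);
  return X;
}

// Reciprocal-lead-field contraction: given the transfer vector t (solution
// of A^T t = g), collocation points X (n x 3, metres) and evaluation points
// P (m x 3, metres), returns for each p the 3-vector
//   sum_i t_i (x_i - p) / (4 pi |x_i - p|^3),
// i.e. t^T s(e_hat at p) for the three unit dipole orientations.
// [[Rcpp::export(name = ".transfer_contract_cpp")]]
NumericMatrix transfer_contract_cpp(NumericMatrix X, NumericVector t,
                                    NumericMatrix P) {
  int n = X.nrow(), m = P.nrow();
  NumericMatrix out(m, 3);
  const double c = 1.0 / (4.0 * M_PI);
  for (int p = 0; p < m; ++p) {
    double px = P(p, 0), py = P(p, 1), pz = P(p, 2);
    double ax = 0, ay = 0, az = 0;
    for (int i = 0; i < n; ++i) {
      double dx = X(i, 0) - px, dy = X(i, 1) - py, dz = X(i, 2) - pz;
      double r2 = dx * dx + dy * dy + dz * dz;
      double w = t[i] / (r2 * std::sqrt(r2));
      ax += w * dx; ay += w * dy; az += w * dz;
    }
    out(p, 0) = c * ax; out(p, 1) = c * ay; out(p, 2) = c * az;
  }
  return out;
}
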