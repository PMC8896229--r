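// Weighted graphical lasso solver.
//
// Maximizes  logdet(Theta) - tr(S * Theta) - sum_{j1 != j2} P[j1,j2] |theta_{j1j2}|
// by block coordinate descent over columns of the working covariance W
// (the classic glasso algorithm, extended to an elementwise penalty matrix
// P with an unpenalized diagonal). Each column update solves a lasso
// problem by coordinate descent; warm starts over a lambda path reuse both
// W and the regression coefficients B.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// min_b 0.5 b' V b - s' b + sum_j rho_j |b_j|, updated in place.
static void lasso_cd(const mat &V, const vec &s, const vec &rho, vec &b,
                     double thr, int max_iter) {
  const uword q = s.n_elem;
  vec Vb = V * b;
  for (int it = 0; it < max_iter; ++it) {
    double dmax = 0.0;
    for (uword j = 0; j < q; ++j) {
      const double bj = b(j);
      const double vjj = std::max(V(j, j), 1e-12);
      const double gj = s(j) - Vb(j) + vjj * bj;
      double bn = 0.0;
      if (gj > rho(j))
        bn = (gj - rho(j)) / vjj;
      else if (gj < -rho(j))
        bn = (gj + rho(j)) / vjj;
      if (bn != bj) {
        Vb += V.col(j) * (bn - bj);
        b(j) = bn;
        double d = std::fabs(bn - bj);
        if (d > dmax) dmax = d;
      }
    }
    if (dmax < thr) break;
  }
}

// [[Rcpp::export]]
Rcpp::List wglasso_cpp(const arma::mat &S, const arma::mat &P, double tol,
                       int max_iter,
                       Rcpp::Nullable<Rcpp::NumericMatrix> W_init,
                       Rcpp::Nullable<Rcpp::NumericMatrix> B_init) {
  const uword p = S.n_rows;
  mat W = W_init.isNotNull()
              ? mat(Rcpp::as<arma::mat>(W_init.get()))
              : mat(S);
  // Solution fixes the working diagonal at S_jj + P_jj (P_jj = 0 here).
  W.diag() = S.diag() + P.diag();
  mat B = B_init.isNotNull() ? mat(Rcpp::as<arma::mat>(B_init.get()))
                             : zeros<mat>(p, p);

  double offmean = 0.0;
  if (p > 1) {
    offmean = (accu(abs(S)) - accu(abs(S.diag()))) /
              static_cast<double>(p * (p - 1));
  }
  const double thr = tol * std::max(offmean, 1e-10);

  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    double dmax = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx(p - 1);
      uword k = 0;
      for (uword i = 0; i < p; ++i)
        if (i != j) idx(k++) = i;
      mat V = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec rho = P.col(j);
      rho = rho.elem(idx);
      vec b = B.col(j);
      b = b.elem(idx);
      lasso_cd(V, s12, rho, b, thr / 10.0, 1000);
      vec w12 = V * b;
      for (uword i = 0; i < p - 1; ++i) {
        double d = std::fabs(W(idx(i), j) - w12(i));
        if (d > dmax) dmax = d;
        W(idx(i), j) = w12(i);
        W(j, idx(i)) = w12(i);
        B(idx(i), j) = b(i);
      }
    }
    if (dmax < thr) {
      converged = true;
      break;
    }
  }

  // Recover Theta from the final W and regression coefficients.
  mat Theta = zeros<mat>(p, p);
  for (uword j = 0; j < p; ++j) {
    uvec idx(p - 1);
    uword k = 0;
    for (uword i = 0; i < p; ++i)
      if (i != j) idx(k++) = i;
    vec b = B.col(j);
    b = b.elem(idx);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double denom = W(j, j) - dot(w12, b);
    if (denom <= 1e-12) denom = 1e-12;
    const double tjj = 1.0 / denom;
    Theta(j, j) = tjj;
    for (uword i = 0; i < p - 1; ++i) Theta(idx(i), j) = -b(i) * tjj;
  }
  // Exact zeros where both regressions dropped the pair, then symmetrize.
  for (uword j = 0; j < p; ++j)
    for (uword i = 0; i < p; ++i)
      if (i != j && B(i, j) == 0.0 && B(j, i) == 0.0) Theta(i, j) = 0.0;
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(
      Rcpp::Named("theta") = Theta, Rcpp::Named("w") = W,
      Rcpp::Named("b") = B, Rcpp::Named("iterations") = iter,
      Rcpp::Named("converged") = converged);
}
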