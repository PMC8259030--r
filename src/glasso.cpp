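// Graphical lasso by block coordinate descent on the covariance (Friedman,
// Hastie & Tibshirani style), off-diagonal-only L1 penalty. The inner lasso
// subproblems are solved by coordinate descent with warm starts; the
// precision matrix is recovered from the final covariance estimate and the
// per-column regression coefficients.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double soft(double z, double lam) {
  if (z > lam) return z - lam;
  if (z < -lam) return z + lam;
  return 0.0;
}

// One glasso fit. B (p x p, zero diagonal) holds the lasso coefficients and
// is used/updated in place so path fits can warm start.
static int glasso_core(const mat& S, double lambda, double tol, int maxit,
                       mat& W, mat& B, mat& Theta) {
  const uword p = S.n_rows;
  int sweeps = 0;
  for (; sweeps < maxit; ++sweeps) {
    double maxdiff = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx(p - 1);
      uword c = 0;
      for (uword k = 0; k < p; ++k) if (k != j) idx(c++) = k;
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j); s12 = s12.elem(idx);
      vec beta = B.col(j); beta = beta.elem(idx);
      // inner lasso: 0.5 b'W11 b - s12'b + lambda|b|_1
      for (int it = 0; it < 1000; ++it) {
        double del = 0.0;
        for (uword k = 0; k < p - 1; ++k) {
          double old = beta(k);
          double denom = std::max(W11(k, k), 1e-12);  // zero-variance guard
          double r = s12(k) - dot(W11.col(k), beta) + W11(k, k) * old;
          double nb = soft(r, lambda) / denom;
          beta(k) = nb;
          del = std::max(del, std::fabs(nb - old));
        }
        if (del < tol * 0.1) break;
      }
      vec w12 = W11 * beta;
      for (uword k = 0; k < p - 1; ++k) {
        maxdiff = std::max(maxdiff, std::fabs(W(idx(k), j) - w12(k)));
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        B(idx(k), j) = beta(k);
      }
    }
    if (maxdiff < tol) { ++sweeps; break; }
  }
  // recover Theta from W and B
  Theta.set_size(p, p);
  for (uword j = 0; j < p; ++j) {
    uvec idx(p - 1);
    uword c = 0;
    for (uword k = 0; k < p; ++k) if (k != j) idx(c++) = k;
    vec beta = B.col(j); beta = beta.elem(idx);
    vec w12 = W.col(j); w12 = w12.elem(idx);
    double t22 = 1.0 / std::max(W(j, j) - dot(w12, beta), 1e-12);
    Theta(j, j) = t22;
    for (uword k = 0; k < p - 1; ++k) Theta(idx(k), j) = -beta(k) * t22;
  }
  Theta = (Theta + Theta.t()) / 2.0;
  return sweeps;
}

// [[Rcpp::export]]
Rcpp::List cpp_glasso(const arma::mat& S, double lambda, double tol,
                      int maxit) {
  mat W = S;                      // diagonal unpenalized: w_jj = s_jj
  mat B = zeros<mat>(S.n_rows, S.n_rows);
  mat Theta;
  int sweeps = glasso_core(S, lambda, tol, maxit, W, B, Theta);
  bool converged = sweeps < maxit;
  return Rcpp::List::create(Rcpp::Named("precision") = Theta,
                            Rcpp::Named("covariance") = W,
                            Rcpp::Named("sweeps") = sweeps,
                            Rcpp::Named("converged") = converged);
}

// Path fit along decreasing lambdas with warm starts.
// [[Rcpp::export]]
Rcpp::List cpp_glasso_path(const arma::mat& S, const arma::vec& lambdas,
                           double tol, int maxit) {
  const uword p = S.n_rows, L = lambdas.n_elem;
  mat W = S;
  mat B = zeros<mat>(p, p);
  cube thetas(p, p, L);
  ivec sweeps(L);
  ivec conv(L);
  for (uword l = 0; l < L; ++l) {
    mat Theta;
    int sw = glasso_core(S, lambdas(l), tol, maxit, W, B, Theta);
    thetas.slice(l) = Theta;
    sweeps(l) = sw;
    conv(l) = sw < maxit ? 1 : 0;
  }
  return Rcpp::List::create(Rcpp::Named("precision") = thetas,
                            Rcpp::Named("sweeps") = sweeps,
                            Rcpp::Named("converged") = conv);
}

// Edge indicator counts along a path for one dataset: returns an
// (p*(p-1)/2) x L 0/1 matrix of upper-triangle edges (|theta| > thr).
// [[Rcpp::export]]
arma::mat cpp_path_edges(const arma::mat& S, const arma::vec& lambdas,
                         double tol, int maxit, double thr) {
  const uword p = S.n_rows, L = lambdas.n_elem;
  mat W = S;
  mat B = zeros<mat>(p, p);
  mat edges(p * (p - 1) / 2, L, fill::zeros);
  for (uword l = 0; l < L; ++l) {
    mat Theta;
    glasso_core(S, lambdas(l), tol, maxit, W, B, Theta);
    uword e = 0;
    for (uword i = 0; i < p - 1; ++i)
      for (uword j = i + 1; j < p; ++j, ++e)
        if (std::fabs(Theta(i, j)) > thr) edges(e, l) = 1.0;
  }
  return edges;
}
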