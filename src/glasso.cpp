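#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Graphical lasso: maximize log det(Theta) - tr(S Theta) - rho * ||Theta||_1,off
// over symmetric positive definite Theta, by block coordinate descent on the
// covariance estimate W (Friedman-style: each column update is a lasso solved
// by coordinate descent). The diagonal is unpenalized, so diag(W) = diag(S)
// throughout.
//
// S must be symmetric with a strictly positive diagonal (typically a sample
// correlation matrix). Returns the precision matrix, the estimated covariance
// W, the sweep count, and a convergence flag.
// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, double rho, int max_iter = 200,
                      double tol = 1e-4) {
  const int p = S.n_rows;
  if (p < 2) Rcpp::stop("need at least 2 variables");

  mat W = S;                 // working covariance; off-diagonals evolve
  mat B(p - 1, p, fill::zeros);  // lasso coefficients per column (warm start)

  // convergence threshold scaled to the average off-diagonal magnitude
  double off_mean = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) off_mean += std::abs(S(i, j));
  off_mean /= (double)(p * (p - 1));
  double thr = tol * std::max(off_mean, 1e-8);

  // index sets excluding each column, built once
  umat idx(p - 1, p);
  for (int j = 0; j < p; ++j) {
    int c = 0;
    for (int k = 0; k < p; ++k)
      if (k != j) idx(c++, j) = k;
  }

  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    double dw_max = 0.0;
    for (int j = 0; j < p; ++j) {
      const uvec id = idx.col(j);
      const mat W11 = W(id, id);
      vec s12(p - 1);
      for (int k = 0; k < p - 1; ++k) s12(k) = S(id(k), j);
      vec beta = B.col(j);
      vec v = W11 * beta;  // running W11 %*% beta, updated incrementally

      // coordinate descent on (1/2) b'W11 b - s12'b + rho|b|_1
      for (int sweep = 0; sweep < 200; ++sweep) {
        double db = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          const double old = beta(k);
          const double r = s12(k) - v(k) + W11(k, k) * old;
          double bnew = 0.0;
          if (r > rho)
            bnew = (r - rho) / W11(k, k);
          else if (r < -rho)
            bnew = (r + rho) / W11(k, k);
          if (bnew != old) {
            v += (bnew - old) * W11.col(k);
            beta(k) = bnew;
            db = std::max(db, std::abs(bnew - old));
          }
        }
        if (db < thr * 1e-2) break;
      }
      B.col(j) = beta;

      const vec w12 = W11 * beta;
      for (int k = 0; k < p - 1; ++k) {
        const double d = std::abs(W(id(k), j) - w12(k));
        if (d > dw_max) dw_max = d;
        W(id(k), j) = w12(k);
        W(j, id(k)) = w12(k);
      }
    }
    if (dw_max < thr) {
      converged = true;
      break;
    }
  }

  // recover Theta from the final W and the per-column lasso coefficients:
  // theta_jj = 1 / (w_jj - w12' beta),  theta_12 = -beta * theta_jj
  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    const uvec id = idx.col(j);
    const vec beta = B.col(j);
    double quad = 0.0;
    for (int k = 0; k < p - 1; ++k) quad += W(id(k), j) * beta(k);
    const double tjj = 1.0 / (W(j, j) - quad);
    Theta(j, j) = tjj;
    for (int k = 0; k < p - 1; ++k) Theta(id(k), j) = -beta(k) * tjj;
  }
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(
      Rcpp::Named("precision") = Theta, Rcpp::Named("covariance") = W,
      Rcpp::Named("iterations") = std::min(iter, max_iter),
      Rcpp::Named("converged") = converged);
}
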