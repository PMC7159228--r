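#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Dual coordinate descent for the L2-regularized L1-loss (hinge) SVM:
//   min_w 0.5 ||w||^2 + sum_i C_i max(0, 1 - y_i w'x_i)
// solved in the dual  min 0.5 a'Qa - e'a,  0 <= a_i <= C_i,
// Q_ij = y_i y_j x_i'x_j  (Hsieh et al., ICML 2008).
// The bias term is handled by the caller through an augmented constant
// column, so it is regularized like any other coordinate of w.
// Sweeps are cyclic in a fixed order: the solution is deterministic for a
// given input, which the trial-reproducibility contract relies on.

// [[Rcpp::export]]
Rcpp::List svm_dcd_linear(const arma::mat& X, const arma::vec& y,
                          const arma::vec& C, int max_passes, double tol) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::vec alpha(n, arma::fill::zeros);
  arma::vec w(p, arma::fill::zeros);
  arma::vec Qii(n);
  for (arma::uword i = 0; i < n; ++i)
    Qii[i] = arma::dot(X.row(i), X.row(i));

  int pass = 0;
  for (; pass < max_passes; ++pass) {
    double max_viol = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      if (Qii[i] <= 0.0) continue;
      const double G = y[i] * arma::dot(w, X.row(i).t()) - 1.0;
      double PG = G;  // projected gradient respecting the box constraint
      if (alpha[i] <= 0.0)        PG = std::min(G, 0.0);
      else if (alpha[i] >= C[i])  PG = std::max(G, 0.0);
      if (std::fabs(PG) > max_viol) max_viol = std::fabs(PG);
      if (std::fabs(PG) > 1e-12) {
        const double a_old = alpha[i];
        const double a_new =
            std::min(std::max(a_old - G / Qii[i], 0.0), C[i]);
        if (a_new != a_old) {
          alpha[i] = a_new;
          w += (a_new - a_old) * y[i] * X.row(i).t();
        }
      }
    }
    if (max_viol < tol) { ++pass; break; }
  }
  return Rcpp::List::create(Rcpp::Named("alpha") = alpha,
                            Rcpp::Named("w") = w,
                            Rcpp::Named("passes") = pass);
}

// Same solver against a precomputed kernel matrix (used for the RBF
// kernel). Maintains f_i = sum_j alpha_j y_j K_ij incrementally.
// [[Rcpp::export]]
Rcpp::List svm_dcd_kernel(const arma::mat& K, const arma::vec& y,
                          const arma::vec& C, int max_passes, double tol) {
  const arma::uword n = K.n_rows;
  arma::vec alpha(n, arma::fill::zeros);
  arma::vec f(n, arma::fill::zeros);

  int pass = 0;
  for (; pass < max_passes; ++pass) {
    double max_viol = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      const double Qii = K(i, i);
      if (Qii <= 0.0) continue;
      const double G = y[i] * f[i] - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0)        PG = std::min(G, 0.0);
      else if (alpha[i] >= C[i])  PG = std::max(G, 0.0);
      if (std::fabs(PG) > max_viol) max_viol = std::fabs(PG);
      if (std::fabs(PG) > 1e-12) {
        const double a_old = alpha[i];
        const double a_new =
            std::min(std::max(a_old - G / Qii, 0.0), C[i]);
        if (a_new != a_old) {
          alpha[i] = a_new;
          f += (a_new - a_old) * y[i] * K.col(i);
        }
      }
    }
    if (max_viol < tol) { ++pass; break; }
  }
  return Rcpp::List::create(Rcpp::Named("alpha") = alpha,
                            Rcpp::Named("f") = f,
                            Rcpp::Named("passes") = pass);
}
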