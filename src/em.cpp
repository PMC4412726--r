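// EM inner loop for full-covariance Gaussian mixtures.
//
// Mirrors the R-level e_step()/m_step() math exactly: log-space component
// densities via Cholesky, log-sum-exp with the row maximum factored out,
// weight-normalized covariance updates with a ridge on the diagonal.
// Only the iteration loop lives here; initialization and restarts stay in
// R so all randomness goes through R's RNG.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// E-step: fills resp and returns the log-likelihood; returns NaN when a
// covariance loses positive definiteness.
static double e_step_ll(const mat& X, const vec& pi_k, const mat& mu,
                        const cube& sigma, mat& resp) {
  const uword n = X.n_rows, d = X.n_cols, K = pi_k.n_elem;
  mat W(n, K);
  W.fill(-datum::inf);
  const double c0 = -0.5 * d * std::log(2.0 * datum::pi);
  for (uword k = 0; k < K; ++k) {
    if (pi_k(k) <= 0.0) continue;
    mat R;
    if (!chol(R, sigma.slice(k))) return datum::nan;
    double logdet = 2.0 * accu(log(R.diag()));
    mat xc = X.each_row() - mu.row(k);
    // solve R^T z^T = xc^T  (lower-triangular forward solve)
    mat z = solve(trimatl(R.t()), xc.t());
    rowvec maha = sum(square(z), 0);
    W.col(k) = std::log(pi_k(k)) + c0 - 0.5 * logdet - 0.5 * maha.t();
  }
  vec m = max(W, 1);
  mat P = exp(W.each_col() - m);
  vec s = sum(P, 1);
  resp = P.each_col() / s;
  return accu(m + log(s));
}

// M-step; returns false when a component's total responsibility degenerates.
static bool m_step_update(const mat& X, const mat& resp, double reg,
                          vec& pi_k, mat& mu, cube& sigma) {
  const uword n = X.n_rows, d = X.n_cols, K = resp.n_cols;
  rowvec nk = sum(resp, 0);
  if (nk.min() < 1e-12) return false;
  pi_k = nk.t() / double(n);
  mu = resp.t() * X;
  mu.each_col() /= nk.t();
  for (uword k = 0; k < K; ++k) {
    mat xc = X.each_row() - mu.row(k);
    mat w = xc.each_col() % resp.col(k);
    sigma.slice(k) = w.t() * xc / nk(k) + reg * eye(d, d);
  }
  return true;
}

// [[Rcpp::export(name = ".em_run")]]
Rcpp::List em_run(const arma::mat& X, arma::mat resp, double reg,
                  double tol, int max_iter) {
  const uword d = X.n_cols, K = resp.n_cols;
  vec pi_k(K);
  mat mu(K, d);
  cube sigma(d, d, K);
  if (!m_step_update(X, resp, reg, pi_k, mu, sigma))
    return Rcpp::List::create(Rcpp::Named("status") = "degenerate");
  std::vector<double> traj;
  traj.reserve(max_iter);
  bool converged = false;
  for (int it = 1; it <= max_iter; ++it) {
    double ll = e_step_ll(X, pi_k, mu, sigma, resp);
    if (!std::isfinite(ll))
      return Rcpp::List::create(Rcpp::Named("status") = "degenerate");
    traj.push_back(ll);
    if (it > 1 && std::fabs(ll - traj[it - 2]) < tol) {
      converged = true;
      break;
    }
    if (it < max_iter) {
      if (!m_step_update(X, resp, reg, pi_k, mu, sigma))
        return Rcpp::List::create(Rcpp::Named("status") = "degenerate");
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("status") = "ok", Rcpp::Named("pi") = pi_k,
      Rcpp::Named("mu") = mu, Rcpp::Named("sigma") = sigma,
      Rcpp::Named("trajectory") = traj,
      Rcpp::Named("converged") = converged);
}
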