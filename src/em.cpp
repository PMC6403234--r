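// EM for Gaussian mixtures, d-dimensional, with an optional fixed-mean mode
// in which component centers are held at their initial values and only the
// weights and covariances are updated.
//
// Density evaluation is done in log space with per-component Cholesky
// factors; responsibilities use the log-sum-exp trick so that well-separated
// components do not underflow.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

// n x k matrix of per-component log densities log N(x | mu_j, Sigma_j).
// Throws if a covariance is not positive definite (caller applies the floor).
static mat log_component_density(const mat& X, const mat& M, const cube& S) {
  const uword n = X.n_rows, d = X.n_cols, k = M.n_rows;
  mat out(n, k);
  for (uword j = 0; j < k; ++j) {
    mat R;
    if (!chol(R, S.slice(j)))
      Rcpp::stop("covariance matrix of component %d is not positive definite", j + 1);
    // log|Sigma| = 2 * sum(log(diag(R)))
    double logdet = 2.0 * accu(log(R.diag()));
    mat Xc = X.each_row() - M.row(j);
    // Mahalanobis via triangular solve: z = R^-T xc
    mat Z = solve(trimatl(R.t()), Xc.t());
    rowvec quad = sum(square(Z), 0);
    out.col(j) = (-0.5 * (d * LOG2PI + logdet) - 0.5 * quad.t());
  }
  return out;
}

// Mixture log-density per row of X: log sum_j w_j N(x|mu_j, Sigma_j)
static vec mixture_logdensity(const mat& X, const vec& w, const mat& M,
                              const cube& S) {
  mat L = log_component_density(X, M, S);
  L.each_row() += log(w.t());
  vec m = max(L, 1);
  vec out = m + log(sum(exp(L.each_col() - m), 1));
  // rows where all components underflow completely
  out.elem(find_nonfinite(m)).fill(-datum::inf);
  return out;
}

// [[Rcpp::export]]
arma::vec gmm_logdensity_cpp(const arma::mat& X, const arma::vec& weights,
                             const arma::mat& means, const arma::cube& covs) {
  return mixture_logdensity(X, weights, means, covs);
}

// [[Rcpp::export]]
arma::mat gmm_responsibilities_cpp(const arma::mat& X, const arma::vec& weights,
                                   const arma::mat& means,
                                   const arma::cube& covs) {
  mat L = log_component_density(X, means, covs);
  L.each_row() += log(weights.t());
  vec m = max(L, 1);
  mat R = exp(L.each_col() - m);
  vec s = sum(R, 1);
  R.each_col() /= s;
  return R;
}

// One EM run from the supplied initial parameters.
//
// rel_tol_pct: stop when |delta log p| / |log p| * 100 < rel_tol_pct.
// cov_floor:   per-dimension ridge added to covariance diagonals each M-step.
// weight_floor: weights of components that lose all posterior mass are
//              clamped here (and the covariance reset to the floor) instead
//              of deleting the component, so component identity survives.
// [[Rcpp::export]]
Rcpp::List em_gmm_cpp(const arma::mat& X, const arma::vec& weights0,
                      const arma::mat& means0, const arma::cube& covs0,
                      int max_iter, double rel_tol_pct,
                      const arma::vec& cov_floor, bool fixed_means,
                      double weight_floor = 1e-12) {
  const uword n = X.n_rows, d = X.n_cols, k = means0.n_rows;
  vec w = weights0;
  mat M = means0;
  cube S = covs0;
  mat floor_mat = diagmat(cov_floor);

  std::vector<double> trace;
  trace.reserve(64);
  double ll_old = -datum::inf;
  bool converged = false;
  int iter = 0;
  bool empty_component = false;

  // univariate fast path: direct normal log-densities, no Cholesky plumbing
  if (d == 1) {
    vec x = X.col(0);
    vec mu = M.col(0);
    vec s2(k);
    for (uword j = 0; j < k; ++j) s2(j) = S.slice(j)(0, 0);
    double floor1 = cov_floor(0);
    mat L(n, k), R(n, k);
    for (iter = 1; iter <= max_iter; ++iter) {
      for (uword j = 0; j < k; ++j) {
        L.col(j) = std::log(w(j)) - 0.5 * std::log(2.0 * M_PI * s2(j)) -
                   square(x - mu(j)) / (2.0 * s2(j));
      }
      vec mx = max(L, 1);
      R = exp(L.each_col() - mx);
      vec sr = sum(R, 1);
      double ll = accu(mx + log(sr));
      trace.push_back(ll);
      R.each_col() /= sr;
      if (std::isfinite(ll_old)) {
        double rel = std::fabs(ll - ll_old) / std::fabs(ll) * 100.0;
        if (rel < rel_tol_pct) { converged = true; break; }
      }
      ll_old = ll;
      rowvec Nk = sum(R, 0);
      for (uword j = 0; j < k; ++j) {
        if (Nk(j) < n * weight_floor || Nk(j) <= 0.0) {
          empty_component = true;
          w(j) = weight_floor;
          s2(j) = std::max(floor1, 1e-300);
          continue;
        }
        w(j) = Nk(j) / n;
        if (!fixed_means) mu(j) = dot(R.col(j), x) / Nk(j);
        s2(j) = dot(R.col(j), square(x - mu(j))) / Nk(j) + floor1;
      }
      w /= accu(w);
    }
    if (iter > max_iter) iter = max_iter;
    M.col(0) = mu;
    for (uword j = 0; j < k; ++j) S.slice(j)(0, 0) = s2(j);
    return Rcpp::List::create(
        Rcpp::Named("weights") = w, Rcpp::Named("means") = M,
        Rcpp::Named("covariances") = S,
        Rcpp::Named("logLik") = trace.empty() ? NA_REAL : trace.back(),
        Rcpp::Named("logLikTrace") = trace,
        Rcpp::Named("nIterations") = (int)trace.size(),
        Rcpp::Named("converged") = converged,
        Rcpp::Named("emptyComponent") = empty_component);
  }

  for (iter = 1; iter <= max_iter; ++iter) {
    // E-step
    mat L = log_component_density(X, M, S);
    L.each_row() += log(w.t());
    vec mx = max(L, 1);
    mat R = exp(L.each_col() - mx);
    vec s = sum(R, 1);
    double ll = accu(mx + log(s));
    trace.push_back(ll);
    R.each_col() /= s;

    if (std::isfinite(ll_old)) {
      double rel = std::fabs(ll - ll_old) / std::fabs(ll) * 100.0;
      if (rel < rel_tol_pct) { converged = true; break; }
    }
    ll_old = ll;

    // M-step
    rowvec Nk = sum(R, 0);
    for (uword j = 0; j < k; ++j) {
      if (Nk(j) < n * weight_floor || Nk(j) <= 0.0) {
        // degenerate component: keep it alive at the floor
        empty_component = true;
        w(j) = weight_floor;
        S.slice(j) = floor_mat;
        if (S.slice(j)(0, 0) <= 0.0) S.slice(j).diag() += 1e-12;
        continue;
      }
      w(j) = Nk(j) / n;
      if (!fixed_means) M.row(j) = (R.col(j).t() * X) / Nk(j);
      mat Xc = X.each_row() - M.row(j);
      mat Sj = (Xc.each_col() % R.col(j)).t() * Xc / Nk(j);
      S.slice(j) = 0.5 * (Sj + Sj.t()) + floor_mat;
    }
    w /= accu(w);
  }

  if (iter > max_iter) iter = max_iter;

  return Rcpp::List::create(
      Rcpp::Named("weights") = w, Rcpp::Named("means") = M,
      Rcpp::Named("covariances") = S,
      Rcpp::Named("logLik") = trace.empty() ? NA_REAL : trace.back(),
      Rcpp::Named("logLikTrace") = trace,
      Rcpp::Named("nIterations") = (int)trace.size(),
      Rcpp::Named("converged") = converged,
      Rcpp::Named("emptyComponent") = empty_component);
}
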