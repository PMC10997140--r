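#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Non-negative least squares by cyclic coordinate descent on the normal
// equations: minimise 0.5 x'Qx - c'x over x >= 0 with Q = A'A, c = A'b.
// Each coordinate update x_j <- max(0, x_j + (c_j - Q_j.x) / Q_jj) is the
// exact 1D minimiser, so the objective is non-increasing; convergence is
// declared when the KKT residual max_j (x_j > 0 ? |g_j| : max(g_j, 0))
// drops below tol * max(|c|, 1), with g = c - Qx.
// [[Rcpp::export]]
List nnls_cd(const arma::mat& Q, const arma::vec& c, int max_iter,
             double tol) {
  const int p = c.n_elem;
  arma::vec x(p, arma::fill::zeros);
  arma::vec g = c;  // gradient of -(objective): c - Qx, maintained incrementally
  const double scale = std::max(arma::abs(c).max(), 1.0);
  const double thresh = tol * scale;

  std::vector<double> obj_trace;
  obj_trace.reserve(64);
  bool converged = false;
  int sweep = 0;

  auto objective = [&]() {
    return 0.5 * arma::as_scalar(x.t() * Q * x) - arma::dot(c, x);
  };
  obj_trace.push_back(objective());

  for (sweep = 0; sweep < max_iter; ++sweep) {
    for (int j = 0; j < p; ++j) {
      const double qjj = Q(j, j);
      if (qjj <= 0.0) continue;  // all-zero column: weight stays 0
      double xj_new = x(j) + g(j) / qjj;
      if (xj_new < 0.0) xj_new = 0.0;
      const double delta = xj_new - x(j);
      if (delta != 0.0) {
        g -= delta * Q.col(j);
        x(j) = xj_new;
      }
    }
    obj_trace.push_back(objective());
    double kkt = 0.0;
    for (int j = 0; j < p; ++j) {
      const double viol = (x(j) > 0.0) ? std::abs(g(j))
                                       : std::max(g(j), 0.0);
      if (viol > kkt) kkt = viol;
    }
    if (kkt <= thresh) { converged = true; ++sweep; break; }
  }

  return List::create(_["x"] = x, _["converged"] = converged,
                      _["iterations"] = sweep,
                      _["objective_trace"] = obj_trace);
}
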