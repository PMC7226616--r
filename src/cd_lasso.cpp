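#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cyclic coordinate descent for the lasso
//   minimise (1/2n) * ||y - X b||^2 + lambda * ||b||_1
// over a decreasing lambda sequence with warm starts.
//
// X is expected already centred/standardised and y centred; columns with
// zero norm are left at coefficient zero. After each full sweep the solver
// iterates on the active set only until it stabilises, then re-checks with
// a full sweep; convergence is a full sweep whose largest absolute
// coefficient update is < tol.
// [[Rcpp::export]]
List cd_lasso_path(const NumericMatrix& X, const NumericVector& y,
                   const NumericVector& lambdas, double tol, int max_iter,
                   Nullable<NumericVector> beta_init = R_NilValue,
                   double dev_ratio_stop = 2.0) {
  const int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  NumericMatrix betas(p, L);
  IntegerVector iters(L);
  LogicalVector conv(L);

  const double* xp = &X(0, 0);       // column-major
  std::vector<double> b(p, 0.0);
  std::vector<double> r(y.begin(), y.end());
  std::vector<double> xx(p);         // X_j . X_j / n
  for (int j = 0; j < p; ++j) {
    const double* xj = xp + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xx[j] = s / n;
  }
  if (beta_init.isNotNull()) {
    NumericVector bi(beta_init);
    if (bi.size() != p) stop("beta_init length must equal ncol(X)");
    for (int j = 0; j < p; ++j) {
      b[j] = bi[j];
      if (b[j] != 0.0) {
        const double* xj = xp + (size_t)j * n;
        for (int i = 0; i < n; ++i) r[i] -= xj[i] * b[j];
      }
    }
  }

  double null_dev = 0.0;
  for (int i = 0; i < n; ++i) null_dev += y[i] * y[i];

  std::vector<int> active;
  active.reserve(p);

  int n_fitted = L;
  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    int it = 0;
    bool ok = false;

    auto update_one = [&](int j) -> double {
      if (xx[j] <= 0.0) return 0.0;
      const double* xj = xp + (size_t)j * n;
      double rho = 0.0;
      for (int i = 0; i < n; ++i) rho += xj[i] * r[i];
      rho = rho / n + xx[j] * b[j];
      double bn = 0.0;
      if (rho > lam)       bn = (rho - lam) / xx[j];
      else if (rho < -lam) bn = (rho + lam) / xx[j];
      const double d = bn - b[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
        b[j] = bn;
      }
      return std::fabs(d);
    };

    while (it < max_iter) {
      ++it;                                   // full sweep
      double maxdiff = 0.0;
      for (int j = 0; j < p; ++j) {
        const double ad = update_one(j);
        if (ad > maxdiff) maxdiff = ad;
      }
      if (maxdiff < tol) { ok = true; break; }
      // iterate the current active set to convergence before re-checking
      active.clear();
      for (int j = 0; j < p; ++j) if (b[j] != 0.0) active.push_back(j);
      while (it < max_iter) {
        ++it;
        double md = 0.0;
        for (size_t a = 0; a < active.size(); ++a) {
          const double ad = update_one(active[a]);
          if (ad > md) md = ad;
        }
        if (md < tol) break;
      }
    }
    iters[l] = it;
    conv[l] = ok;
    for (int j = 0; j < p; ++j) betas(j, l) = b[j];
    if (dev_ratio_stop < 1.0 && null_dev > 0.0) {
      double rss = 0.0;
      for (int i = 0; i < n; ++i) rss += r[i] * r[i];
      if (1.0 - rss / null_dev >= dev_ratio_stop) { n_fitted = l + 1; break; }
    }
  }

  return List::create(_["beta"] = betas, _["n_iter"] = iters,
                      _["converged"] = conv, _["n_fitted"] = n_fitted);
}
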