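// Coordinate-descent LASSO path solver and the stability-selection
// accumulator that drives it across jackknife subsamples.
//
// Objective (note: NOT divided by n):
//     0.5 * || y - X b ||^2  +  lambda * || b ||_1
// so lambda_max = max_j |x_j' y| gives the all-zero solution.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// One lambda: cyclic coordinate descent with warm-started b and residual r.
// cnorm holds the column sums of squares; columns with cnorm ~ 0 are frozen
// at zero (degenerate within-subsample constants).
static bool cd_solve(const arma::mat& X, arma::vec& r, arma::vec& b,
                     const arma::vec& cnorm, double lambda,
                     double tol, int maxit) {
  const arma::uword p = X.n_cols;
  for (int it = 0; it < maxit; ++it) {
    double maxdel = 0.0;
    for (arma::uword j = 0; j < p; ++j) {
      if (cnorm[j] <= 1e-12) continue;
      double bj = b[j];
      double z = arma::dot(X.col(j), r) + cnorm[j] * bj;
      double bn = soft_threshold(z, lambda) / cnorm[j];
      if (bn != bj) {
        r += X.col(j) * (bj - bn);
        b[j] = bn;
        double d = std::abs(bn - bj);
        if (d > maxdel) maxdel = d;
      }
    }
    if (maxdel < tol) return true;
  }
  return false;
}

// Full path over a decreasing lambda grid with warm starts.
// Returns p x nlambda coefficient matrix; attribute "converged" flags
// per-lambda convergence.
// [[Rcpp::export]]
NumericMatrix lasso_cd_path_cpp(const arma::mat& X, const arma::vec& y,
                                const arma::vec& lambda,
                                double tol, int maxit) {
  const arma::uword p = X.n_cols, L = lambda.n_elem;
  arma::vec cnorm = arma::sum(arma::square(X), 0).t();
  arma::vec b(p, arma::fill::zeros);
  arma::vec r = y;
  arma::mat B(p, L, arma::fill::zeros);
  LogicalVector conv(L);
  for (arma::uword l = 0; l < L; ++l) {
    conv[l] = cd_solve(X, r, b, cnorm, lambda[l], tol, maxit);
    B.col(l) = b;
  }
  NumericMatrix out = wrap(B);
  out.attr("converged") = conv;
  return out;
}

// Stability-selection accumulator.  X is the full (n x p) candidate block on
// the log10 scale, y the centered numeric group label.  smask / fmask hold
// 1-based kept indices per iteration (rows = iterations).  Per iteration the
// in-bag block is standardized (mean 0, unit sd, n-1 denominator), y is
// re-centered within the subsample, and a nlambda-point log-spaced grid from
// lambda_max down to lambda_min_ratio * lambda_max is solved.  A feature
// counts as selected when its coefficient is nonzero anywhere on the grid
// (decision_rule = 1) or at grid position fixed_index (decision_rule = 2).
// [[Rcpp::export]]
List stability_accumulate_cpp(const arma::mat& X, const arma::vec& y,
                              const IntegerMatrix& smask,
                              const IntegerMatrix& fmask,
                              int nlambda, double lambda_min_ratio,
                              int decision_rule, int fixed_index,
                              double tol, int maxit) {
  const arma::uword p = X.n_cols;
  const int iters = smask.nrow();
  const int ns = smask.ncol(), nf = fmask.ncol();

  arma::ivec eligible(p, arma::fill::zeros);
  arma::ivec selected(p, arma::fill::zeros);
  arma::vec coefsum(p, arma::fill::zeros);
  int skipped = 0;

  arma::uvec rows(ns), cols(nf);
  for (int it = 0; it < iters; ++it) {
    for (int i = 0; i < ns; ++i) rows[i] = smask(it, i) - 1;
    for (int i = 0; i < nf; ++i) cols[i] = fmask(it, i) - 1;

    arma::uvec scols = arma::sort(cols);
    arma::mat Xs = X.submat(rows, scols);
    arma::vec ys = y.elem(rows);
    ys -= arma::mean(ys);

    // standardize columns; zero-variance columns stay identically zero
    arma::rowvec m = arma::mean(Xs, 0);
    Xs.each_row() -= m;
    arma::rowvec sd = arma::sqrt(arma::sum(arma::square(Xs), 0) / (ns - 1.0));
    for (int j = 0; j < nf; ++j) {
      if (sd[j] > 1e-12) Xs.col(j) /= sd[j];
      else Xs.col(j).zeros();
    }

    for (int j = 0; j < nf; ++j) eligible[scols[j]] += 1;

    arma::vec corr = Xs.t() * ys;
    double lmax = arma::abs(corr).max();
    if (!(lmax > 0)) continue;

    arma::vec grid = arma::exp(arma::linspace(
        std::log(lmax), std::log(lambda_min_ratio * lmax), nlambda));

    arma::vec cnorm = arma::sum(arma::square(Xs), 0).t();
    arma::vec b(nf, arma::fill::zeros);
    arma::vec r = ys;
    arma::vec absmax(nf, arma::fill::zeros);
    arma::uvec hit(nf, arma::fill::zeros);
    bool ok = true;
    for (int l = 0; l < nlambda; ++l) {
      bool conv = cd_solve(Xs, r, b, cnorm, grid[l], tol, maxit);
      if (!conv) {  // retry once from cold start, then give up on iteration
        b.zeros(); r = ys;
        conv = cd_solve(Xs, r, b, cnorm, grid[l], tol, 2 * maxit);
        if (!conv) { ok = false; break; }
      }
      bool record = (decision_rule == 1) || (l == fixed_index - 1);
      if (record) {
        for (int j = 0; j < nf; ++j) {
          double a = std::abs(b[j]);
          if (a > 1e-9) { hit[j] = 1; if (a > absmax[j]) absmax[j] = a; }
        }
      }
    }
    if (!ok) { skipped += 1; continue; }
    for (int j = 0; j < nf; ++j) {
      if (hit[j]) {
        selected[scols[j]] += 1;
        coefsum[scols[j]] += absmax[j];
      }
    }
  }

  return List::create(_["eligible"] = wrap(eligible),
                      _["selected"] = wrap(selected),
                      _["coefsum"] = wrap(coefsum),
                      _["skipped"] = skipped);
}
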