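#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the penalized least-squares objective
//
//   || y - X b ||_2^2  +  lambda * ( a * ||b||_1  +  (1 - a) * ||b||_2^2 )
//
// written on the Gram scale: G = X'X, xty = X'y.  Note the absence of any
// 1/2 or 1/n factor on either term; the coordinate update is therefore
//
//   b_j <- S( xty_j - sum_{k != j} G_jk b_k , lambda * a / 2 ) /
//          ( G_jj + lambda * (1 - a) )
//
// where S is the soft-threshold operator.  The objective is convex (strictly
// so for a < 1 or full-rank G), so cyclic descent converges to the minimizer.

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// [[Rcpp::export(name = ".cd_enet_gram")]]
NumericVector cd_enet_gram(NumericMatrix G, NumericVector xty,
                           double lambda, double a,
                           NumericVector init,
                           double tol = 1e-12, int maxit = 100000) {
  const int k = G.ncol();
  NumericVector b = clone(init);
  const double thr = lambda * a / 2.0;
  const double l2 = lambda * (1.0 - a);

  // residual correlations: r_j = xty_j - sum_k G_jk b_k
  std::vector<double> r(k);
  for (int j = 0; j < k; ++j) {
    double s = xty[j];
    for (int m = 0; m < k; ++m) s -= G(m, j) * b[m];
    r[j] = s;
  }

  for (int it = 0; it < maxit; ++it) {
    double delta = 0.0;
    for (int j = 0; j < k; ++j) {
      const double denom = G(j, j) + l2;
      if (denom <= 0.0) { continue; } // all-zero column under pure lasso
      const double z = r[j] + G(j, j) * b[j];
      const double bj = soft(z, thr) / denom;
      const double d = bj - b[j];
      if (d != 0.0) {
        for (int m = 0; m < k; ++m) r[m] -= G(j, m) * d;
        b[j] = bj;
        double ad = std::abs(d);
        if (ad > delta) delta = ad;
      }
    }
    if (delta < tol) return b;
  }
  warning("coordinate descent reached maxit without meeting tol");
  return b;
}

// Evaluate a whole (lambda, a) grid with warm starts, returning a k x n_grid
// matrix of solutions.  Grid points are supplied as parallel vectors; within
// a fixed `a`, callers should order lambdas decreasingly for best warm starts.
// [[Rcpp::export(name = ".cd_enet_gram_grid")]]
NumericMatrix cd_enet_gram_grid(NumericMatrix G, NumericVector xty,
                                NumericVector lambdas, NumericVector as,
                                double tol = 1e-12, int maxit = 100000) {
  const int k = G.ncol();
  const int ng = lambdas.size();
  NumericMatrix out(k, ng);
  NumericVector warm(k); // zeros
  double prev_a = as[0];
  for (int g = 0; g < ng; ++g) {
    if (as[g] != prev_a) { // new a-block: restart from zero
      for (int j = 0; j < k; ++j) warm[j] = 0.0;
      prev_a = as[g];
    }
    NumericVector b = cd_enet_gram(G, xty, lambdas[g], as[g], warm, tol, maxit);
    for (int j = 0; j < k; ++j) { out(j, g) = b[j]; warm[j] = b[j]; }
  }
  return out;
}
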