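#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double softThreshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// L1-penalised precision estimation by block coordinate descent on the
// covariance (Friedman-style graphical lasso). Each sweep solves, for every
// column j, the lasso subproblem
//   min_beta 1/2 beta' W11 beta - s12' beta + lambda |beta|_1
// by coordinate descent, then updates the working covariance W. The
// precision matrix is recovered from the final regression coefficients.
// Diagonal penalisation shifts the working diagonal by lambda.
// [[Rcpp::export]]
List glasso_cpp(NumericMatrix S, double lambda, bool penalizeDiagonal,
                double tol, int maxit, int innerMaxit) {
  const int n = S.ncol();
  NumericMatrix W(n, n), B(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) W(i, j) = S(i, j);
  if (penalizeDiagonal)
    for (int i = 0; i < n; ++i) W(i, i) += lambda;

  // mean |off-diagonal of S| sets the convergence scale
  double offScale = 0.0;
  int nOff = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j) { offScale += std::fabs(S(i, j)); ++nOff; }
  offScale = (nOff > 0) ? offScale / nOff : 0.0;
  if (offScale < 1e-12) offScale = 1e-12;
  const double innerTol = 1e-10;

  int sweeps = 0;
  bool converged = (n == 1);
  for (int it = 0; it < maxit && !converged; ++it) {
    double maxChange = 0.0;
    for (int j = 0; j < n; ++j) {
      // lasso coordinate descent for column j, warm-started from B(,j)
      for (int inner = 0; inner < innerMaxit; ++inner) {
        double del = 0.0;
        for (int k = 0; k < n; ++k) {
          if (k == j) continue;
          double r = S(k, j);
          for (int l = 0; l < n; ++l) {
            if (l == j || l == k) continue;
            r -= W(l, k) * B(l, j);
          }
          double bNew = softThreshold(r, lambda) / W(k, k);
          double d = std::fabs(bNew - B(k, j));
          if (d > del) del = d;
          B(k, j) = bNew;
        }
        if (del < innerTol) break;
      }
      // w12 <- W11 beta
      for (int k = 0; k < n; ++k) {
        if (k == j) continue;
        double w = 0.0;
        for (int l = 0; l < n; ++l) {
          if (l == j) continue;
          w += W(k, l) * B(l, j);
        }
        double d = std::fabs(w - W(k, j));
        if (d > maxChange) maxChange = d;
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    ++sweeps;
    if (maxChange < tol * offScale) converged = true;
  }

  // recover Theta from the regression coefficients
  NumericMatrix Theta(n, n);
  for (int j = 0; j < n; ++j) {
    double denom = W(j, j);
    for (int k = 0; k < n; ++k)
      if (k != j) denom -= W(k, j) * B(k, j);
    double tjj = 1.0 / denom;
    Theta(j, j) = tjj;
    for (int k = 0; k < n; ++k)
      if (k != j) Theta(k, j) = -B(k, j) * tjj;
  }
  for (int i = 0; i < n; ++i) // symmetrise numerical asymmetry
    for (int j = i + 1; j < n; ++j) {
      double v = 0.5 * (Theta(i, j) + Theta(j, i));
      Theta(i, j) = v;
      Theta(j, i) = v;
    }

  // duality gap: tr(S Theta) - n + lambda * ||Theta||_1 (penalised entries)
  double trST = 0.0, pen = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      trST += S(i, j) * Theta(i, j);
      if (i != j || penalizeDiagonal) pen += std::fabs(Theta(i, j));
    }
  double gap = trST - n + lambda * pen;

  return List::create(_["theta"] = Theta, _["w"] = W,
                      _["sweeps"] = sweeps, _["converged"] = converged,
                      _["gap"] = gap);
}
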