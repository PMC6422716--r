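#include <Rcpp.h>
using namespace Rcpp;

// Graphical LASSO by block coordinate descent (Friedman-Hastie-Tibshirani).
// Maximizes log det(Theta) - tr(S Theta) - lambda * sum_{i!=j} |Theta_ij|;
// the L1 penalty is applied to off-diagonal entries only, so diag(W) = diag(S).
// Each column update solves a lasso problem on the current covariance estimate
// W11 by cyclic coordinate descent with exact soft-thresholding, which is what
// produces exact zeros in the recovered precision matrix.

static inline double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Lambda is a full penalty matrix: a constant matrix gives the ordinary
// graphical LASSO; a 0/Inf pattern gives the support-constrained MLE used
// to refit a selected model without shrinkage.
// [[Rcpp::export(name = ".glasso_cd")]]
List glasso_cd(NumericMatrix S, NumericMatrix Lambda,
               NumericMatrix W_init, NumericMatrix B_init, bool warm,
               double tol = 1e-6, int max_iter = 500, int max_inner = 500) {
  const int p = S.nrow();
  NumericMatrix W(p, p), B(p, p);

  if (warm) {
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j) {
        W(i, j) = W_init(i, j);
        B(i, j) = B_init(i, j);
      }
    for (int i = 0; i < p; ++i) W(i, i) = S(i, i); // diagonal never penalized
  } else {
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j) W(i, j) = S(i, j);
  }

  // scale for the convergence test: mean |off-diagonal of S|
  double s_bar = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) s_bar += std::fabs(S(i, j));
  s_bar /= std::max(1, p * (p - 1));
  const double thr = tol * std::max(s_bar, 1e-12);

  std::vector<double> beta(p), grad(p);
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < max_iter && !converged; ++iter) {
    double max_delta = 0.0;
    for (int j = 0; j < p; ++j) {
      // lasso on column j: min 0.5 b' W11 b - s12' b + lambda |b|_1
      for (int k = 0; k < p; ++k) beta[k] = B(k, j);
      beta[j] = 0.0;
      for (int inner = 0; inner < max_inner; ++inner) {
        double delta = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double g = S(k, j);
          for (int l = 0; l < p; ++l) {
            if (l == j || l == k) continue;
            g -= W(k, l) * beta[l];
          }
          double bk = soft_threshold(g, Lambda(k, j)) / W(k, k);
          double d = std::fabs(bk - beta[k]);
          if (d > delta) delta = d;
          beta[k] = bk;
        }
        if (delta < thr) break;
      }
      // w12 = W11 * beta
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        double w = 0.0;
        for (int l = 0; l < p; ++l) {
          if (l == j) continue;
          w += W(k, l) * beta[l];
        }
        double d = std::fabs(w - W(k, j));
        if (d > max_delta) max_delta = d;
        W(k, j) = w;
        W(j, k) = w;
        B(k, j) = beta[k];
      }
    }
    if (max_delta < thr) converged = true;
  }

  // Recover Theta from the regression coefficients:
  // theta_jj = 1 / (w_jj - w12' beta_j); theta_12 = -beta_j * theta_jj.
  NumericMatrix Theta(p, p);
  for (int j = 0; j < p; ++j) {
    double dot = 0.0;
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      dot += W(k, j) * B(k, j);
    }
    double tjj = 1.0 / (W(j, j) - dot);
    Theta(j, j) = tjj;
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      Theta(k, j) = (B(k, j) == 0.0) ? 0.0 : -B(k, j) * tjj;
    }
  }

  return List::create(_["w"] = W, _["theta"] = Theta, _["beta"] = B,
                      _["iterations"] = iter, _["converged"] = converged);
}
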