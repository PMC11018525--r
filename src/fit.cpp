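// Core optimizer for the per-gene non-negative Poisson regression.
//
// Loss (per-cell average):
//   L(w, e) = (1/N) sum_i [ exp(X_i w + e) - y_i (X_i w + e) ] + alpha ||w||^2
//
// Minimized by full-batch Adam with projection of w onto the non-negative
// orthant after every step, followed by an optional active-set projected
// Newton polish that drives the KKT residual to tight tolerance.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double pois_loss(const mat& X, const vec& y, const vec& w,
                        double eps, double alpha) {
  vec eta = X * w + eps;
  return mean(exp(eta) - y % eta) + alpha * dot(w, w);
}

// [[Rcpp::export]]
double cpp_poisson_loss(const arma::mat& X, const arma::vec& y,
                        const arma::vec& w, double eps, double alpha) {
  return pois_loss(X, y, w, eps, alpha);
}

// KKT residual under the non-negativity constraint: for free coordinates the
// penalized gradient must vanish; for coordinates at the bound it must be
// non-negative (no descent direction into the feasible set).
static double kkt_residual(const vec& g_w, double g_e, const vec& w,
                           bool nonneg) {
  double r = std::abs(g_e);
  for (uword j = 0; j < w.n_elem; ++j) {
    double v = (nonneg && w[j] <= 0.0) ? std::max(0.0, -g_w[j])
                                       : std::abs(g_w[j]);
    r = std::max(r, v);
  }
  return r;
}

// [[Rcpp::export]]
Rcpp::List cpp_fit_poisson(const arma::mat& X, const arma::vec& y,
                           double alpha, double lr, int max_iter,
                           double tol, bool nonneg, double eps_init,
                           double eps_min, bool polish, int polish_max_iter,
                           double polish_tol) {
  const uword N = X.n_rows, P = X.n_cols;
  vec w(P, fill::zeros);
  double eps = eps_init;

  // Adam state over the concatenated (w, eps) parameter vector
  vec m_w(P, fill::zeros), v_w(P, fill::zeros);
  double m_e = 0.0, v_e = 0.0;
  const double b1 = 0.9, b2 = 0.999, adam_eps = 1e-8;

  double loss_prev = pois_loss(X, y, w, eps, alpha);
  if (!std::isfinite(loss_prev))
    Rcpp::stop("non-finite loss at initialization");
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    vec mu = exp(X * w + eps);
    vec resid = mu - y;
    vec g_w = X.t() * resid / double(N) + 2.0 * alpha * w;
    double g_e = mean(resid);

    double bc1 = 1.0 - std::pow(b1, iter);
    double bc2 = 1.0 - std::pow(b2, iter);
    m_w = b1 * m_w + (1.0 - b1) * g_w;
    v_w = b2 * v_w + (1.0 - b2) * square(g_w);
    m_e = b1 * m_e + (1.0 - b1) * g_e;
    v_e = b2 * v_e + (1.0 - b2) * g_e * g_e;

    w -= lr * (m_w / bc1) / (sqrt(v_w / bc2) + adam_eps);
    eps -= lr * (m_e / bc1) / (std::sqrt(v_e / bc2) + adam_eps);
    if (nonneg) w.transform([](double x) { return x < 0.0 ? 0.0 : x; });
    if (eps < eps_min) eps = eps_min;

    double loss = pois_loss(X, y, w, eps, alpha);
    if (!std::isfinite(loss))
      Rcpp::stop("Poisson fit diverged (non-finite loss); try a smaller learning rate");
    if (std::abs(loss_prev - loss) <
        tol * std::max(1.0, std::abs(loss_prev))) {
      converged = true;
      loss_prev = loss;
      break;
    }
    loss_prev = loss;
  }

  // Active-set projected Newton refinement: exact curvature drives the KKT
  // residual far below what a first-order stop on the loss can guarantee.
  int polish_iter = 0;
  if (polish) {
    for (polish_iter = 1; polish_iter <= polish_max_iter; ++polish_iter) {
      vec mu = exp(X * w + eps);
      vec resid = mu - y;
      vec g_w = X.t() * resid / double(N) + 2.0 * alpha * w;
      double g_e = mean(resid);
      if (kkt_residual(g_w, g_e, w, nonneg) < polish_tol) break;

      // free set: positive coordinates, and bound coordinates whose gradient
      // points into the feasible region
      uvec free_idx;
      if (nonneg) {
        free_idx = find(w > 0.0 || g_w < 0.0);
      } else {
        free_idx = regspace<uvec>(0, P - 1);
      }
      uword k = free_idx.n_elem;

      vec d(k + 1);
      if (k == 0) {
        d[0] = -g_e / std::max(mean(mu), 1e-12);
      } else {
        mat Xf = X.cols(free_idx);
        mat H(k + 1, k + 1);
        mat XtD = Xf.t() * (Xf.each_col() % mu) / double(N);
        H.submat(0, 0, k - 1, k - 1) =
            XtD + 2.0 * alpha * eye<mat>(k, k);
        vec xmu = Xf.t() * mu / double(N);
        H.submat(0, k, k - 1, k) = xmu;
        H.submat(k, 0, k, k - 1) = xmu.t();
        H(k, k) = mean(mu);
        H.diag() += 1e-12;

        vec g(k + 1);
        g.head(k) = g_w.elem(free_idx);
        g[k] = g_e;
        if (!solve(d, H, -g,
                   solve_opts::likely_sympd + solve_opts::no_approx)) {
          d = -g;  // fall back to a gradient step if the system is singular
        }
      }

      double t = 1.0;
      double base = pois_loss(X, y, w, eps, alpha);
      vec w_new = w;
      double eps_new = eps;
      bool improved = false;
      for (int ls = 0; ls < 40; ++ls) {
        w_new = w;
        w_new.elem(free_idx) += t * d.head(k);
        if (nonneg)
          w_new.transform([](double x) { return x < 0.0 ? 0.0 : x; });
        eps_new = std::max(eps + t * d[k], eps_min);
        double lnew = pois_loss(X, y, w_new, eps_new, alpha);
        if (std::isfinite(lnew) && lnew <= base + 1e-12) {
          improved = lnew < base - 1e-15 || ls == 0;
          break;
        }
        t *= 0.5;
      }
      if (!improved && t < 1.0) break;  // no progress possible
      w = w_new;
      eps = eps_new;
    }
    loss_prev = pois_loss(X, y, w, eps, alpha);
  }

  vec mu = exp(X * w + eps);
  vec resid = mu - y;
  vec g_w = X.t() * resid / double(N) + 2.0 * alpha * w;
  double g_e = mean(resid);

  return Rcpp::List::create(
      Rcpp::Named("w") = w, Rcpp::Named("epsilon") = eps,
      Rcpp::Named("loss") = loss_prev, Rcpp::Named("n_iter") = iter,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("kkt") = kkt_residual(g_w, g_e, w, nonneg));
}
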