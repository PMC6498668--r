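// Hot numerical kernels: proximal-gradient iteration for the joint
// two-condition sparse regression, the closed-form two-variable fused-lasso
// prox, and a coordinate-descent lasso in the same (no 1/n) objective
// scaling.  All kernels work on Gram matrices (Z'Z, Z'y) so that whole-
// network drivers can share one crossproduct per data split.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft_thr(double x, double a) {
  if (x > a) return x - a;
  if (x < -a) return x + a;
  return 0.0;
}

// Closed-form minimiser of
//   lam1eff(|b| + |bt|) + lam2eff|b - bt| + ((b - t)^2 + (bt - tt)^2)/2
// i.e. the per-coordinate prox of the nonsmooth penalty, obtained by first
// solving the lam1eff = 0 fusion problem and then soft-thresholding.
static inline void prox_pair_1(double t, double tt, double lam1eff,
                               double lam2eff, double &b, double &bt) {
  double d = t - tt;
  if (std::abs(d) <= 2.0 * lam2eff) {
    b = bt = 0.5 * (t + tt);
  } else if (d > 2.0 * lam2eff) {
    b = t - lam2eff;
    bt = tt + lam2eff;
  } else {
    b = t + lam2eff;
    bt = tt - lam2eff;
  }
  b = soft_thr(b, lam1eff);
  bt = soft_thr(bt, lam1eff);
}

// [[Rcpp::export]]
NumericMatrix cpp_prox_pair(NumericVector t, NumericVector tt,
                            double lam1eff, double lam2eff) {
  int p = t.size();
  NumericMatrix out(p, 2);
  for (int j = 0; j < p; ++j) {
    double b, bt;
    prox_pair_1(t[j], tt[j], lam1eff, lam2eff, b, bt);
    out(j, 0) = b;
    out(j, 1) = bt;
  }
  return out;
}

static double joint_objective(const arma::vec &beta, const arma::vec &betat,
                              const arma::mat &Ga, const arma::vec &ca,
                              const arma::mat &Gb, const arma::vec &cb,
                              double yty, double lam1, double lam2) {
  double quad = yty - 2.0 * arma::dot(ca, beta) +
                arma::dot(beta, Ga * beta) - 2.0 * arma::dot(cb, betat) +
                arma::dot(betat, Gb * betat);
  double pen = lam1 * (arma::norm(beta, 1) + arma::norm(betat, 1)) +
               lam2 * arma::norm(beta - betat, 1);
  return quad + pen;
}

// Proximal gradient solver in Gram form.  `yty` is |y|^2 + |y~|^2 so that
// the recorded objective equals the residual-sum-of-squares objective.
// [[Rcpp::export]]
List cpp_joint_pg(const arma::mat &Ga, const arma::vec &ca,
                  const arma::mat &Gb, const arma::vec &cb, double yty,
                  double lam1, double lam2, double step,
                  arma::vec beta, arma::vec betat,
                  double tol, int max_iter, bool track_objective) {
  const int p = beta.n_elem;
  const double l1e = lam1 * step;
  const double l2e = lam2 * step;
  std::vector<double> obj;
  if (track_objective) {
    obj.reserve(64);
    obj.push_back(joint_objective(beta, betat, Ga, ca, Gb, cb, yty,
                                  lam1, lam2));
  }
  bool converged = false;
  int iter = 0;
  arma::vec t(p), tt(p);
  for (iter = 1; iter <= max_iter; ++iter) {
    // gradient step: t = beta - step * 2 (Ga beta - ca)
    t = beta - step * 2.0 * (Ga * beta - ca);
    tt = betat - step * 2.0 * (Gb * betat - cb);
    double num = 0.0, den = 0.0;
    for (int j = 0; j < p; ++j) {
      double b, bt;
      prox_pair_1(t[j], tt[j], l1e, l2e, b, bt);
      double db = b - beta[j], dbt = bt - betat[j];
      num += db * db + dbt * dbt;
      den += beta[j] * beta[j] + betat[j] * betat[j];
      beta[j] = b;
      betat[j] = bt;
    }
    if (track_objective)
      obj.push_back(joint_objective(beta, betat, Ga, ca, Gb, cb, yty,
                                    lam1, lam2));
    double rel = std::sqrt(num) / std::max(1.0, std::sqrt(den));
    if (rel <= tol) {
      converged = true;
      break;
    }
  }
  if (iter > max_iter) iter = max_iter;
  return List::create(_["beta"] = beta, _["beta_tilde"] = betat,
                      _["objective"] = obj, _["n_iter"] = iter,
                      _["converged"] = converged);
}

// Coordinate-descent lasso for  |y - Z b|^2 + lam |b|_1  in Gram form
// (G = Z'Z, c = Z'y).  Stops when the KKT subgradient residual is within
// kkt_tol * max(1, max|c|).
// [[Rcpp::export]]
List cpp_lasso_cd(const arma::mat &G, const arma::vec &c, double lam,
                  arma::vec b, double kkt_tol, int max_sweeps) {
  const int p = b.n_elem;
  const double half = lam / 2.0;
  const double scale = std::max(1.0, c.n_elem ? arma::abs(c).max() : 1.0);
  // residual gradient bookkeeping: g = G b - c maintained incrementally
  arma::vec g = G * b - c;
  bool converged = false;
  int sweep = 0;
  for (sweep = 1; sweep <= max_sweeps; ++sweep) {
    for (int j = 0; j < p; ++j) {
      double gjj = G(j, j);
      if (gjj <= 0.0) { // zero column: coefficient stays 0
        if (b[j] != 0.0) {
          g -= b[j] * G.col(j);
          b[j] = 0.0;
        }
        continue;
      }
      double old = b[j];
      double r = gjj * old - g[j]; // c_j - sum_{k != j} G_jk b_k
      double bn = soft_thr(r, half) / gjj;
      if (bn != old) {
        g += (bn - old) * G.col(j);
        b[j] = bn;
      }
    }
    // KKT check: 2 g_j + lam s_j = 0, s_j subgradient of |b_j|
    double worst = 0.0;
    for (int j = 0; j < p; ++j) {
      double v;
      if (b[j] > 0.0)
        v = std::abs(2.0 * g[j] + lam);
      else if (b[j] < 0.0)
        v = std::abs(2.0 * g[j] - lam);
      else
        v = std::max(0.0, std::abs(2.0 * g[j]) - lam);
      if (v > worst) worst = v;
    }
    if (worst <= kkt_tol * scale) {
      converged = true;
      break;
    }
  }
  if (sweep > max_sweeps) sweep = max_sweeps;
  return List::create(_["b"] = b, _["n_sweeps"] = sweep,
                      _["converged"] = converged);
}
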