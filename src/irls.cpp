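#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Weighted logistic regression by iteratively reweighted least squares.
// Matches stats::glm(family = binomial) with prior (case) weights for 0/1
// responses: same deviance, same AIC convention (deviance + 2 * rank).
// Used by the GLM member engine, where stepwise selection refits many
// nested models; correctness against stats::glm is asserted in the tests.
// `beta0` optionally warm-starts the iteration (e.g. from a neighbouring
// model in the stepwise search).
// [[Rcpp::export]]
List irls_logit(const arma::mat& X, const arma::vec& y, const arma::vec& w,
                int maxit = 30, double tol = 1e-8,
                Nullable<NumericVector> beta0 = R_NilValue) {
  const arma::uword p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  if (beta0.isNotNull()) {
    NumericVector b0(beta0);
    if (b0.size() == (int)p) beta = as<arma::vec>(b0);
  }
  arma::vec eta = X * beta;
  double dev = arma::datum::inf;
  bool converged = false;
  bool ok = true;

  for (int it = 0; it < maxit; ++it) {
    arma::vec mu = 1.0 / (1.0 + arma::exp(-arma::clamp(eta, -30.0, 30.0)));
    mu = arma::clamp(mu, 1e-10, 1.0 - 1e-10);
    arma::vec v = mu % (1.0 - mu);            // variance function
    arma::vec W = w % v;
    arma::vec z = eta + (y - mu) / v;         // working response
    arma::mat Xw = X.each_col() % W;
    arma::mat XtWX = X.t() * Xw;
    arma::vec XtWz = Xw.t() * z;
    arma::vec beta_new;
    bool solved = arma::solve(beta_new, XtWX, XtWz,
                              arma::solve_opts::no_approx);
    if (!solved || !beta_new.is_finite()) { ok = false; break; }
    beta = beta_new;
    eta = X * beta;
    arma::vec mu2 = 1.0 / (1.0 + arma::exp(-arma::clamp(eta, -30.0, 30.0)));
    mu2 = arma::clamp(mu2, 1e-10, 1.0 - 1e-10);
    double dev_new = -2.0 * arma::accu(
        w % (y % arma::log(mu2) + (1.0 - y) % arma::log(1.0 - mu2)));
    if (std::abs(dev - dev_new) / (std::abs(dev_new) + 0.1) < tol) {
      dev = dev_new;
      converged = true;
      break;
    }
    dev = dev_new;
  }

  return List::create(_["coefficients"] = beta,
                      _["deviance"] = dev,
                      _["converged"] = converged,
                      _["ok"] = ok);
}

namespace {
struct IrlsFit {
  arma::vec beta;
  double dev;
  bool ok;
};

IrlsFit irls_fit(const arma::mat& X, const arma::vec& y, const arma::vec& w,
                 const arma::vec* beta0, int maxit, double tol) {
  IrlsFit out;
  out.beta.zeros(X.n_cols);
  if (beta0 && beta0->n_elem == X.n_cols) out.beta = *beta0;
  arma::vec eta = X * out.beta;
  double dev = arma::datum::inf;
  out.ok = true;
  for (int it = 0; it < maxit; ++it) {
    arma::vec mu = 1.0 / (1.0 + arma::exp(-arma::clamp(eta, -30.0, 30.0)));
    mu = arma::clamp(mu, 1e-10, 1.0 - 1e-10);
    arma::vec v = mu % (1.0 - mu);
    arma::vec W = w % v;
    arma::vec z = eta + (y - mu) / v;
    arma::mat Xw = X.each_col() % W;
    arma::vec beta_new;
    if (!arma::solve(beta_new, X.t() * Xw, Xw.t() * z,
                     arma::solve_opts::no_approx) ||
        !beta_new.is_finite()) {
      out.ok = false;
      break;
    }
    out.beta = beta_new;
    eta = X * out.beta;
    arma::vec mu2 = 1.0 / (1.0 + arma::exp(-arma::clamp(eta, -30.0, 30.0)));
    mu2 = arma::clamp(mu2, 1e-10, 1.0 - 1e-10);
    double dev_new = -2.0 * arma::accu(
        w % (y % arma::log(mu2) + (1.0 - y) % arma::log(1.0 - mu2)));
    if (std::abs(dev - dev_new) / (std::abs(dev_new) + 0.1) < tol) {
      dev = dev_new;
      break;
    }
    dev = dev_new;
  }
  out.dev = dev;
  return out;
}

arma::mat active_design(const arma::mat& Xterms,
                        const std::vector<int>& active) {
  arma::uword k = 0;
  for (size_t j = 0; j < active.size(); ++j) k += active[j];
  arma::mat X(Xterms.n_rows, k + 1);
  X.col(0).ones();
  arma::uword c = 1;
  for (size_t j = 0; j < active.size(); ++j)
    if (active[j]) X.col(c++) = Xterms.col(j);
  return X;
}
}  // namespace

// Bidirectional stepwise AIC selection over the columns of `Xterms`
// (candidate terms; the intercept is always kept), starting from the full
// model.  Each step evaluates every single-term addition and removal and
// takes the best one while it improves AIC by more than `aic_tol`.
// AIC = deviance + 2 * n_coefficients, consistent with stats::glm for 0/1
// responses.  Mirrors the R reference implementation used as its oracle.
// [[Rcpp::export]]
List stepwise_logit_cpp(const arma::mat& Xterms, const arma::vec& y,
                        const arma::vec& w, int maxit = 25,
                        double tol = 1e-8, double aic_tol = 1e-4,
                        int max_steps = 0) {
  const int K = Xterms.n_cols;
  if (max_steps <= 0) max_steps = 2 * K;
  std::vector<int> active(K, 1);

  IrlsFit cur = irls_fit(active_design(Xterms, active), y, w, nullptr,
                         maxit, tol);
  if (!cur.ok)
    return List::create(_["ok"] = false);
  int n_active = K;
  double cur_aic = cur.dev + 2.0 * (n_active + 1);

  for (int step = 0; step < max_steps; ++step) {
    double best_aic = cur_aic;
    int best_j = -1;
    IrlsFit best_fit;
    for (int j = 0; j < K; ++j) {
      std::vector<int> cand = active;
      cand[j] = 1 - cand[j];
      // warm start: current coefficients mapped onto the candidate design
      arma::mat Xc = active_design(Xterms, cand);
      arma::vec warm(Xc.n_cols, arma::fill::zeros);
      warm(0) = cur.beta(0);
      {
        arma::uword cc = 1, co = 1;
        for (int t = 0; t < K; ++t) {
          if (cand[t] && active[t]) warm(cc) = cur.beta(co);
          if (cand[t]) ++cc;
          if (active[t]) ++co;
        }
      }
      IrlsFit f = irls_fit(Xc, y, w, &warm, maxit, tol);
      if (!f.ok) continue;
      int na = 0;
      for (int t = 0; t < K; ++t) na += cand[t];
      double aic = f.dev + 2.0 * (na + 1);
      if (aic < best_aic - aic_tol) {
        best_aic = aic;
        best_j = j;
        best_fit = f;
      }
    }
    if (best_j < 0) break;
    active[best_j] = 1 - active[best_j];
    cur = best_fit;
    cur_aic = best_aic;
  }

  // expand coefficients to full term vector (0 for inactive)
  arma::vec beta_full(K + 1, arma::fill::zeros);
  beta_full(0) = cur.beta(0);
  arma::uword c = 1;
  for (int j = 0; j < K; ++j)
    if (active[j]) beta_full(j + 1) = cur.beta(c++);

  LogicalVector act(K);
  for (int j = 0; j < K; ++j) act[j] = active[j] == 1;
  return List::create(_["ok"] = true,
                      _["coefficients"] = beta_full,
                      _["active"] = act,
                      _["deviance"] = cur.dev,
                      _["aic"] = cur_aic);
}
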