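// IRLS kernels for the marker-by-transcript likelihood-ratio scans:
// negative-binomial GLM with fixed overdispersion (log link) and logistic
// regression. The tight loops over markers live here; model setup, theta
// estimation and inference wrappers are in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double ETA_CAP = 30.0;

static double nb_loglik(const vec& y, const vec& mu, double theta) {
  double ll = 0.0;
  const double lgt = std::lgamma(theta);
  const double tlt = theta * std::log(theta);
  for (uword i = 0; i < y.n_elem; ++i) {
    ll += std::lgamma(y[i] + theta) - lgt - std::lgamma(y[i] + 1.0) + tlt -
          (y[i] + theta) * std::log(mu[i] + theta);
    if (y[i] > 0) ll += y[i] * std::log(mu[i]);
  }
  return ll;
}

// IRLS for NB with fixed theta; returns convergence flag, updates beta/ll.
static bool nb_irls(const vec& y, const mat& X, double theta, vec& beta,
                    double& ll, int max_iter = 100, double tol = 1e-8) {
  vec eta = clamp(X * beta, -ETA_CAP, ETA_CAP);
  vec mu = exp(eta);
  ll = nb_loglik(y, mu, theta);
  for (int it = 0; it < max_iter; ++it) {
    vec w = mu * theta / (mu + theta);
    vec z = eta + (y - mu) / mu;
    mat Xw = X.each_col() % w;
    mat A = X.t() * Xw;
    vec b = Xw.t() * z;
    vec beta_new;
    bool ok = solve(beta_new, A, b, solve_opts::no_approx);
    if (!ok) return false;
    vec eta_new = clamp(X * beta_new, -ETA_CAP, ETA_CAP);
    vec mu_new = exp(eta_new);
    double ll_new = nb_loglik(y, mu_new, theta);
    // step-halve if the likelihood drops (rare, near-separated designs)
    int halves = 0;
    while (ll_new < ll - 1e-10 && halves < 10) {
      beta_new = 0.5 * (beta_new + beta);
      eta_new = clamp(X * beta_new, -ETA_CAP, ETA_CAP);
      mu_new = exp(eta_new);
      ll_new = nb_loglik(y, mu_new, theta);
      ++halves;
    }
    double delta = std::fabs(ll_new - ll);
    beta = beta_new; eta = eta_new; mu = mu_new; ll = ll_new;
    if (delta < tol) return true;
  }
  return false;
}

// observed-information SE for each coefficient
static vec nb_obs_se(const vec& y, const mat& X, const vec& beta,
                     double theta) {
  vec mu = exp(clamp(X * beta, -ETA_CAP, ETA_CAP));
  vec w = (y + theta) % mu * theta / square(mu + theta);
  mat info = X.t() * (X.each_col() % w);
  mat cov;
  if (!inv_sympd(cov, info)) {
    if (!pinv(cov, info)) return vec(beta.n_elem, fill::value(NA_REAL));
  }
  return sqrt(cov.diag());
}

// [[Rcpp::export]]
Rcpp::List cpp_nb_fit(const arma::vec& y, const arma::mat& X, double theta,
                      Rcpp::Nullable<Rcpp::NumericVector> beta_init =
                          R_NilValue) {
  vec beta(X.n_cols, fill::zeros);
  if (beta_init.isNotNull()) {
    beta = Rcpp::as<vec>(beta_init.get());
  } else {
    beta[0] = std::log(mean(y) + 1e-8);
  }
  double ll = 0.0;
  bool conv = nb_irls(y, X, theta, beta, ll);
  vec se = nb_obs_se(y, X, beta, theta);
  return Rcpp::List::create(
      Rcpp::Named("beta") = beta, Rcpp::Named("se") = se,
      Rcpp::Named("loglik") = ll, Rcpp::Named("converged") = conv);
}

// Per-marker NB likelihood-ratio scan for one transcript at fixed theta.
// X0: base design (n x p0); G: candidate markers (n x m).
// [[Rcpp::export]]
Rcpp::List cpp_nb_scan(const arma::vec& y, const arma::mat& X0,
                       const arma::mat& G, double theta) {
  vec beta0(X0.n_cols, fill::zeros);
  beta0[0] = std::log(mean(y) + 1e-8);
  double ll0 = 0.0;
  bool conv0 = nb_irls(y, X0, theta, beta0, ll0);
  const uword m = G.n_cols;
  vec lod(m, fill::zeros), beta(m), se(m);
  std::vector<bool> conv(m, false);
  mat X(y.n_elem, X0.n_cols + 1);
  X.cols(0, X0.n_cols - 1) = X0;
  for (uword j = 0; j < m; ++j) {
    X.col(X0.n_cols) = G.col(j);
    vec b(X.n_cols, fill::zeros);
    b.head(X0.n_cols) = beta0;
    double ll1 = 0.0;
    bool ok = nb_irls(y, X, theta, b, ll1);
    conv[j] = ok && conv0;
    double lr = 2.0 * (ll1 - ll0);
    lod[j] = lr > 0 ? lr / (2.0 * std::log(10.0)) : 0.0;
    beta[j] = b[X0.n_cols];
    vec s = nb_obs_se(y, X, b, theta);
    se[j] = s[X0.n_cols];
  }
  return Rcpp::List::create(
      Rcpp::Named("lod") = lod, Rcpp::Named("beta") = beta,
      Rcpp::Named("se") = se, Rcpp::Named("loglik_null") = ll0,
      Rcpp::Named("converged") = conv);
}

static double binom_loglik(const vec& y, const vec& p) {
  double ll = 0.0;
  for (uword i = 0; i < y.n_elem; ++i) {
    ll += y[i] * std::log(p[i]) + (1.0 - y[i]) * std::log1p(-p[i]);
  }
  return ll;
}

static bool logistic_irls(const vec& y, const mat& X, vec& beta, double& ll,
                          int max_iter = 100, double tol = 1e-8) {
  vec eta = clamp(X * beta, -ETA_CAP, ETA_CAP);
  vec p = 1.0 / (1.0 + exp(-eta));
  ll = binom_loglik(y, p);
  for (int it = 0; it < max_iter; ++it) {
    vec w = p % (1.0 - p);
    w = clamp(w, 1e-10, 0.25);
    vec z = eta + (y - p) / w;
    mat Xw = X.each_col() % w;
    vec beta_new;
    if (!solve(beta_new, X.t() * Xw, Xw.t() * z, solve_opts::no_approx)) {
      return false;
    }
    vec eta_new = clamp(X * beta_new, -ETA_CAP, ETA_CAP);
    vec p_new = 1.0 / (1.0 + exp(-eta_new));
    double ll_new = binom_loglik(y, p_new);
    int halves = 0;
    while (ll_new < ll - 1e-10 && halves < 10) {
      beta_new = 0.5 * (beta_new + beta);
      eta_new = clamp(X * beta_new, -ETA_CAP, ETA_CAP);
      p_new = 1.0 / (1.0 + exp(-eta_new));
      ll_new = binom_loglik(y, p_new);
      ++halves;
    }
    double delta = std::fabs(ll_new - ll);
    beta = beta_new; eta = eta_new; p = p_new; ll = ll_new;
    if (delta < tol) return true;
  }
  return false;
}

// Per-marker logistic LR scan: LOD = (l_full - l_null) / ln(10).
// [[Rcpp::export]]
Rcpp::List cpp_logistic_scan(const arma::vec& y, const arma::mat& X0,
                             const arma::mat& G) {
  vec beta0(X0.n_cols, fill::zeros);
  double pbar = mean(y);
  beta0[0] = std::log((pbar + 1e-8) / (1.0 - pbar + 1e-8));
  double ll0 = 0.0;
  logistic_irls(y, X0, beta0, ll0);
  const uword m = G.n_cols;
  vec lod(m, fill::zeros), beta(m);
  Rcpp::LogicalVector separated(m);
  mat X(y.n_elem, X0.n_cols + 1);
  X.cols(0, X0.n_cols - 1) = X0;
  for (uword j = 0; j < m; ++j) {
    X.col(X0.n_cols) = G.col(j);
    vec b(X.n_cols, fill::zeros);
    b.head(X0.n_cols) = beta0;
    double ll1 = 0.0;
    logistic_irls(y, X, b, ll1);
    double d = ll1 - ll0;
    lod[j] = d > 0 ? d / std::log(10.0) : 0.0;
    beta[j] = b[X0.n_cols];
    separated[j] = std::fabs(b[X0.n_cols]) > 15.0;
  }
  return Rcpp::List::create(
      Rcpp::Named("lod") = lod, Rcpp::Named("beta") = beta,
      Rcpp::Named("separated") = separated,
      Rcpp::Named("loglik_null") = ll0);
}
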