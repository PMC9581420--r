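// Fast maximum-likelihood fitting of GLMMs with a single random intercept.
//
// Non-gaussian families (Bernoulli/logit, Poisson/log) use the Laplace
// approximation to the marginal likelihood.  For a fixed random-intercept
// standard deviation sigma the conditional modes of (beta, u) are found by
// penalized IRLS; because the grouping factor is a single random intercept
// the q x q block of the working Hessian is diagonal, so each Newton step
// costs O(n p^2) via a Schur complement.  The outer problem is a 1-D Brent
// search over log(sigma).  The gaussian family has a closed-form profile:
// for theta = sigma_u / sigma_e the GLS problem is a penalized least
// squares and both sigma_e and beta profile out analytically, leaving a
// 1-D search over log(theta).
//
// This exists because exhaustive-subset model selection with randomized
// null recalibration needs ~1e5 refits per analysis, which general-purpose
// mixed-model software cannot deliver at interactive speed.

#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>

using namespace arma;

namespace {

const double ETA_MAX = 30.0;

inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// mu, IRLS weights and summed log-likelihood for canonical links.
// family: 1 = Bernoulli(logit), 2 = Poisson(log)
void family_terms(int fam, const vec& eta, const vec& y,
                  vec& mu, vec& w, double& ll) {
  const uword n = eta.n_elem;
  ll = 0.0;
  if (fam == 1) {
    for (uword j = 0; j < n; ++j) {
      double e = clampd(eta[j], -ETA_MAX, ETA_MAX);
      double m = 1.0 / (1.0 + std::exp(-e));
      m = clampd(m, 1e-10, 1.0 - 1e-10);
      mu[j] = m;
      w[j] = m * (1.0 - m);
      ll += y[j] * std::log(m) + (1.0 - y[j]) * std::log1p(-m);
    }
  } else {
    for (uword j = 0; j < n; ++j) {
      double e = clampd(eta[j], -ETA_MAX, ETA_MAX);
      double m = std::exp(e);
      mu[j] = m;
      w[j] = std::max(m, 1e-10);
      // continuous extension in y so that averaged counts are accepted
      ll += y[j] * e - m - std::lgamma(y[j] + 1.0);
    }
  }
}

struct Fit {
  vec beta, u;
  double lap, penll, maxeta;
  bool ok;
  vec wsum;
  mat schur;
  // scratch buffers reused across objective evaluations
  vec eta, mu, w, etaProp, muP, wP;
  Fit() : lap(-datum::inf), penll(-datum::inf), maxeta(0.0), ok(false) {}
};

// Penalized IRLS for fixed sigma; leaves conditional modes and the
// Laplace log-likelihood in F (the beta-block Schur complement only when
// need_schur).  Warm-started from whatever F already holds.
void pirls(const mat& X, const vec& y, const ivec& g, int q, int fam,
           double sigma, Fit& F, int maxit, bool need_schur) {
  const uword n = X.n_rows, p = X.n_cols;
  const double s2 = sigma * sigma, invs2 = 1.0 / s2;
  if (F.beta.n_elem != p) { F.beta = zeros<vec>(p); F.u = zeros<vec>(q); }
  if (F.eta.n_elem != n) {
    F.eta.set_size(n); F.mu.set_size(n); F.w.set_size(n);
    F.etaProp.set_size(n); F.muP.set_size(n); F.wP.set_size(n);
  }

  double ll;
  F.eta = X * F.beta;
  for (uword j = 0; j < n; ++j) F.eta[j] += F.u[g[j]];
  family_terms(fam, F.eta, y, F.mu, F.w, ll);
  double P = ll - 0.5 * invs2 * dot(F.u, F.u);
  bool conv = false;

  const mat Xt = X.t();
  mat A(p, p), B(p, q);
  vec c(p), d(q), D(q), wsum(q), rhs(p), beta_new(p), u_new(q);
  vec wz(n);

  for (int it = 0; it < maxit; ++it) {
    // working response z = eta + (y - mu)/w, accumulated as w*z
    wz = F.w % F.eta + (y - F.mu);
    A = Xt * (X.each_col() % F.w);
    c = Xt * wz;
    B.zeros(); d.zeros(); wsum.zeros();
    for (uword j = 0; j < n; ++j) {
      const int gi = g[j];
      B.unsafe_col(gi) += F.w[j] * Xt.unsafe_col(j);
      d[gi] += wz[j];
      wsum[gi] += F.w[j];
    }
    D = wsum + invs2;

    mat S = A - B * diagmat(1.0 / D) * B.t();
    rhs = c - B * (d / D);
    if (!solve(beta_new, S, rhs, solve_opts::likely_sympd + solve_opts::no_approx)) {
      F.ok = false;
      F.lap = -datum::inf;
      if (need_schur) F.schur = S;
      F.wsum = wsum;
      return;
    }
    u_new = (d - B.t() * beta_new) / D;

    // evaluate the proposal, halving the step while it does not improve
    // the penalized objective (eta is linear in the parameters, so the
    // halved eta interpolates the current and proposed eta)
    F.etaProp = X * beta_new;
    for (uword j = 0; j < n; ++j) F.etaProp[j] += u_new[g[j]];
    double step = 1.0;
    vec bs = beta_new, us = u_new;
    family_terms(fam, F.etaProp, y, F.muP, F.wP, ll);
    double Pn = ll - 0.5 * invs2 * dot(us, us);
    int h = 0;
    while (Pn < P && h < 12) {
      step *= 0.5;
      ++h;
      bs = F.beta + step * (beta_new - F.beta);
      us = F.u + step * (u_new - F.u);
      F.etaProp = (1.0 - step) * F.eta + step * F.etaProp;
      // note: after the first halving etaProp is no longer the full-step
      // eta, so recompute from scratch to stay exact
      if (h > 1) {
        F.etaProp = X * bs;
        for (uword j = 0; j < n; ++j) F.etaProp[j] += us[g[j]];
      }
      family_terms(fam, F.etaProp, y, F.muP, F.wP, ll);
      Pn = ll - 0.5 * invs2 * dot(us, us);
    }
    double dP = std::abs(Pn - P);
    F.beta = bs;
    F.u = us;
    F.eta = F.etaProp;
    F.mu = F.muP;
    F.w = F.wP;
    P = Pn;
    if (dP < 1e-8 * (1.0 + std::abs(Pn))) { conv = true; break; }
  }

  // Laplace correction from the per-group summed weights at the mode
  wsum.zeros();
  for (uword j = 0; j < n; ++j) wsum[g[j]] += F.w[j];
  double logdet = 0.0;
  for (int i = 0; i < q; ++i) logdet += std::log1p(s2 * wsum[i]);
  F.penll = P;
  F.lap = P - 0.5 * logdet;
  F.wsum = wsum;
  F.maxeta = abs(F.eta).max();
  F.ok = conv;

  if (need_schur) {
    A = Xt * (X.each_col() % F.w);
    B.zeros();
    for (uword j = 0; j < n; ++j)
      B.unsafe_col(g[j]) += F.w[j] * Xt.unsafe_col(j);
    D = wsum + invs2;
    F.schur = A - B * diagmat(1.0 / D) * B.t();
  }
}

// Brent's 1-D minimizer on [a, b] (never evaluates the endpoints exactly;
// converges into them when the minimum sits on the boundary).
template <class Fn>
double brent_min(Fn f, double a, double b, double tol, double& fmin) {
  const double gr = 0.3819660112501051;
  double x = a + gr * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 200; ++iter) {
    double m = 0.5 * (a + b);
    double tol1 = tol * std::abs(x) + 1e-10, tol2 = 2.0 * tol1;
    if (std::abs(x - m) <= tol2 - 0.5 * (b - a)) break;
    double p = 0.0, q = 0.0, r = 0.0;
    bool golden = true;
    if (std::abs(e) > tol1) {
      r = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::abs(q);
      double etmp = e;
      e = d;
      if (std::abs(p) < std::abs(0.5 * q * etmp) &&
          p > q * (a - x) && p < q * (b - x)) {
        golden = false;
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (x < m) ? tol1 : -tol1;
      }
    }
    if (golden) {
      e = (x < m) ? (b - x) : (a - x);
      d = gr * e;
    }
    double u = (std::abs(d) >= tol1) ? (x + d)
                                     : (x + ((d > 0.0) ? tol1 : -tol1));
    double fu = f(u);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  fmin = fx;
  return x;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".glmm_fit_cpp")]]
Rcpp::List glmm_fit_cpp(const arma::mat& X, const arma::vec& y,
                        const arma::ivec& g, int ngrp, int family,
                        double tmin, double tmax, double ttol, int maxit,
                        bool se = true) {
  Fit F;
  auto obj = [&](double t) {
    pirls(X, y, g, ngrp, family, std::exp(t), F, maxit, false);
    return -F.lap;
  };
  double fbest;
  double that = brent_min(obj, tmin, tmax, ttol, fbest);
  double sigma = std::exp(that);
  pirls(X, y, g, ngrp, family, sigma, F, maxit, se);

  vec sev;
  if (se) {
    mat cov;
    if (!inv_sympd(cov, F.schur)) cov = pinv(F.schur);
    sev = sqrt(cov.diag());
  } else {
    sev = vec(X.n_cols, fill::value(NA_REAL));
  }

  return Rcpp::List::create(
      Rcpp::Named("beta") = F.beta,
      Rcpp::Named("se") = sev,
      Rcpp::Named("u") = F.u,
      Rcpp::Named("sigma_u") = sigma,
      Rcpp::Named("loglik") = F.lap,
      Rcpp::Named("converged") = F.ok,
      Rcpp::Named("boundary") = (that <= tmin + 4.0 * ttol),
      Rcpp::Named("max_abs_eta") = F.maxeta);
}

//' @noRd
// [[Rcpp::export(name = ".lmm_fit_cpp")]]
Rcpp::List lmm_fit_cpp(const arma::mat& X, const arma::vec& y,
                       const arma::ivec& g, int ngrp,
                       double tmin, double tmax, double ttol) {
  const uword n = X.n_rows, p = X.n_cols;
  const int q = ngrp;

  // sufficient statistics do not depend on theta
  mat A = X.t() * X;
  mat B(p, q, fill::zeros);
  vec c = X.t() * y;
  vec d(q, fill::zeros), nvec(q, fill::zeros);
  for (uword j = 0; j < n; ++j) {
    const int gi = g[j];
    for (uword k = 0; k < p; ++k) B(k, gi) += X(j, k);
    d[gi] += y[j];
    nvec[gi] += 1.0;
  }

  vec beta(p, fill::zeros), u(q, fill::zeros);
  mat S(p, p);
  double r2 = datum::inf;
  bool ok = true;

  auto profile_m2l = [&](double t) {
    const double th2 = std::exp(2.0 * t);
    const double invt2 = 1.0 / th2;
    vec D = nvec + invt2;
    S = A - B * diagmat(1.0 / D) * B.t();
    vec rhs = c - B * (d / D);
    if (!solve(beta, S, rhs, solve_opts::likely_sympd + solve_opts::no_approx)) {
      ok = false;
      return datum::inf;
    }
    u = (d - B.t() * beta) / D;
    vec resid = y - X * beta;
    for (uword j = 0; j < n; ++j) resid[j] -= u[g[j]];
    r2 = dot(resid, resid) + invt2 * dot(u, u);
    double logdet = 0.0;
    for (int i = 0; i < q; ++i) logdet += std::log1p(th2 * nvec[i]);
    return n * std::log(2.0 * datum::pi * r2 / n) + n + logdet;
  };

  double fbest;
  double that = brent_min(profile_m2l, tmin, tmax, ttol, fbest);
  double m2l = profile_m2l(that);

  const double theta = std::exp(that);
  const double sigma_e = std::sqrt(r2 / n);
  const double sigma_u = theta * sigma_e;

  mat cov;
  if (!inv_sympd(cov, S)) cov = pinv(S);
  vec se = sigma_e * sqrt(cov.diag());

  return Rcpp::List::create(
      Rcpp::Named("beta") = beta,
      Rcpp::Named("se") = se,
      Rcpp::Named("u") = u,
      Rcpp::Named("sigma_u") = sigma_u,
      Rcpp::Named("sigma_e") = sigma_e,
      Rcpp::Named("loglik") = -0.5 * m2l,
      Rcpp::Named("converged") = ok,
      Rcpp::Named("boundary") = (that <= tmin + 4.0 * ttol),
      Rcpp::Named("max_abs_eta") = NA_REAL);
}
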