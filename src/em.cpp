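// EM for a Gaussian finite mixture with profile-specific means and a shared
// diagonal covariance (variances equal across profiles, free across
// indicators).  Called once per restart; restart policy and initialization
// live on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

// log-sum-exp over rows of an n x T matrix
static vec row_logsumexp(const mat& L) {
  vec mx = max(L, 1);
  vec out = mx + log(sum(exp(L.each_col() - mx), 1));
  return out;
}

// One EM run from initial responsibilities phi0.
// Returns parameters, responsibilities, log-likelihood trace and flags.
// var_floor guards against degenerate likelihood spikes.
// [[Rcpp::export(name = ".em_run_cpp")]]
Rcpp::List em_run_cpp(const arma::mat& X, const arma::mat& phi0,
                      double tol, int max_iter, double var_floor) {
  const uword n = X.n_rows, m = X.n_cols, T = phi0.n_cols;
  mat phi = phi0;
  mat mu(T, m, fill::zeros);
  rowvec sigma2(m, fill::ones);
  rowvec lpi(T, fill::zeros);
  vec Xsq_rowsum;            // filled per E-step
  mat X2 = square(X);
  rowvec sumX2 = sum(X2, 0);

  std::vector<double> trace;
  double ll = -datum::inf, ll_prev = -datum::inf;
  bool converged = false, collapsed = false;
  int reinit_left = 3;

  for (int it = 0; it < max_iter; ++it) {
    // ---- M-step from current phi
    rowvec Nt = sum(phi, 0);                   // 1 x T
    if (Nt.min() < 1e-8 * (double) n) {
      if (reinit_left-- > 0) {
        // revive the starved component at the observation worst explained
        // by the current model (lowest max responsibility mass)
        uword t_bad = Nt.index_min();
        vec conf = max(phi, 1);
        uword i_bad = conf.index_min();
        phi.row(i_bad).zeros();
        phi(i_bad, t_bad) = 1.0;
        Nt = sum(phi, 0);
        trace.clear();                         // trace restarts after surgery
        ll_prev = -datum::inf;
      } else {
        collapsed = true;
        break;
      }
    }
    mat S = phi.t() * X;                       // T x m
    mu = S.each_col() / Nt.t();
    mat Ssq = square(S);
    sigma2 = (sumX2 - sum(Ssq.each_col() / Nt.t(), 0)) / (double) n;
    sigma2 = clamp(sigma2, var_floor, datum::inf);
    lpi = log(Nt / (double) n);

    // ---- E-step: log phi_{i,t} up to row normalization
    rowvec inv_s2 = 1.0 / sigma2;
    double cst = -0.5 * (double) m * LOG2PI - 0.5 * accu(log(sigma2));
    vec q1 = X2 * inv_s2.t();                  // n
    mat q2 = X * (mu.each_row() % inv_s2).t(); // n x T
    mat musq = square(mu);
    rowvec q3 = sum(musq.each_row() % inv_s2, 1).t(); // 1 x T
    mat L = q2;
    L.each_col() -= 0.5 * q1;
    L.each_row() += lpi - 0.5 * q3 + cst;
    vec lse = row_logsumexp(L);
    ll = accu(lse);
    phi = exp(L.each_col() - lse);

    trace.push_back(ll);
    if (std::isfinite(ll_prev) &&
        (ll - ll_prev) < tol * std::abs(ll_prev)) {
      converged = true;
      break;
    }
    ll_prev = ll;
  }

  return Rcpp::List::create(
    Rcpp::Named("mu") = mu,
    Rcpp::Named("sigma2") = sigma2.t(),
    Rcpp::Named("weights") = exp(lpi.t()),
    Rcpp::Named("resp") = phi,
    Rcpp::Named("loglik") = ll,
    Rcpp::Named("trace") = trace,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("collapsed") = collapsed);
}
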