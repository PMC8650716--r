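#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Huber M-estimation by iteratively reweighted least squares.
// Scale is re-estimated each iteration as median(|r|)/0.6745 (MAD about 0).
// A vanishing scale (near-exact fit) falls back to unit weights, whose
// solution interpolates the data anyway.
struct HuberFit {
  vec beta;
  vec w;
  double scale;
  bool converged;
  int iter;
};

static HuberFit huber_irls(const mat& X, const vec& y, double k,
                           double tol, int maxit, bool check_rank = true) {
  HuberFit out;
  mat Q, R;
  if (!qr_econ(Q, R, X) || (check_rank && arma::rank(X) < X.n_cols))
    Rcpp::stop("design matrix is rank deficient");
  vec beta = solve(R, Q.t() * y);
  vec w(y.n_elem, fill::ones);
  double scale = 0.0;
  bool conv = false;
  int it = 0;
  const double eps = 1e-12 * std::max(1.0, arma::abs(y).max());
  for (it = 0; it < maxit; ++it) {
    vec r = y - X * beta;
    scale = median(abs(r)) / 0.6745;
    if (scale < eps || !std::isfinite(k)) {
      w.ones();
    } else {
      vec u = abs(r) / scale;
      for (uword i = 0; i < u.n_elem; ++i)
        w(i) = (u(i) <= k) ? 1.0 : k / u(i);
    }
    mat Xw = X.each_col() % sqrt(w);
    vec yw = y % sqrt(w);
    vec beta_new = solve(Xw.t() * Xw, Xw.t() * yw);
    double step = abs(beta_new - beta).max();
    beta = beta_new;
    if (step < tol) { conv = true; ++it; break; }
  }
  out.beta = beta;
  out.w = w;
  out.scale = scale;
  out.converged = conv;
  out.iter = it;
  return out;
}

// Heteroskedasticity-consistent sandwich Wald statistic for one coefficient
// of the Huber M-estimate: W = beta_j^2 / V_jj with
//   V = A^-1 B A^-1,  A = X' diag(w) X,  B = X' diag(w^2 r^2) X,
// where w are the converged IRLS weights (so w * r = s * psi(r/s)): the
// estimating-equation sandwich of the weighted normal equations. The
// weights are strictly positive, so A is positive definite whenever X has
// full column rank. In the OLS limit (k -> Inf) this is exactly HC0.
static double wald_from_fit(const mat& X, const vec& y, const HuberFit& fit,
                            double k, uword j) {
  (void) k;
  vec r = y - X * fit.beta;
  mat A = X.t() * (X.each_col() % fit.w);
  vec meat = square(fit.w % r);
  mat B = X.t() * (X.each_col() % meat);
  mat Ainv;
  if (!inv(Ainv, A)) Rcpp::stop("degenerate design: singular bread matrix");
  mat V = Ainv * B * Ainv.t();
  double vjj = V(j, j);
  if (!(vjj > 0)) Rcpp::stop("degenerate design: zero variance estimate");
  double b = fit.beta(j);
  return b * b / vjj;
}

// [[Rcpp::export]]
Rcpp::List cpp_huber_fit(const arma::mat& X, const arma::vec& y,
                         double k, double tol, int maxit) {
  HuberFit fit = huber_irls(X, y, k, tol, maxit);
  return Rcpp::List::create(
    Rcpp::Named("coefficients") = fit.beta,
    Rcpp::Named("weights") = fit.w,
    Rcpp::Named("scale") = fit.scale,
    Rcpp::Named("converged") = fit.converged,
    Rcpp::Named("iterations") = fit.iter);
}

// [[Rcpp::export]]
Rcpp::List cpp_wald(const arma::mat& X, const arma::vec& y, int j,
                    double k, double tol, int maxit) {
  HuberFit fit = huber_irls(X, y, k, tol, maxit);
  double W = wald_from_fit(X, y, fit, k, (uword) j);
  return Rcpp::List::create(
    Rcpp::Named("wald") = W,
    Rcpp::Named("estimate") = fit.beta((uword) j),
    Rcpp::Named("converged") = fit.converged);
}

// Permute the predictor-of-interest column (index j) across rows, keeping
// nuisance columns fixed, and recompute the Wald statistic each time.
// Uses R's RNG (via unif_rand) so set.seed() in R controls the draws.
// With early_h > 0, stop as soon as early_h permutation statistics reach
// the observed one (Besag-Clifford sequential stopping): the significance
// decision at any threshold below early_h/(n_perm+1) is unchanged and the
// run is much shorter for clearly null predictors.
// [[Rcpp::export]]
Rcpp::List cpp_perm_wald(const arma::mat& X, const arma::vec& y, int j,
                         int n_perm, double k, double tol, int maxit,
                         int early_h = 0) {
  const uword n = X.n_rows;
  const uword jj = (uword) j;
  HuberFit fit = huber_irls(X, y, k, tol, maxit);
  double W_obs = wald_from_fit(X, y, fit, k, jj);

  vec col = X.col(jj);
  mat Xp = X;
  int n_done = 0, n_exceed = 0;
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates shuffle driven by R's RNG
    for (uword i = n - 1; i > 0; --i) {
      uword swap = (uword) std::floor(unif_rand() * (i + 1));
      if (swap > i) swap = i;
      std::swap(idx[i], idx[swap]);
    }
    for (uword i = 0; i < n; ++i) Xp(i, jj) = col(idx[i]);
    HuberFit pf = huber_irls(Xp, y, k, tol, maxit, false);
    double W = wald_from_fit(Xp, y, pf, k, jj);
    ++n_done;
    if (W >= W_obs - 1e-12) {
      ++n_exceed;
      if (early_h > 0 && n_exceed >= early_h) break;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("wald_obs") = W_obs,
    Rcpp::Named("n_done") = n_done,
    Rcpp::Named("n_exceed") = n_exceed,
    Rcpp::Named("estimate") = fit.beta(jj));
}

// Wald statistics for an explicit matrix of permutations (1-based row
// indices), used for exhaustive enumeration at small n.
// [[Rcpp::export]]
arma::vec cpp_wald_perm_matrix(const arma::mat& X, const arma::vec& y, int j,
                               const arma::umat& perms,
                               double k, double tol, int maxit) {
  const uword jj = (uword) j;
  vec col = X.col(jj);
  mat Xp = X;
  vec W(perms.n_rows);
  for (uword b = 0; b < perms.n_rows; ++b) {
    for (uword i = 0; i < X.n_rows; ++i) Xp(i, jj) = col(perms(b, i) - 1);
    HuberFit pf = huber_irls(Xp, y, k, tol, maxit);
    W(b) = wald_from_fit(Xp, y, pf, k, jj);
  }
  return W;
}
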