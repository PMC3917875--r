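// Numerical cores for the mixture fits.
//
// All randomness (null draws, restart initializations, k-means++ seeds) is
// generated on the R side and passed in, so these routines are deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Fit1d {
  double pi, mu1, mu2, sigma2, loglik;
  int iters;
  bool converged;
};

// EM for a two-component equal-variance univariate Gaussian mixture.
Fit1d em1d(const arma::vec &x, double m1, double m2, double pi,
           double tol, int maxit) {
  const int n = x.n_elem;
  const double var_floor = 1e-12;
  double s2 = arma::var(x, 1);  // population variance as starting sigma^2
  if (s2 < var_floor) s2 = var_floor;
  double ll = -std::numeric_limits<double>::infinity();
  double ll_old = ll;
  arma::vec g(n);
  int it = 0;
  bool conv = false;
  for (it = 1; it <= maxit; ++it) {
    // E-step (log-space for stability)
    const double lp1 = std::log(pi), lp2 = std::log1p(-pi);
    const double inv2s = 1.0 / (2.0 * s2);
    const double lnorm = -0.5 * std::log(2.0 * M_PI * s2);
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      const double d1 = x[i] - m1, d2 = x[i] - m2;
      const double a = lp1 - d1 * d1 * inv2s;
      const double b = lp2 - d2 * d2 * inv2s;
      const double mx = a > b ? a : b;
      const double ea = std::exp(a - mx), eb = std::exp(b - mx);
      g[i] = ea / (ea + eb);
      ll += mx + std::log(ea + eb) + lnorm;
    }
    if (std::abs(ll - ll_old) < tol) { conv = true; break; }
    ll_old = ll;
    // M-step
    const double n1 = arma::accu(g);
    const double n2 = n - n1;
    if (n1 < 1e-10 || n2 < 1e-10) break;  // component emptied out
    m1 = arma::dot(g, x) / n1;
    m2 = (arma::accu(x) - arma::dot(g, x)) / n2;
    pi = n1 / n;
    if (pi < 1e-9) pi = 1e-9;
    if (pi > 1.0 - 1e-9) pi = 1.0 - 1e-9;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      const double d1 = x[i] - m1, d2 = x[i] - m2;
      ss += g[i] * d1 * d1 + (1.0 - g[i]) * d2 * d2;
    }
    s2 = ss / n;
    if (s2 < var_floor) s2 = var_floor;
  }
  Fit1d f;
  f.pi = pi; f.mu1 = m1; f.mu2 = m2; f.sigma2 = s2;
  f.loglik = ll; f.iters = it; f.converged = conv;
  return f;
}

double quantile7(const arma::vec &xs, double p) {
  // xs sorted ascending; type-7 interpolation as in stats::quantile
  const int n = xs.n_elem;
  const double h = (n - 1) * p;
  const int lo = (int)std::floor(h);
  const int hi = lo + 1 >= n ? n - 1 : lo + 1;
  return xs[lo] + (h - lo) * (xs[hi] - xs[lo]);
}

}  // namespace

// Fit each column of X with a best-of-restarts two-component EM.
// init_q1, init_q2, init_pi: (n_restarts x G) matrices of initial quantile
// positions for the two means and the initial mixing proportion. Restarts are
// screened at coarse_tol and the winner is polished at tol.
// Returns a G x 7 matrix: pi, mu1, mu2, sigma, loglik, converged, iters.
// [[Rcpp::export(name = ".fit_mix_batch")]]
NumericMatrix fit_mix_batch(const arma::mat &X,
                            const arma::mat &init_q1,
                            const arma::mat &init_q2,
                            const arma::mat &init_pi,
                            double tol = 1e-8, int maxit = 1000,
                            double coarse_tol = 1e-4, int coarse_maxit = 300) {
  const int G = X.n_cols;
  const int R = init_q1.n_rows;
  NumericMatrix out(G, 7);
  colnames(out) = CharacterVector::create("pi", "mu1", "mu2", "sigma",
                                          "loglik", "converged", "iters");
  for (int gidx = 0; gidx < G; ++gidx) {
    arma::vec x = X.col(gidx);
    arma::vec xs = arma::sort(x);
    Fit1d best; best.loglik = -std::numeric_limits<double>::infinity();
    int tot_it = 0;
    for (int r = 0; r < R; ++r) {
      double m1 = quantile7(xs, init_q1(r, gidx));
      double m2 = quantile7(xs, init_q2(r, gidx));
      if (m1 > m2) std::swap(m1, m2);
      if (m2 - m1 < 1e-12) m2 = m1 + 1e-6 * (xs[xs.n_elem - 1] - xs[0] + 1.0);
      Fit1d f = em1d(x, m1, m2, init_pi(r, gidx), coarse_tol, coarse_maxit);
      tot_it += f.iters;
      if (f.loglik > best.loglik) best = f;
    }
    // polish the winner at the final tolerance
    Fit1d f = em1d(x, best.mu1, best.mu2, best.pi, tol, maxit);
    tot_it += f.iters;
    if (f.loglik < best.loglik) f = best;  // polishing can only help; guard anyway
    // convention: mu1 <= mu2, pi is the weight of the lower component
    double pi = f.pi, mu1 = f.mu1, mu2 = f.mu2;
    if (mu1 > mu2) { std::swap(mu1, mu2); pi = 1.0 - pi; }
    out(gidx, 0) = pi;
    out(gidx, 1) = mu1;
    out(gidx, 2) = mu2;
    out(gidx, 3) = std::sqrt(f.sigma2);
    out(gidx, 4) = f.loglik;
    out(gidx, 5) = f.converged ? 1.0 : 0.0;
    out(gidx, 6) = tot_it;
  }
  return out;
}

// EM for a k-component Gaussian mixture over rows of X (observations x dims)
// with spherical (sigma_k^2 I) or diagonal per-component covariances.
// centers0: k x d initial means. Returns converged parameters, posteriors
// and the log-likelihood; model selection (BIC) happens on the R side.
// [[Rcpp::export(name = ".gmm_diag_em")]]
List gmm_diag_em(const arma::mat &X, const arma::mat &centers0,
                 bool spherical, double tol = 1e-6, int maxit = 200,
                 double var_floor_frac = 1e-4) {
  const int n = X.n_rows, d = X.n_cols, k = centers0.n_rows;
  arma::mat mu = centers0;                 // k x d
  arma::mat vr(k, d);                      // per-component variances
  const double total_var = std::max(arma::accu(arma::var(X, 0, 0)) / d, 1e-12);
  const double vfloor = var_floor_frac * total_var;
  vr.fill(total_var);
  arma::vec pro(k, arma::fill::value(1.0 / k));
  arma::mat logdens(n, k);
  arma::mat z(n, k);
  double ll = -std::numeric_limits<double>::infinity(), ll_old = ll;
  bool conv = false;
  int it;
  for (it = 1; it <= maxit; ++it) {
    // E-step
    for (int j = 0; j < k; ++j) {
      arma::rowvec m = mu.row(j);
      arma::rowvec v = vr.row(j);
      double logdet = arma::accu(arma::log(v));
      arma::mat D = X.each_row() - m;
      arma::vec q = (D % D) * (0.5 / v.t());
      logdens.col(j) = std::log(pro[j]) - 0.5 * d * std::log(2.0 * M_PI)
                       - 0.5 * logdet - q;
    }
    arma::vec mx = arma::max(logdens, 1);
    z = arma::exp(logdens.each_col() - mx);
    arma::vec rs = arma::sum(z, 1);
    ll = arma::accu(mx + arma::log(rs));
    z.each_col() /= rs;
    if (std::abs(ll - ll_old) < tol * (std::abs(ll) + 1.0)) { conv = true; break; }
    ll_old = ll;
    // M-step
    arma::rowvec nk = arma::sum(z, 0);
    nk = arma::clamp(nk, 1e-8, arma::datum::inf);
    pro = (nk / n).t();
    mu = (z.t() * X);
    mu.each_col() /= nk.t();
    for (int j = 0; j < k; ++j) {
      arma::mat D = X.each_row() - mu.row(j);
      arma::rowvec ssq = (z.col(j).t() * (D % D)) / nk[j];
      if (spherical) {
        double s = std::max(arma::accu(ssq) / d, vfloor);
        vr.row(j).fill(s);
      } else {
        vr.row(j) = arma::clamp(ssq, vfloor, arma::datum::inf);
      }
    }
  }
  // degeneracy check: the mixture likelihood is unbounded when a component
  // collapses onto (nearly) a single observation; such solutions are not
  // meaningful ML estimates and are rejected by the caller
  arma::rowvec nk_fin = arma::sum(z, 0);
  bool degen = nk_fin.min() < 2.0 || vr.min() <= vfloor * (1.0 + 1e-9);
  return List::create(_["loglik"] = ll,
                      _["pro"] = pro,
                      _["mean"] = mu,
                      _["variance"] = vr,
                      _["z"] = z,
                      _["converged"] = conv,
                      _["degenerate"] = degen,
                      _["iters"] = it);
}
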