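// Gibbs sampler core for the threshold-liability sire model
//   lambda = X beta + Z_h h + Z_s s + e,  e ~ N(0, I) (residual fixed at 1)
//   h ~ N(0, I sigma2_h),  s ~ N(0, H sigma2_s),  threshold fixed at 0.
//
// Location effects are updated in three Gaussian blocks (beta | h,s),
// (h | beta,s), (s | beta,h). Z_h'Z_h and Z_s'Z_s are diagonal (each record
// belongs to one class / one sire), so the h block factorizes over classes
// and the s block precision is  D_c + H^-1 / sigma2_s.  A one-off
// generalized eigendecomposition  L^-1 D_c L^-T = Q Lambda Q'  (H^-1 = LL')
// turns the s draw into two dense mat-vecs per sweep, so chain cost does not
// depend on re-factorizing the MME when sigma2_s moves.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// draw z ~ N(0,1) truncated to (a, Inf)
static double rtnorm_std_lower(double a) {
  if (a < 0.4) {
    // acceptance >= ~0.34; cheap for the common case
    for (;;) {
      double z = R::norm_rand();
      if (z > a) return z;
    }
  } else if (a < 4.0) {
    double pa = R::pnorm(a, 0.0, 1.0, 1, 0);
    double u = R::runif(pa, 1.0);
    return R::qnorm(u, 0.0, 1.0, 1, 0);
  } else {
    // Robert (1995) exponential rejection for the far tail
    double astar = 0.5 * (a + std::sqrt(a * a + 4.0));
    for (;;) {
      double z = a + R::exp_rand() / astar;
      double rho = std::exp(-0.5 * (z - astar) * (z - astar));
      if (R::unif_rand() <= rho) return z;
    }
  }
}

// lambda ~ N(mu, 1) truncated to (0, Inf)
static double rtnorm_pos(double mu) { return mu + rtnorm_std_lower(-mu); }

// [[Rcpp::export(name = ".rtnorm_pos")]]
NumericVector rtnorm_pos_vec(int n, double mu) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rtnorm_pos(mu);
  return out;
}

// [[Rcpp::export(name = ".gibbs_core")]]
List gibbs_core(const arma::mat& X,
                const IntegerVector& hy,
                const IntegerVector& sv,
                const arma::mat& Hinv,
                const IntegerVector& y,
                const NumericVector& lambda_obs,
                bool gaussian,
                int niter, int burnin, int thin,
                double nu_h, double S_h, double nu_s, double S_s,
                double sigma2_h0, double sigma2_s0) {
  const int n = X.n_rows;
  const int nb = X.n_cols;
  const int ns = Hinv.n_rows;
  int nh = 0;
  for (int i = 0; i < n; ++i) nh = std::max(nh, hy[i]);

  arma::vec cnt_h(nh, arma::fill::zeros), cnt_s(ns, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    cnt_h[hy[i] - 1] += 1.0;
    cnt_s[sv[i] - 1] += 1.0;
  }

  // fixed-effect block: precision X'X is constant, factor once
  arma::mat XtX = X.t() * X;
  arma::mat Rb = arma::chol(XtX);  // upper

  // sire block: H^-1 = L L', M = L^-1 diag(cnt_s) L^-T = Q Lam Q'
  arma::mat L;
  if (!arma::chol(L, Hinv, "lower")) {
    arma::mat Hj = Hinv + arma::eye(ns, ns) * (1e-8 * arma::mean(Hinv.diag()));
    if (!arma::chol(L, Hj, "lower")) stop("H^-1 is not positive definite");
  }
  arma::mat Linv = arma::inv(arma::trimatl(L));
  arma::mat Scl = Linv * arma::diagmat(arma::sqrt(cnt_s));
  arma::mat M = Scl * Scl.t();
  arma::vec lam_eig;
  arma::mat Q;
  if (!arma::eig_sym(lam_eig, Q, M)) stop("eigendecomposition of the sire block failed");
  arma::mat Binv = Q.t() * Linv;     // B^-1, with B = L Q
  arma::mat BinvT = Binv.t();        // B^-T

  const int df_h = nh + (int)nu_h, df_s = ns + (int)nu_s;
  if (!gaussian && (df_h <= 0 || df_s <= 0))
    stop("too few levels for the variance full conditionals under this prior");

  arma::vec beta(nb, arma::fill::zeros), h(nh, arma::fill::zeros),
            s(ns, arma::fill::zeros), lambda(n, arma::fill::zeros);
  double sigma2_h = sigma2_h0, sigma2_s = sigma2_s0;
  if (gaussian) for (int i = 0; i < n; ++i) lambda[i] = lambda_obs[i];

  const int nkeep = (niter - burnin) / thin;
  arma::mat var_samples(nkeep, 3);                    // sigma2_h, sigma2_s, h2
  arma::mat loc_samples(nkeep, nb + nh + ns);
  int kept = 0;

  arma::vec fitted(n), resid(n), rhs_h(nh), rhs_s(ns);

  for (int it = 1; it <= niter; ++it) {
    // 1. liabilities
    if (!gaussian) {
      for (int i = 0; i < n; ++i) {
        double mu = h[hy[i] - 1] + s[sv[i] - 1];
        for (int j = 0; j < nb; ++j) mu += X(i, j) * beta[j];
        lambda[i] = (y[i] == 1) ? rtnorm_pos(mu) : -rtnorm_pos(-mu);
      }
    }

    // 2. beta | h, s  (flat prior)
    for (int i = 0; i < n; ++i) resid[i] = lambda[i] - h[hy[i] - 1] - s[sv[i] - 1];
    {
      arma::vec rhs = X.t() * resid;
      arma::vec bhat = arma::solve(arma::trimatu(Rb),
                                   arma::solve(arma::trimatl(Rb.t()), rhs));
      arma::vec z(nb);
      for (int j = 0; j < nb; ++j) z[j] = R::norm_rand();
      beta = bhat + arma::solve(arma::trimatu(Rb), z);
    }

    // 3. h | beta, s  (diagonal precision cnt_h + 1/sigma2_h)
    {
      arma::vec xb = X * beta;
      rhs_h.zeros();
      for (int i = 0; i < n; ++i) rhs_h[hy[i] - 1] += lambda[i] - xb[i] - s[sv[i] - 1];
      double prec0 = 1.0 / sigma2_h;
      for (int k = 0; k < nh; ++k) {
        double prec = cnt_h[k] + prec0;
        h[k] = rhs_h[k] / prec + R::norm_rand() / std::sqrt(prec);
      }

      // 4. s | beta, h  via the spectral factorization of the precision
      rhs_s.zeros();
      for (int i = 0; i < n; ++i) rhs_s[sv[i] - 1] += lambda[i] - xb[i] - h[hy[i] - 1];
      arma::vec v = Binv * rhs_s;
      arma::vec u(ns);
      double precs = 1.0 / sigma2_s;
      for (int k = 0; k < ns; ++k) {
        double den = lam_eig[k] + precs;
        u[k] = v[k] / den + R::norm_rand() / std::sqrt(den);
      }
      s = BinvT * u;
    }

    // 5. variance components (scaled inverse chi-square full conditionals);
    //    residual variance stays fixed at 1
    if (!gaussian) {
      double ssq_h = arma::dot(h, h) + nu_h * S_h;
      sigma2_h = ssq_h / R::rchisq((double)df_h);
      arma::vec q = Hinv * s;
      double ssq_s = arma::dot(s, q) + nu_s * S_s;
      sigma2_s = ssq_s / R::rchisq((double)df_s);
    }

    if (it > burnin && (it - burnin) % thin == 0 && kept < nkeep) {
      double h2 = 4.0 * sigma2_s / (sigma2_s + sigma2_h + 1.0);
      var_samples(kept, 0) = sigma2_h;
      var_samples(kept, 1) = sigma2_s;
      var_samples(kept, 2) = h2;
      for (int j = 0; j < nb; ++j) loc_samples(kept, j) = beta[j];
      for (int k = 0; k < nh; ++k) loc_samples(kept, nb + k) = h[k];
      for (int k = 0; k < ns; ++k) loc_samples(kept, nb + nh + k) = s[k];
      ++kept;
    }
  }

  return List::create(_["var_samples"] = var_samples,
                      _["loc_samples"] = loc_samples,
                      _["n_kept"] = kept);
}
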