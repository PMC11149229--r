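// Block-structured MCMC kernel shared by every fitter in the package.
//
// A posterior is assembled from up to four optional blocks:
//   * a case-control logistic block      y_c ~ Bern(invlogit(X_c beta_c))
//   * a population logistic block, either with its own coefficients
//     (pop_mode = 1, re-estimation) or through a shrinkage pair
//     (pop_mode = 2): y_u ~ Bern(invlogit(g0 + g1 * X_u beta_c))
//   * a constrained-branch Bernoulli block with a Beta prior on its
//     probability (parameterised on the logit scale; the Beta density
//     plus log-Jacobian gives a*log(p) + b*log(1-p) up to a constant)
//   * a biomarker-membership logistic block  t ~ Bern(invlogit(X_t beta_t))
//
// All regression parameters carry independent normal priors and are updated
// jointly by adaptive random-walk Metropolis (Haario-style covariance
// adaptation with Robbins-Monro scale tuning during burn-in, frozen after).
// The branch probability is posterior-independent of the regression blocks,
// so it is updated by univariate slice sampling, which keeps autocorrelation
// near zero for this one-dimensional unimodal conditional.
//
// Randomness comes from R's RNG (RNGScope), so chains are reproducible via
// set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double bern_loglik(const arma::vec &lp, const arma::vec &y) {
  double ll = 0.0;
  const arma::uword n = lp.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    // stable -log(1 + exp(-s)) with s = (2y-1) * linear predictor
    double s = (2.0 * y[i] - 1.0) * lp[i];
    if (s < -37.0) ll += s;
    else ll += -std::log1p(std::exp(-s));
  }
  return ll;
}

struct BlockModel {
  const arma::mat &Xc; const arma::vec &yc; bool use_cc;
  const arma::mat &Xu; const arma::vec &yu; int pop_mode;
  bool use_b1; double m1, n1, a1, b1;
  const arma::mat &Xt; const arma::vec &yt; bool use_t;
  const arma::vec &prior_mean; const arma::vec &prior_sd;

  int pC, pU, nG, pT, d, idx_b1;

  BlockModel(const arma::mat &Xc_, const arma::vec &yc_, bool use_cc_,
             const arma::mat &Xu_, const arma::vec &yu_, int pop_mode_,
             bool use_b1_, double m1_, double n1_, double a1_, double b1_,
             const arma::mat &Xt_, const arma::vec &yt_, bool use_t_,
             const arma::vec &pm, const arma::vec &ps)
      : Xc(Xc_), yc(yc_), use_cc(use_cc_), Xu(Xu_), yu(yu_),
        pop_mode(pop_mode_), use_b1(use_b1_), m1(m1_), n1(n1_), a1(a1_),
        b1(b1_), Xt(Xt_), yt(yt_), use_t(use_t_), prior_mean(pm),
        prior_sd(ps) {
    pC = use_cc ? (int)Xc.n_cols : 0;
    pU = (pop_mode == 1) ? (int)Xu.n_cols : 0;
    nG = (pop_mode == 2) ? 2 : 0;
    pT = use_t ? (int)Xt.n_cols : 0;
    idx_b1 = pC + pU + nG;          // position of logit branch prob, if any
    d = pC + pU + nG + (use_b1 ? 1 : 0) + pT;
  }

  double logpost(const arma::vec &theta) const {
    double ll = 0.0;
    int off = 0;
    arma::vec betaC;
    if (use_cc) {
      betaC = theta.subvec(0, pC - 1);
      ll += bern_loglik(Xc * betaC, yc);
      off += pC;
    }
    if (pop_mode == 1) {
      ll += bern_loglik(Xu * theta.subvec(off, off + pU - 1), yu);
      off += pU;
    } else if (pop_mode == 2) {
      double g0 = theta[off], g1 = theta[off + 1];
      arma::vec z = Xu * betaC;
      ll += bern_loglik(g0 + g1 * z, yu);
      off += 2;
    }
    if (use_b1) {
      double lp1 = theta[off];
      // log p = -log1p(exp(-lp1)), log(1-p) = -log1p(exp(lp1)), stabilised
      double logp = (lp1 < -37.0) ? lp1 : -std::log1p(std::exp(-lp1));
      double log1mp = (lp1 > 37.0) ? -lp1 : -std::log1p(std::exp(lp1));
      // likelihood m*log p + (n-m)*log(1-p); prior+Jacobian a*log p + b*log(1-p)
      ll += (m1 + a1) * logp + (n1 - m1 + b1) * log1mp;
      off += 1;
    }
    if (use_t) {
      ll += bern_loglik(Xt * theta.subvec(off, off + pT - 1), yt);
      off += pT;
    }
    // independent normal priors on every parameter except the branch logit
    for (int j = 0; j < d; ++j) {
      if (use_b1 && j == idx_b1) continue;
      double zf = (theta[j] - prior_mean[j]) / prior_sd[j];
      ll += -0.5 * zf * zf;
    }
    if (!std::isfinite(ll)) ll = -std::numeric_limits<double>::infinity();
    return ll;
  }

  // log conditional density of the branch logit alone (posterior-independent)
  double logdens_b1(double lp1) const {
    double logp = (lp1 < -37.0) ? lp1 : -std::log1p(std::exp(-lp1));
    double log1mp = (lp1 > 37.0) ? -lp1 : -std::log1p(std::exp(lp1));
    return (m1 + a1) * logp + (n1 - m1 + b1) * log1mp;
  }
};

// univariate slice sampler (stepping out + shrinkage), Neal (2003)
static double slice_update(const BlockModel &mod, double x0, double w) {
  double f0 = mod.logdens_b1(x0);
  double logy = f0 + std::log(R::runif(0.0, 1.0));
  double u = R::runif(0.0, 1.0);
  double L = x0 - w * u, Rr = L + w;
  int steps = 0;
  while (mod.logdens_b1(L) > logy && steps++ < 100) L -= w;
  steps = 0;
  while (mod.logdens_b1(Rr) > logy && steps++ < 100) Rr += w;
  for (int it = 0; it < 200; ++it) {
    double x1 = R::runif(L, Rr);
    if (mod.logdens_b1(x1) > logy) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0;
}

// [[Rcpp::export]]
List run_chain_cpp(const arma::mat &Xc, const arma::vec &yc, bool use_cc,
                   const arma::mat &Xu, const arma::vec &yu, int pop_mode,
                   bool use_b1, double m1, double n1, double a1, double b1,
                   const arma::mat &Xt, const arma::vec &yt, bool use_t,
                   const arma::vec &prior_mean, const arma::vec &prior_sd,
                   const arma::vec &init, int n_iter, int n_burn, int thin,
                   double slice_w, const arma::mat &prop_chol) {
  RNGScope scope;
  BlockModel mod(Xc, yc, use_cc, Xu, yu, pop_mode, use_b1, m1, n1, a1, b1,
                 Xt, yt, use_t, prior_mean, prior_sd);
  const int d = mod.d;
  if ((int)init.n_elem != d) stop("init length does not match parameter count");

  // indices of the Metropolis (regression) block
  std::vector<int> mh_idx;
  for (int j = 0; j < d; ++j)
    if (!(use_b1 && j == mod.idx_b1)) mh_idx.push_back(j);
  const int dm = (int)mh_idx.size();

  arma::vec theta = init;
  double lp_cur = mod.logpost(theta);
  if (!std::isfinite(lp_cur))
    stop("non-finite log posterior at initial values");

  const int n_keep = (n_iter - n_burn) / thin;
  arma::mat out(n_keep, d);

  // adaptation state; an externally supplied Laplace proposal (lower
  // Cholesky of 2.38^2/d * cov) seeds the kernel, Haario adaptation then
  // refines it during burn-in
  arma::vec mu = arma::zeros(dm);
  arma::mat M2 = arma::zeros(dm, dm);        // running scatter
  arma::mat chol_prop;
  bool have_chol = false;
  double log_lambda = std::log(0.1 / std::sqrt((double)std::max(dm, 1)));
  if (prop_chol.n_rows == (arma::uword)dm && dm > 0) {
    chol_prop = prop_chol;
    have_chol = true;
    log_lambda = 0.0;
  }
  const double acc_target = (dm <= 2) ? 0.44 : 0.234;
  long n_adapt = 0;
  int accepted = 0, proposed = 0;
  const double eps_reg = 1e-10;

  int keep_row = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    if (dm > 0) {
      arma::vec cur(dm), prop(dm);
      for (int k = 0; k < dm; ++k) cur[k] = theta[mh_idx[k]];

      arma::vec zr(dm);
      for (int k = 0; k < dm; ++k) zr[k] = R::rnorm(0.0, 1.0);
      if (have_chol) prop = cur + std::exp(log_lambda) * (chol_prop * zr);
      else prop = cur + std::exp(log_lambda) * zr;

      arma::vec theta_prop = theta;
      for (int k = 0; k < dm; ++k) theta_prop[mh_idx[k]] = prop[k];
      double lp_prop = mod.logpost(theta_prop);
      double alpha = std::min(1.0, std::exp(lp_prop - lp_cur));
      ++proposed;
      if (R::runif(0.0, 1.0) < alpha) {
        theta = theta_prop;
        lp_cur = lp_prop;
        ++accepted;
      }

      if (iter <= n_burn) {
        // Robbins-Monro scale tuning + running covariance (Haario)
        double gam = 1.0 / std::pow((double)iter, 0.6);
        log_lambda += gam * (alpha - acc_target);
        ++n_adapt;
        arma::vec x(dm);
        for (int k = 0; k < dm; ++k) x[k] = theta[mh_idx[k]];
        arma::vec delta = x - mu;
        mu += delta / (double)n_adapt;
        M2 += delta * (x - mu).t();
        if (n_adapt >= 10 * dm && iter % 50 == 0) {
          arma::mat S = M2 / (double)(n_adapt - 1);
          S.diag() += eps_reg;
          arma::mat C;
          if (arma::chol(C, (2.38 * 2.38 / (double)dm) * S, "lower")) {
            chol_prop = C;
            if (!have_chol) { have_chol = true; log_lambda = 0.0; }
          }
        }
      }
    }

    if (use_b1) {
      double old_b1 = theta[mod.idx_b1];
      double new_b1 = slice_update(mod, old_b1, slice_w);
      theta[mod.idx_b1] = new_b1;
      // the branch term is separable, so update the cached log posterior
      lp_cur += mod.logdens_b1(new_b1) - mod.logdens_b1(old_b1);
    }

    if (iter > n_burn && ((iter - n_burn) % thin == 0)) {
      out.row(keep_row++) = theta.t();
    }
  }

  return List::create(
      _["draws"] = out,
      _["accept_rate"] = proposed > 0 ? (double)accepted / proposed : NA_REAL);
}
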