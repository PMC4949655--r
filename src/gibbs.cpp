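// Gibbs samplers for whole-genome regression: y = mu*1 + Z beta + e.
//
// Five priors on beta_k (method codes):
//   1 BayesA     beta_k ~ scaled-t(nu, lambda) via N(0, sig2_k),
//                sig2_k ~ scaled-inv-chisq(nu, lambda)
//   2 BayesB     as BayesA but beta_k = 0 exactly with prob (1 - pi)
//   3 BayesC     beta_k ~ pi N(0, sigs2) + (1 - pi) point mass at 0
//   4 SSVS       beta_k ~ pi N(0, sigs2) + (1 - pi) N(0, sigs2 / div)
//   5 BayesLasso beta_k ~ Laplace(lambda) via N(0, tau2_k),
//                tau2_k ~ Exp(lambda^2 / 2)
//
// Hyperparameters (lambda, nu, sigs2, pi where estimated) and sigma_e^2 carry
// bounded flat priors; nu is updated by griddy Gibbs on a fixed grid.
// Uses R's RNG throughout so set.seed() in R gives reproducible chains.

#include <Rcpp.h>
using namespace Rcpp;

// scaled-inv-chisq(df, scale) draw: df * scale / chisq(df)
static inline double rscinvchisq(double df, double scale) {
  return df * scale / R::rchisq(df);
}

// X ~ Gamma(shape, rate) truncated to X >= lo  (used for variance draws
// sig2 = S / (2X) under a flat prior bounded above on sig2)
static double rgamma_ltrunc(double shape, double rate, double lo) {
  double plo = R::pgamma(lo, shape, 1.0 / rate, 1, 0);
  if (plo > 1.0 - 1e-12) return lo; // numerically all mass below lo
  double u = plo + unif_rand() * (1.0 - plo);
  return R::qgamma(u, shape, 1.0 / rate, 1, 0);
}

// X ~ Gamma(shape, rate) truncated to X <= hi
static double rgamma_rtrunc(double shape, double rate, double hi) {
  double phi = R::pgamma(hi, shape, 1.0 / rate, 1, 0);
  if (phi < 1e-300) return hi;
  double u = unif_rand() * phi;
  return R::qgamma(u, shape, 1.0 / rate, 1, 0);
}

// inverse-Gaussian(mu, lambda), Michael-Schucany-Haas
static double rinvgauss(double mu, double lambda) {
  double z = norm_rand();
  double y = z * z;
  double x = mu + mu * mu * y / (2.0 * lambda) -
             (mu / (2.0 * lambda)) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// log marginal-likelihood gain of fitting beta_k ~ N(0, v) vs beta_k = 0,
// given rhs = z_k' r (r = residual with SNP k removed) and zz = z_k' z_k
static inline double log_ml_ratio(double v, double zz, double rhs, double se2) {
  double d = se2 + v * zz;
  return 0.5 * std::log(se2 / d) + 0.5 * v * rhs * rhs / (se2 * d);
}

// [[Rcpp::export]]
List gibbs_wgr_cpp(const NumericMatrix& Z, const NumericVector& y, int method,
                   int burnin, int nsamples, int thin,
                   double pi0, bool estimate_pi,
                   NumericVector nu_grid,
                   double bound_lambda, double bound_s2, double bound_e2,
                   double ssvs_div,
                   double fix_s2, double fix_e2,
                   Nullable<NumericMatrix> Zval_,
                   bool store_beta) {
  const bool s2_fixed = std::isfinite(fix_s2);
  const bool e2_fixed = std::isfinite(fix_e2);
  const int n = Z.nrow(), m = Z.ncol();
  if (nsamples < 2) stop("need at least 2 retained samples (PEV undefined otherwise)");
  if (method < 1 || method > 5) stop("unknown method code");
  const bool has_t = (method == 1 || method == 2);      // scaled-t variances
  const bool has_delta = (method >= 2 && method <= 4);  // indicator models
  const bool is_lasso = (method == 5);
  const bool has_sigs2 = (method == 3 || method == 4);

  NumericMatrix Zval;
  int nval = 0;
  if (Zval_.isNotNull()) { Zval = Zval_.get(); nval = Zval.nrow(); }

  // precompute column sums of squares
  std::vector<double> zz(m);
  for (int k = 0; k < m; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, k) * Z(i, k);
    zz[k] = s;
  }

  // initial state
  double ybar = mean(y), vary = var(y);
  if (vary <= 0.0) stop("phenotype variance must be > 0");
  double mu = ybar, se2 = 0.5 * vary;
  double vzbar = 0.0;
  for (int k = 0; k < m; ++k) vzbar += zz[k];
  vzbar = std::max(vzbar / (double(n) * double(m)), 1e-8);
  double pi = pi0;
  double lambda, nu = 4.0, sigs2 = 0.0;
  std::vector<double> beta(m, 0.0), sig2k, tau2;
  std::vector<int> delta(m, 1);
  if (has_t) {
    // scale so prior E[sig2_k] spreads half the phenotypic variance
    double target = 0.5 * vary / (std::max(1.0, pi * m) * vzbar);
    lambda = std::min(target * (nu - 2.0) / nu, bound_lambda);
    sig2k.assign(m, target);
  } else {
    lambda = std::min(std::sqrt(2.0 * m * vzbar / (0.5 * vary)), bound_lambda);
  }
  if (has_sigs2) sigs2 = std::min(0.5 * vary / (std::max(1.0, pi * m) * vzbar), bound_s2);
  if (s2_fixed) sigs2 = fix_s2;
  if (e2_fixed) se2 = fix_e2;
  if (is_lasso) tau2.assign(m, 0.5 * vary / (m * vzbar));
  if (has_delta) for (int k = 0; k < m; ++k) delta[k] = (unif_rand() < pi) ? 1 : 0;

  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  std::vector<double> gval(nval, 0.0);

  // accumulators
  std::vector<double> gsum(n, 0.0), gss(n, 0.0), bsum(m, 0.0), dsum(m, 0.0);
  std::vector<double> gvsum(nval, 0.0), gvss(nval, 0.0);
  NumericVector se2_chain(nsamples), mu_chain(nsamples);
  NumericVector lam_chain(has_t || is_lasso ? nsamples : 0);
  NumericVector nu_chain(has_t ? nsamples : 0);
  NumericVector pi_chain(has_delta ? nsamples : 0);
  NumericVector s2_chain(has_sigs2 ? nsamples : 0);
  NumericMatrix beta_chain(store_beta ? nsamples : 0, store_beta ? m : 0);

  const int total = burnin + nsamples * thin;
  const int ngrid = nu_grid.size();
  std::vector<double> gridlp(ngrid);
  int kept = 0;

  for (int cyc = 1; cyc <= total; ++cyc) {
    // ---- effects sweep ----
    for (int k = 0; k < m; ++k) {
      double bold = beta[k];
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += Z(i, k) * e[i];
      rhs += zz[k] * bold; // z_k' (residual with SNP k removed)
      double bnew = 0.0;
      if (method == 1) { // BayesA
        double C = zz[k] + se2 / sig2k[k];
        bnew = rhs / C + norm_rand() * std::sqrt(se2 / C);
      } else if (method == 2) { // BayesB: point mass + scaled-t slab
        double lr = std::log(pi / (1.0 - pi)) + log_ml_ratio(sig2k[k], zz[k], rhs, se2);
        delta[k] = (unif_rand() < 1.0 / (1.0 + std::exp(-lr))) ? 1 : 0;
        if (delta[k]) {
          double C = zz[k] + se2 / sig2k[k];
          bnew = rhs / C + norm_rand() * std::sqrt(se2 / C);
        }
      } else if (method == 3) { // BayesC
        double lr = std::log(pi / (1.0 - pi)) + log_ml_ratio(sigs2, zz[k], rhs, se2);
        delta[k] = (unif_rand() < 1.0 / (1.0 + std::exp(-lr))) ? 1 : 0;
        if (delta[k]) {
          double C = zz[k] + se2 / sigs2;
          bnew = rhs / C + norm_rand() * std::sqrt(se2 / C);
        }
      } else if (method == 4) { // SSVS: slab vs spike, both normal
        double v1 = sigs2, v0 = sigs2 / ssvs_div;
        double lr = std::log(pi / (1.0 - pi)) +
                    log_ml_ratio(v1, zz[k], rhs, se2) - log_ml_ratio(v0, zz[k], rhs, se2);
        delta[k] = (unif_rand() < 1.0 / (1.0 + std::exp(-lr))) ? 1 : 0;
        double v = delta[k] ? v1 : v0;
        double C = zz[k] + se2 / v;
        bnew = rhs / C + norm_rand() * std::sqrt(se2 / C);
      } else { // BayesLasso
        double C = zz[k] + se2 / tau2[k];
        bnew = rhs / C + norm_rand() * std::sqrt(se2 / C);
      }
      double db = bnew - bold;
      if (db != 0.0) {
        beta[k] = bnew;
        for (int i = 0; i < n; ++i) e[i] -= Z(i, k) * db;
        for (int i = 0; i < nval; ++i) gval[i] += Zval(i, k) * db;
      }
      // per-SNP variance updates
      if (has_t) {
        sig2k[k] = (method == 2 && !delta[k])
          ? rscinvchisq(nu, lambda) // prior draw for excluded SNPs
          : rscinvchisq(nu + 1.0, (nu * lambda + beta[k] * beta[k]) / (nu + 1.0));
      } else if (is_lasso) {
        double ab = std::fabs(beta[k]);
        if (ab < 1e-10) {
          tau2[k] = R::rexp(2.0 / (lambda * lambda));
        } else {
          tau2[k] = 1.0 / rinvgauss(lambda / ab, lambda * lambda);
        }
        if (tau2[k] < 1e-12) tau2[k] = 1e-12;
      }
    }

    // ---- mean ----
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double munew = (mu + ebar) + norm_rand() * std::sqrt(se2 / n);
    double dmu = munew - mu;
    mu = munew;
    for (int i = 0; i < n; ++i) e[i] -= dmu;

    // ---- hyperparameters ----
    if (has_t) {
      double sinv = 0.0, slog = 0.0;
      for (int k = 0; k < m; ++k) { sinv += 1.0 / sig2k[k]; slog += std::log(sig2k[k]); }
      // lambda | sig2k: Gamma(m nu / 2 + 1, nu/2 * sum 1/sig2k), flat prior, bounded
      lambda = rgamma_rtrunc(0.5 * m * nu + 1.0, 0.5 * nu * sinv, bound_lambda);
      if (lambda < 1e-12) lambda = 1e-12;
      // nu | sig2k, lambda: griddy Gibbs on the fixed grid
      double lpmax = -1e300;
      for (int g = 0; g < ngrid; ++g) {
        double v = nu_grid[g];
        double lp = m * (0.5 * v * std::log(0.5 * v * lambda) - R::lgammafn(0.5 * v)) -
                    (1.0 + 0.5 * v) * slog - 0.5 * v * lambda * sinv;
        gridlp[g] = lp;
        if (lp > lpmax) lpmax = lp;
      }
      double tot = 0.0;
      for (int g = 0; g < ngrid; ++g) { gridlp[g] = std::exp(gridlp[g] - lpmax); tot += gridlp[g]; }
      double u = unif_rand() * tot, acc = 0.0;
      nu = nu_grid[ngrid - 1];
      for (int g = 0; g < ngrid; ++g) { acc += gridlp[g]; if (u <= acc) { nu = nu_grid[g]; break; } }
    }
    if (is_lasso) {
      double st = 0.0;
      for (int k = 0; k < m; ++k) st += tau2[k];
      // lambda^2 | tau2: Gamma(m + 1, sum tau2 / 2), flat prior on lambda^2, bounded
      double lam2 = rgamma_rtrunc(m + 1.0, 0.5 * st, bound_lambda * bound_lambda);
      lambda = std::sqrt(std::max(lam2, 1e-12));
    }
    if (has_sigs2 && !s2_fixed) {
      double S = 0.0; int meff = 0;
      if (method == 3) {
        for (int k = 0; k < m; ++k) if (delta[k]) { S += beta[k] * beta[k]; ++meff; }
      } else { // SSVS: all SNPs inform sigs2 through their component scaling
        for (int k = 0; k < m; ++k) {
          S += beta[k] * beta[k] * (delta[k] ? 1.0 : ssvs_div);
        }
        meff = m;
      }
      if (meff >= 3 && S > 0.0) {
        double x = rgamma_ltrunc(0.5 * meff - 1.0, 1.0, S / (2.0 * bound_s2));
        sigs2 = S / (2.0 * x);
      } // else: keep current value (degenerate conditional under flat prior)
    }
    if (has_delta && estimate_pi) {
      int min = 0;
      for (int k = 0; k < m; ++k) min += delta[k];
      pi = R::rbeta(min + 1.0, m - min + 1.0);
      if (pi < 1e-8) pi = 1e-8;
      if (pi > 1.0 - 1e-8) pi = 1.0 - 1e-8;
    }
    // residual variance, flat prior on (0, bound_e2]
    if (!e2_fixed) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      double x = rgamma_ltrunc(0.5 * n - 1.0, 1.0, sse / (2.0 * bound_e2));
      se2 = sse / (2.0 * x);
    }
    if (!std::isfinite(se2) || se2 <= 0.0)
      stop("non-finite sampler state at cycle %d", cyc);

    // periodic refresh of residual to cancel incremental round-off
    if (cyc % 10000 == 0) {
      for (int i = 0; i < n; ++i) {
        double g = 0.0;
        for (int k = 0; k < m; ++k) g += Z(i, k) * beta[k];
        e[i] = y[i] - mu - g;
      }
      for (int i = 0; i < nval; ++i) {
        double g = 0.0;
        for (int k = 0; k < m; ++k) g += Zval(i, k) * beta[k];
        gval[i] = g;
      }
    }

    // ---- retain ----
    if (cyc > burnin && (cyc - burnin) % thin == 0) {
      for (int i = 0; i < n; ++i) {
        double g = y[i] - mu - e[i];
        gsum[i] += g; gss[i] += g * g;
      }
      for (int i = 0; i < nval; ++i) { gvsum[i] += gval[i]; gvss[i] += gval[i] * gval[i]; }
      for (int k = 0; k < m; ++k) { bsum[k] += beta[k]; dsum[k] += delta[k]; }
      se2_chain[kept] = se2; mu_chain[kept] = mu;
      if (has_t || is_lasso) lam_chain[kept] = lambda;
      if (has_t) nu_chain[kept] = nu;
      if (has_delta) pi_chain[kept] = pi;
      if (has_sigs2) s2_chain[kept] = sigs2;
      if (store_beta) for (int k = 0; k < m; ++k) beta_chain(kept, k) = beta[k];
      ++kept;
    }
    if (cyc % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  const double ns = (double)nsamples;
  NumericVector gebv(n), pev(n), bmean(m), incl(m);
  for (int i = 0; i < n; ++i) {
    gebv[i] = gsum[i] / ns;
    pev[i] = std::max((gss[i] - gsum[i] * gsum[i] / ns) / (ns - 1.0), 0.0);
  }
  for (int k = 0; k < m; ++k) { bmean[k] = bsum[k] / ns; incl[k] = dsum[k] / ns; }
  NumericVector gebv_val(nval), pev_val(nval);
  for (int i = 0; i < nval; ++i) {
    gebv_val[i] = gvsum[i] / ns;
    pev_val[i] = std::max((gvss[i] - gvsum[i] * gvsum[i] / ns) / (ns - 1.0), 0.0);
  }

  List chains = List::create(_["sigma_e2"] = se2_chain, _["mu"] = mu_chain);
  if (has_t || is_lasso) chains["lambda"] = lam_chain;
  if (has_t) chains["nu"] = nu_chain;
  if (has_delta) chains["pi"] = pi_chain;
  if (has_sigs2) chains["sigma_s2"] = s2_chain;

  double mu_mean = mean(mu_chain);
  List out = List::create(
    _["beta"] = bmean, _["mu"] = mu_mean,
    _["gebv"] = gebv, _["pev"] = pev,
    _["gebv_val"] = gebv_val, _["pev_val"] = pev_val,
    _["inclusion_prob"] = incl, _["chains"] = chains);
  if (store_beta) out["beta_chain"] = beta_chain;
  return out;
}
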