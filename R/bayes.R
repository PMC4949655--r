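#' Bayesian whole-genome regression by Gibbs sampling
#'
#' Fits `y = mu 1 + Z beta + e` with one of five priors on the SNP effects:
#'
#' * **BayesA** - every `beta_k` from a scaled Student's t with scale `lambda`
#'   and shape `nu` (normal-scale-mixture representation: `beta_k ~ N(0,
#'   sigma_k^2)`, `sigma_k^2 ~` scaled-inverse-chi-square(`nu`, `lambda`)).
#' * **BayesB** - as BayesA but only a fraction `pi` of SNPs have effects;
#'   the rest are an exact point mass at zero.
#' * **BayesC** - non-zero effects normal with a common variance `sigma_s2`,
#'   mixing proportion `pi` (fixed at 0.1 by default, the study's choice).
#' * **BayesSSVS** - every effect from a two-component normal mixture with
#'   variances `sigma_s2` and `sigma_s2 / 10000`.
#' * **BayesLasso** - Laplace prior with scale `lambda`
#'   (normal-exponential augmentation).
#'
#' Hyperparameters (`lambda`, `nu`, `sigma_s2`, and `pi` where not fixed) are
#' estimated from the data under bounded flat priors; `nu` is restricted to
#' `[0.5, 8]` and updated by griddy Gibbs on a log-spaced grid. The residual
#' variance carries a bounded flat prior. Genotype columns are used
#' uncentred (the model carries an explicit mean); set `center = TRUE` to
#' centre them (correlation-based accuracies are invariant to this).
#'
#' @param y numeric phenotype vector (pre-corrected log concentrations).
#' @param Z animals x SNPs matrix of allele counts, or a [geno_matrix()];
#'   must be complete (run [impute_missing()] first).
#' @param method one of `"BayesA"`, `"BayesB"`, `"BayesC"`, `"BayesSSVS"`,
#'   `"BayesLasso"`.
#' @param schedule a [chain_schedule()]; the default is the study's
#'   50 000 / 20 000 / 50 (long-running) - pass a reduced schedule for
#'   interactive work.
#' @param pi mixing proportion: `NULL` estimates it with a uniform prior
#'   (default for BayesB/SSVS); a value in (0, 1] fixes it. BayesC defaults
#'   to fixed 0.1.
#' @param nu_bounds bounds of the shape parameter grid, default `c(0.5, 8)`.
#' @param nu_grid_size griddy-Gibbs grid points (default 64, log-spaced).
#' @param bounds named list of flat-prior upper bounds (`lambda`, `sigma_s2`,
#'   `sigma_e2`); defaults are 1e6 x the phenotypic variance
#'   (and 1e6 for `lambda`) so the prior influence is negligible.
#' @param ssvs_div divisor of the SSVS small-variance component (10 000).
#' @param fix named list fixing hyperparameters instead of estimating them:
#'   elements `sigma_s2` and/or `sigma_e2` (used by the conjugate oracle
#'   checks; normal analyses estimate everything).
#' @param Z_val optional validation genotype rows (same SNP columns): their
#'   genetic values are tracked along the chain, giving posterior means and
#'   prediction error variances for unphenotyped animals.
#' @param center centre genotype columns before sampling.
#' @param store_beta keep the full effect chain (memory heavy; small panels).
#' @param seed RNG seed (chains are reproducible given the seed).
#' @return an object of class `bayes_wgr`: per-SNP posterior mean effects
#'   (`beta`), posterior mean `mu`, per-animal genetic value posterior means
#'   (`gebv`) and prediction error variances (`pev`), the same for validation
#'   animals (`gebv_val`, `pev_val`), per-SNP `inclusion_prob`, retained
#'   hyperparameter `chains`, and the Nadaf genetic variance / heritability
#'   computed from the chain (`sigma_g2`, `sigma_e2`, `h2`).
#' @references The sampler implements the model descriptions of the boar-taint
#'   genomic evaluation study this package emulates.
#' @export
bayes_wgr <- function(y, Z, method = c("BayesA", "BayesB", "BayesC",
                                       "BayesSSVS", "BayesLasso"),
                      schedule = chain_schedule(), pi = NULL,
                      nu_bounds = c(0.5, 8), nu_grid_size = 64,
                      bounds = list(), ssvs_div = 10000, fix = list(),
                      Z_val = NULL, center = FALSE,
                      store_beta = FALSE, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(schedule, "chain_schedule"))
  if (inherits(Z, "geno_matrix")) Z <- Z$codes
  Z <- as.matrix(Z)
  if (!is.null(Z_val)) {
    if (inherits(Z_val, "geno_matrix")) Z_val <- Z_val$codes
    Z_val <- as.matrix(Z_val)
    stopifnot(ncol(Z_val) == ncol(Z))
  }
  stopifnot(length(y) == nrow(Z))
  if (anyNA(Z) || (!is.null(Z_val) && anyNA(Z_val)))
    stop("genotypes must be complete; run impute_missing() first")
  if (var(y) <= 0) stop("phenotype variance must be > 0")
  if (center) {
    cm <- colMeans(Z)
    Z <- sweep(Z, 2, cm)
    if (!is.null(Z_val)) Z_val <- sweep(Z_val, 2, cm)
  }
  mcode <- match(method, c("BayesA", "BayesB", "BayesC", "BayesSSVS", "BayesLasso"))
  estimate_pi <- is.null(pi)
  if (method %in% c("BayesA", "BayesLasso")) { pi0 <- 1; estimate_pi <- FALSE }
  else if (estimate_pi && method == "BayesC") { pi0 <- 0.1; estimate_pi <- FALSE }
  else if (estimate_pi) pi0 <- 0.5
  else {
    if (pi <= 0 || pi > 1) stop("fixed pi must lie in (0, 1]")
    pi0 <- min(pi, 1 - 1e-12)
  }
  stopifnot(length(nu_bounds) == 2, nu_bounds[1] > 0, nu_bounds[2] > nu_bounds[1])
  if (nu_bounds[1] != 0.5 || nu_bounds[2] != 8)
    warning("nu bounds differ from the default [0.5, 8]")
  nu_grid <- exp(seq(log(nu_bounds[1]), log(nu_bounds[2]),
                     length.out = nu_grid_size))
  vy <- var(y)
  b <- list(lambda = 1e6, sigma_s2 = 1e6 * vy, sigma_e2 = 1e6 * vy)
  b[names(bounds)] <- bounds
  if (!is.null(seed)) set.seed(seed)
  res <- gibbs_wgr_cpp(Z, y, mcode, schedule$burnin, schedule$n_samples,
                       schedule$thin, pi0, estimate_pi, nu_grid,
                       b$lambda, b$sigma_s2, b$sigma_e2, ssvs_div,
                       fix$sigma_s2 %||% NA_real_, fix$sigma_e2 %||% NA_real_,
                       Z_val, store_beta)
  names(res$beta) <- names(res$inclusion_prob) <- colnames(Z)
  names(res$gebv) <- names(res$pev) <- rownames(Z) %||% names(y)
  if (!is.null(Z_val)) names(res$gebv_val) <- names(res$pev_val) <- rownames(Z_val)
  sg2 <- nadaf_genetic_variance(res$gebv, res$pev)
  se2 <- mean(res$chains$sigma_e2)
  fit <- structure(c(res, list(
    method = method, schedule = schedule, n = nrow(Z), m = ncol(Z),
    pi_fixed = if (estimate_pi) NULL else pi0, bounds = b,
    sigma_g2 = sg2, sigma_e2 = se2, h2 = heritability(sg2, se2),
    seed = seed)), class = "bayes_wgr")
  fit
}

#' @export
print.bayes_wgr <- function(x, ...) {
  cat(sprintf("%s fit (Gibbs): %d animals x %d SNPs\n", x$method, x$n, x$m))
  cat(sprintf("  schedule: burn-in %d, %d samples, thin %d (%s cycles)\n",
              x$schedule$burnin, x$schedule$n_samples, x$schedule$thin,
              format(chain_total_cycles(x$schedule), big.mark = " ")))
  cat(sprintf("  sigma_g2 (Nadaf) = %.4f  sigma_e2 = %.4f  h2 = %.3f\n",
              x$sigma_g2, x$sigma_e2, x$h2))
  invisible(x)
}

#' @export
summary.bayes_wgr <- function(object, ...) {
  ch <- object$chains
  hyp <- t(vapply(ch, function(v) c(mean = mean(v), sd = sd(v)), c(0, 0)))
  out <- list(method = object$method, n = object$n, m = object$m,
              sigma_g2 = object$sigma_g2, sigma_e2 = object$sigma_e2,
              h2 = object$h2, hyperparameters = hyp,
              geweke_sigma_e2 = geweke_z(ch$sigma_e2))
  class(out) <- "summary.bayes_wgr"
  out
}

#' @export
print.summary.bayes_wgr <- function(x, ...) {
  cat(sprintf("%s: n = %d, m = %d\n", x$method, x$n, x$m))
  cat(sprintf("sigma_g2 = %.4f, sigma_e2 = %.4f, h2 = %.3f\n",
              x$sigma_g2, x$sigma_e2, x$h2))
  cat(sprintf("Geweke z (sigma_e2 chain): %.2f\n", x$geweke_sigma_e2))
  print(round(x$hyperparameters, 4))
  invisible(x)
}

#' @export
coef.bayes_wgr <- function(object, ...) object$beta

#' @export
fitted.bayes_wgr <- function(object, ...) object$mu + object$gebv

#' @export
residuals.bayes_wgr <- function(object, y, ...) {
  if (missing(y)) stop("supply the training phenotypes y")
  y - object$mu - object$gebv
}

#' Predict genetic values for new animals from posterior mean effects
#'
#' `g = Z_new %*% beta_bar`; identical to the posterior mean of the genetic
#' value chain for those animals (the chain is linear in `beta`). For
#' prediction error variances of new animals, pass them as `Z_val` to
#' [bayes_wgr()] instead so their values are tracked along the chain.
#'
#' @param object a [bayes_wgr()] fit.
#' @param Z_new genotype rows on the training SNP panel.
#' @param ... unused.
#' @return named vector of predicted genetic values.
#' @export
predict.bayes_wgr <- function(object, Z_new, ...) {
  if (inherits(Z_new, "geno_matrix")) Z_new <- Z_new$codes
  Z_new <- as.matrix(Z_new)
  stopifnot(ncol(Z_new) == length(object$beta))
  drop(Z_new %*% object$beta)
}

#' Posterior genetic values and prediction error variances from a chain
#'
#' Recomputes per-animal posterior mean genetic values and PEVs (sample
#' variance over retained realisations) from a stored effect chain. Needs a
#' fit run with `store_beta = TRUE`.
#'
#' @param fit a [bayes_wgr()] fit with a stored `beta_chain`.
#' @param Z genotype rows (training or validation) on the fit's SNP panel.
#' @return list with `gebv` and `pev` per animal.
#' @export
gebv_pev <- function(fit, Z) {
  stopifnot(inherits(fit, "bayes_wgr"))
  if (is.null(fit$beta_chain))
    stop("fit lacks a stored effect chain; rerun with store_beta = TRUE")
  if (inherits(Z, "geno_matrix")) Z <- Z$codes
  Z <- as.matrix(Z)
  Gc <- fit$beta_chain %*% t(Z) # realisations x animals
  if (nrow(Gc) < 2) stop("PEV needs at least 2 retained realisations")
  list(gebv = colMeans(Gc), pev = apply(Gc, 2, var))
}

#' Geweke-style stationarity z-score
#'
#' Compares the means of the first `frac1` and last `frac2` portions of a
#' chain, with variances estimated by non-overlapping batch means. Values of
#' |z| well above 2 suggest the chain has not reached stationarity.
#'
#' @param x numeric chain of retained realisations.
#' @param frac1,frac2 leading/trailing fractions (defaults 0.1 and 0.5).
#' @param n_batches batches per segment for the variance estimate.
#' @return the z statistic (may be `NA` for degenerate chains).
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5, n_batches = 10) {
  n <- length(x)
  if (n < 4 * n_batches) n_batches <- max(2, n %/% 4)
  a <- x[seq_len(max(2, floor(frac1 * n)))]
  b <- x[seq.int(n - max(2, floor(frac2 * n)) + 1, n)]
  bm <- function(v) {
    k <- max(2, min(n_batches, length(v) %/% 2))
    mns <- tapply(v, cut(seq_along(v), k, labels = FALSE), mean)
    var(mns) / k
  }
  (mean(a) - mean(b)) / sqrt(bm(a) + bm(b))
}
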