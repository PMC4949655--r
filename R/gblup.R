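#' GBLUP: REML variance components and genomic breeding values
#'
#' Fits the mixed model `y = mu 1 + u + e` with `u ~ MVN(0, sigma_g2 G)` and
#' `e ~ MVN(0, sigma_e2 I)` by restricted maximum likelihood. The genomic
#' relationship matrix is eigendecomposed once and the restricted likelihood
#' is profiled over the variance ratio `gamma = sigma_g2 / sigma_e2` by
#' one-dimensional bounded optimisation (tolerance 1e-8 on `gamma`), which is
#' exact and robust at the study's scale (~1000 animals). Negative variance
#' estimates are truncated at zero (flagged in `converged`); eigenvalues of G
#' in `(-1e-8, 0]` are clamped to zero, and a smaller eigenvalue aborts the
#' fit.
#'
#' @param y named numeric vector of (pre-corrected) phenotypes.
#' @param G a [compute_grm()] result or a symmetric matrix whose dimnames
#'   match `names(y)`.
#' @param gamma_range search interval for `gamma` (log-uniform profiling).
#' @return an object of class `gblup` with components `sigma_g2`, `sigma_e2`,
#'   `h2`, `mu`, `gebv` (BLUP of `u` for training animals), `loglik`
#'   (restricted), `gamma`, `converged`, and internals used by `predict()`.
#' @seealso [predict.gblup()] for validation-animal GEBVs.
#' @export
gblup <- function(y, G, gamma_range = c(1e-6, 1e4)) {
  if (inherits(G, "grm")) G <- G$G
  G <- as.matrix(G)
  n <- length(y)
  stopifnot(n >= 2, nrow(G) == n, ncol(G) == n)
  if (!is.null(names(y)) && !is.null(rownames(G))) {
    stopifnot(all(names(y) %in% rownames(G)))
    G <- G[names(y), names(y)]
  }
  if (var(y) <= 0) stop("constant phenotype: restricted likelihood is degenerate")
  if (max(abs(G - diag(n))) < 1e-10)
    warning("G is the identity: sigma_g2 and sigma_e2 are only weakly identified")
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lam <- eg$values
  min_eig <- min(lam)
  # the heterozygosity-diagonal G is mildly indefinite in finite samples;
  # project to the nearest PSD matrix (clamp negative eigenvalues to 0)
  if (min_eig < -0.25 * max(lam))
    stop("G has eigenvalue ", format(min_eig),
         "; too far from a valid relationship matrix")
  lam[lam < 0] <- 0
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))

  # restricted log-likelihood profiled over gamma (sigma_e2 profiled out)
  rll <- function(log_gamma) {
    g <- exp(log_gamma)
    v <- g * lam + 1
    w <- 1 / v
    xwx <- sum(xt^2 * w)
    mu <- sum(xt * yt * w) / xwx
    rss <- sum((yt - mu * xt)^2 * w)
    se2 <- rss / (n - 1)
    -0.5 * ((n - 1) * log(se2) + sum(log(v)) + log(xwx) + (n - 1))
  }
  opt <- optimize(rll, log(gamma_range), maximum = TRUE, tol = 1e-10)
  gamma <- exp(opt$maximum)
  converged <- TRUE
  # boundary check: if the optimum sits at the lower edge, gamma ~ 0
  if (abs(opt$maximum - log(gamma_range[1])) < 1e-6) {
    gamma <- 0; converged <- FALSE
  }
  v <- gamma * lam + 1
  w <- 1 / v
  xwx <- sum(xt^2 * w)
  mu <- sum(xt * yt * w) / xwx
  se2 <- sum((yt - mu * xt)^2 * w) / (n - 1)
  sg2 <- gamma * se2
  ytc <- yt - mu * xt
  # u-hat = sigma_g2 G V^{-1} (y - mu) = U diag(gamma lam / (gamma lam + 1)) U' (y - mu)
  gebv <- drop(U %*% ((gamma * lam * w) * ytc))
  # weights for conditional prediction: sigma_g2 V^{-1}(y - mu)
  wts <- drop(U %*% ((sg2 / se2) * w * ytc))
  names(gebv) <- names(wts) <- names(y)
  structure(list(sigma_g2 = sg2, sigma_e2 = se2, h2 = sg2 / (sg2 + se2),
                 mu = mu, gebv = gebv, gamma = gamma, loglik = opt$objective,
                 converged = converged, n = n, weights = wts,
                 min_eigenvalue = min_eig),
            class = "gblup")
}

#' @export
print.gblup <- function(x, ...) {
  cat("GBLUP fit (REML)\n")
  cat(sprintf("  n = %d animals\n", x$n))
  cat(sprintf("  sigma_g2 = %.4f  sigma_e2 = %.4f  h2 = %.3f\n",
              x$sigma_g2, x$sigma_e2, x$h2))
  cat(sprintf("  mu = %.4f  restricted logLik = %.2f\n", x$mu, x$loglik))
  if (!x$converged) cat("  note: genetic variance truncated at the boundary\n")
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  out <- object[c("sigma_g2", "sigma_e2", "h2", "mu", "gamma", "loglik",
                  "converged", "n")]
  class(out) <- "summary.gblup"
  out
}

#' @export
print.summary.gblup <- function(x, ...) {
  cat("GBLUP REML summary\n")
  print(unlist(x[c("sigma_g2", "sigma_e2", "h2", "mu", "gamma", "loglik")]))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) c(mu = object$mu)

#' @export
fitted.gblup <- function(object, ...) object$mu + object$gebv

#' @export
residuals.gblup <- function(object, ...) {
  # e-hat = y - mu - u-hat, recovered from the stored weights:
  # sigma_e2 V^{-1}(y - mu) = (sigma_e2/sigma_g2) * weights
  if (object$sigma_g2 <= 0) stop("residuals undefined for a boundary fit")
  object$weights * object$sigma_e2 / object$sigma_g2
}

#' Predict GEBVs for validation animals
#'
#' Conditional-expectation predictor `u_v = G_vt G_tt^{-1} u_t`, computed in
#' the numerically robust equivalent form `sigma_g2 G_vt V^{-1}(y - mu)`;
#' this equals the solution of the mixed-model equations with the validation
#' animals included at unknown phenotypes.
#'
#' @param object a [gblup()] fit.
#' @param G_cross validation-by-training relationship block (e.g. from
#'   [grm_cross()] or a sub-block of the full G); columns must align with
#'   (or be named by) the training animals.
#' @param ... unused.
#' @return named vector of validation GEBVs.
#' @export
predict.gblup <- function(object, G_cross, ...) {
  G_cross <- as.matrix(G_cross)
  if (!is.null(colnames(G_cross)) && !is.null(names(object$weights))) {
    if (!all(names(object$weights) %in% colnames(G_cross)))
      stop("validation block does not cover the training animals")
    G_cross <- G_cross[, names(object$weights), drop = FALSE]
  }
  stopifnot(ncol(G_cross) == object$n)
  drop(G_cross %*% object$weights)
}
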