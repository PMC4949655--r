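#' Genetic variance from a posterior fit (Nadaf decomposition)
#'
#' `sigma_g2 = var(EBV) + mean(PEV)` over the training animals: the variance
#' of the posterior-mean genetic values plus the average prediction error
#' variance, recovering the genetic variance that shrinkage removes from
#' `var(EBV)` alone.
#'
#' @param gebv posterior-mean genetic values of the training animals, or a
#'   [bayes_wgr()] fit (in which case `pev` is taken from the fit).
#' @param pev per-animal prediction error variances.
#' @return the genetic variance estimate.
#' @export
nadaf_genetic_variance <- function(gebv, pev) {
  if (inherits(gebv, "bayes_wgr")) { pev <- gebv$pev; gebv <- gebv$gebv }
  if (length(gebv) < 2) stop("need at least 2 training animals")
  stopifnot(length(pev) == length(gebv), all(pev >= 0))
  var(gebv) + mean(pev)
}

#' Heritability from variance components
#'
#' `h2 = sigma_g2 / (sigma_g2 + sigma_e2)`.
#'
#' @param sigma_g2,sigma_e2 non-negative variance components (not both 0).
#' @return heritability in `[0, 1]`.
#' @export
heritability <- function(sigma_g2, sigma_e2) {
  stopifnot(sigma_g2 >= 0, sigma_e2 >= 0)
  if (sigma_g2 + sigma_e2 == 0) stop("both variance components are zero")
  sigma_g2 / (sigma_g2 + sigma_e2)
}

#' Relative accuracy
#'
#' Scales the cross-validated phenotype-prediction accuracy by the square
#' root of the average heritability over methods:
#' `r* = r / sqrt(mean(h2))`, an estimate of the accuracy of predicting the
#' breeding value itself.
#'
#' @param mean_r average accuracy (correlation) over validation folds.
#' @param method_h2_list heritability estimates of all compared methods.
#' @return the relative accuracy `r*`.
#' @export
relative_accuracy <- function(mean_r, method_h2_list) {
  stopifnot(all(method_h2_list > 0), all(method_h2_list <= 1))
  hbar <- mean(method_h2_list)
  if (hbar == 0) stop("mean heritability is zero")
  mean_r / sqrt(hbar)
}

#' Pair-preserving cross-validation folds
#'
#' Assigns discordant sib pairs to folds as indivisible units and singletons
#' individually, keeping fold sizes (in animals) as equal as the unit sizes
#' permit. Deterministic given the seed.
#'
#' @param design a `study_design` whose `pairs` attribute (from
#'   [apply_case_control_selection()]) identifies the pairs; animals not in a
#'   pair are treated as singletons.
#' @param k number of folds (default 5).
#' @param seed RNG seed for the random unit order.
#' @return named integer vector: fold (1..k) per animal id.
#' @export
make_cv_folds <- function(design, k = 5, seed = 1L) {
  stopifnot(k >= 2)
  ids <- design$animal_id
  pairs <- attr(design, "pairs")
  units <- list()
  if (!is.null(pairs) && nrow(pairs)) {
    pairs <- pairs[pairs$case %in% ids & pairs$control %in% ids, ]
    units <- c(units, lapply(seq_len(nrow(pairs)),
                             function(i) c(pairs$case[i], pairs$control[i])))
  }
  singles <- setdiff(ids, unlist(units))
  n_pairs <- length(units)
  units <- c(units, as.list(singles))
  if (length(units) < k) stop("fewer units (pairs + singletons) than folds")
  set.seed(seed)
  # random order within unit class, but pairs before singletons so the
  # singletons even out fold sizes (spread <= 1 animal when enough of them)
  ord <- c(sample.int(n_pairs),
           if (length(singles)) n_pairs + sample.int(length(singles)))
  fold_n <- integer(k)
  assign <- integer(length(units))
  for (u in ord) { # greedy: drop each unit into the currently smallest fold
    f <- which.min(fold_n)
    assign[u] <- f
    fold_n[f] <- fold_n[f] + length(units[[u]])
  }
  out <- integer(0)
  for (u in seq_along(units)) out[units[[u]]] <- assign[u]
  out[ids]
  setNames(out[ids], ids)
}

#' Per-fold prediction accuracy of given GEBVs
#'
#' Pearson correlation between GEBV and phenotype within each validation
#' fold; the overall accuracy is the average over folds and its standard
#' error the SD of fold accuracies over `sqrt(k)`. Folds with constant GEBV
#' have undefined correlation and are excluded with a warning.
#'
#' @param gebv named vector of predicted genetic values (all animals).
#' @param y named vector of (pre-corrected) phenotypes.
#' @param folds named fold assignment from [make_cv_folds()].
#' @return list `r_fold`, `mean_r`, `se`.
#' @export
fold_accuracy <- function(gebv, y, folds) {
  ids <- names(folds)
  stopifnot(!is.null(ids), all(ids %in% names(gebv)), all(ids %in% names(y)))
  ks <- sort(unique(folds))
  r <- vapply(ks, function(f) {
    sel <- ids[folds == f]
    g <- gebv[sel]
    if (sd(g) == 0 || sd(y[sel]) == 0) return(NA_real_)
    cor(g, y[sel])
  }, 1.0)
  if (anyNA(r)) warning("fold(s) with undefined correlation excluded: ",
                        paste(ks[is.na(r)], collapse = ", "))
  ok <- !is.na(r)
  list(r_fold = setNames(r, paste0("fold", ks)),
       mean_r = mean(r[ok]), se = sd(r[ok]) / sqrt(sum(ok)))
}

#' Cross-validated accuracy of the six genomic evaluation methods
#'
#' For each training fold, fits the requested methods (GBLUP by REML on the
#' whole-data G sub-block; the Bayesian regressions by Gibbs sampling on the
#' training genotypes) and predicts the validation animals; accuracy is the
#' within-fold correlation between prediction and pre-corrected phenotype.
#' Heritability per training fit is REML-based for GBLUP and the Nadaf
#' chain-based estimate for the Bayesian methods. Relative accuracies `r*`
#' scale each method's mean `r` by the across-method average of whole-data
#' heritabilities (per-fold averages are available via
#' `h2_for_rstar = "fold_mean"`, which skips the whole-data fits).
#'
#' @param y named pre-corrected phenotype vector.
#' @param Z complete genotype matrix (or [geno_matrix()]) for the same
#'   animals, used by the Bayesian methods and the G matrix.
#' @param folds named fold assignment from [make_cv_folds()].
#' @param methods subset of `c("GBLUP", "BayesA", "BayesB", "BayesC",
#'   "BayesSSVS", "BayesLasso")`.
#' @param schedule [chain_schedule()] for the Gibbs chains.
#' @param G optional precomputed [compute_grm()] on all animals (built from
#'   `Z` when omitted); allele frequencies are those of the full data set,
#'   matching the single-G workflow.
#' @param h2_for_rstar `"whole"` (default) or `"fold_mean"`.
#' @param seed master seed; per-fold and per-method chain seeds are derived
#'   from it deterministically.
#' @param ... further arguments passed to [bayes_wgr()].
#' @return object of class `cv_report`: per-method/fold accuracies and
#'   heritabilities, mean `r`, SE, `h2` used for scaling, `r_star`, the fold
#'   assignment, and the GEBV matrix (animals x methods, validation
#'   predictions) for [gebv_pca()].
#' @export
cv_evaluate <- function(y, Z, folds, methods = c("GBLUP", "BayesA", "BayesB",
                                                 "BayesC", "BayesSSVS",
                                                 "BayesLasso"),
                        schedule = chain_schedule(), G = NULL,
                        h2_for_rstar = c("whole", "fold_mean"),
                        seed = 1L, ...) {
  h2_for_rstar <- match.arg(h2_for_rstar)
  if (inherits(Z, "geno_matrix")) Z <- Z$codes
  Z <- as.matrix(Z)
  ids <- names(folds)
  stopifnot(all(ids %in% names(y)), all(ids %in% rownames(Z)))
  y <- y[ids]; Z <- Z[ids, , drop = FALSE]
  ks <- sort(unique(folds))
  needG <- "GBLUP" %in% methods
  if (needG && is.null(G)) {
    gm <- geno_matrix(Z)
    G <- compute_grm(impute_missing(gm))
  }
  if (inherits(G, "grm")) G <- G$G
  gebv_mat <- matrix(NA_real_, length(ids), length(methods),
                     dimnames = list(ids, methods))
  r_fold <- h2_fold <- matrix(NA_real_, length(ks), length(methods),
                              dimnames = list(paste0("fold", ks), methods))
  for (fi in seq_along(ks)) {
    f <- ks[fi]
    tr <- ids[folds != f]; va <- ids[folds == f]
    for (mi in seq_along(methods)) {
      mth <- methods[mi]
      sd_seed <- derive_seed(seed, fi * 10L + mi)
      if (mth == "GBLUP") {
        fit <- gblup(y[tr], G[tr, tr])
        pred <- predict(fit, G[va, tr, drop = FALSE])
        h2_fold[fi, mi] <- fit$h2
      } else {
        fit <- bayes_wgr(y[tr], Z[tr, , drop = FALSE], method = mth,
                         schedule = schedule, seed = sd_seed, ...)
        pred <- drop(Z[va, , drop = FALSE] %*% fit$beta)
        h2_fold[fi, mi] <- fit$h2
      }
      gebv_mat[va, mi] <- pred
      if (sd(pred) > 0 && sd(y[va]) > 0)
        r_fold[fi, mi] <- cor(pred, y[va])
    }
  }
  mean_r <- colMeans(r_fold, na.rm = TRUE)
  se_r <- apply(r_fold, 2, function(v) sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  if (h2_for_rstar == "whole") {
    h2_whole <- vapply(seq_along(methods), function(mi) {
      mth <- methods[mi]
      if (mth == "GBLUP") gblup(y, G)$h2
      else bayes_wgr(y, Z, method = mth, schedule = schedule,
                     seed = derive_seed(seed, 900L + mi), ...)$h2
    }, 1.0)
    names(h2_whole) <- methods
  } else {
    h2_whole <- colMeans(h2_fold, na.rm = TRUE)
  }
  r_star <- mean_r / sqrt(mean(h2_whole))
  structure(list(folds = folds, methods = methods, r_fold = r_fold,
                 h2_fold = h2_fold, mean_r = mean_r, se = se_r,
                 h2 = h2_whole, h2_bar = mean(h2_whole), r_star = r_star,
                 gebv = gebv_mat, schedule = schedule),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Cross-validation report (%d folds, %d animals)\n",
              nrow(x$r_fold), length(x$folds)))
  tab <- data.frame(r = round(x$mean_r, 3), se = round(x$se, 3),
                    h2 = round(x$h2, 3), r_star = round(x$r_star, 3))
  print(tab)
  cat(sprintf("mean h2 over methods: %.3f\n", x$h2_bar))
  invisible(x)
}

#' Single-QTL baseline predictor
#'
#' Per training fold, ordinary least squares of the pre-corrected phenotype
#' on one SNP's allele count (the allelic substitution effect); validation
#' phenotypes are predicted as `intercept + slope x code` and scored as in
#' [fold_accuracy()]. Folds where the SNP is monomorphic in training are
#' flagged and excluded.
#'
#' @param snp vector of allele counts (0/1/2) named by animal id, or a
#'   single SNP id to extract from `Z`.
#' @param y named pre-corrected phenotypes.
#' @param folds named fold assignment.
#' @param Z genotype matrix, required when `snp` is an id.
#' @return list `r_fold`, `mean_r`, `se`, `slope_fold`.
#' @export
qtl_only_predict <- function(snp, y, folds, Z = NULL) {
  if (is.character(snp) && length(snp) == 1) {
    if (is.null(Z)) stop("supply Z to look up the SNP id")
    if (inherits(Z, "geno_matrix")) Z <- Z$codes
    if (!snp %in% colnames(Z)) stop("SNP ", snp, " not in the panel")
    snp <- Z[, snp]
  }
  ids <- names(folds)
  stopifnot(all(ids %in% names(snp)), all(ids %in% names(y)))
  ks <- sort(unique(folds))
  r <- slope <- rep(NA_real_, length(ks))
  for (fi in seq_along(ks)) {
    tr <- ids[folds != ks[fi]]; va <- ids[folds == ks[fi]]
    x <- snp[tr]
    if (sd(x) == 0) { warning("SNP monomorphic in training fold ", ks[fi]); next }
    fit <- lm(y[tr] ~ x)
    slope[fi] <- coef(fit)[2]
    pred <- coef(fit)[1] + coef(fit)[2] * snp[va]
    if (sd(pred) > 0 && sd(y[va]) > 0) r[fi] <- cor(pred, y[va])
  }
  ok <- !is.na(r)
  list(r_fold = setNames(r, paste0("fold", ks)), mean_r = mean(r[ok]),
       se = sd(r[ok]) / sqrt(sum(ok)), slope_fold = slope)
}

#' PCA comparison of methods on their GEBVs
#'
#' Standardises each method's GEBV column to unit variance, runs a principal
#' component analysis of the animals x methods matrix, and places each
#' method at its loading coordinates on the first two components. The sign
#' of each component is fixed so its largest-magnitude loading is positive.
#'
#' @param gebv_by_method animals x methods numeric matrix (or the `gebv`
#'   element of a `cv_report`).
#' @param standardize scale columns to unit variance (default) or use the
#'   raw covariance PCA.
#' @return object of class `gebv_pca`: data.frame of method coordinates
#'   (`PC1`, `PC2`) plus the proportion of variance explained.
#' @export
gebv_pca <- function(gebv_by_method, standardize = TRUE) {
  M <- as.matrix(gebv_by_method)
  stopifnot(ncol(M) >= 2, nrow(M) >= 3)
  sds <- apply(M, 2, sd)
  if (any(sds == 0))
    stop("constant GEBV column(s): ", paste(colnames(M)[sds == 0], collapse = ", "))
  pc <- prcomp(M, center = TRUE, scale. = standardize)
  L <- pc$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  out <- data.frame(method = colnames(M), PC1 = L[, 1], PC2 = L[, 2],
                    row.names = NULL)
  structure(list(coordinates = out, var_explained = ve[1:2]),
            class = "gebv_pca")
}

#' @export
print.gebv_pca <- function(x, ...) {
  cat(sprintf("PCA of GEBVs by method (PC1 %.1f%%, PC2 %.1f%% of variance)\n",
              100 * x$var_explained[1], 100 * x$var_explained[2]))
  print(x$coordinates)
  invisible(x)
}

#' @export
plot.gebv_pca <- function(x, ...) {
  co <- x$coordinates
  plot(co$PC1, co$PC2,
       xlab = sprintf("PC1 (%.1f%%)", 100 * x$var_explained[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * x$var_explained[2]),
       main = "Methods in GEBV loading space", ...)
  graphics::text(co$PC1, co$PC2, labels = co$method, pos = 3, cex = 0.8)
  invisible(x)
}
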