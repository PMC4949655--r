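#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' One-degree-of-freedom chi-square goodness-of-fit test of the genotype
#' counts against Hardy-Weinberg proportions at the sample allele frequency,
#' or the exact (Wigginton-style) test summing probabilities of heterozygote
#' counts no more probable than the observed one. Monomorphic SNPs return
#' p = 1 (no departure is testable).
#'
#' @param counts integer vector `(n_AA, n_Aa, n_aa)`.
#' @param method `"chisq"` (default) or `"exact"`.
#' @return p-value in `[0, 1]`.
#' @export
hwe_test <- function(counts, method = c("chisq", "exact")) {
  method <- match.arg(method)
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n < 1) stop("need at least one genotyped individual")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  if (method == "chisq") {
    expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stat <- sum((counts - expd)^2 / expd)
    return(unname(pchisq(stat, df = 1, lower.tail = FALSE)))
  }
  # exact: condition on allele counts, enumerate heterozygote counts
  nA <- 2 * counts[1] + counts[2]
  nB <- 2 * n - nA
  rare <- min(nA, nB)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    na <- (min(nA, nB) - h) / 2          # rare-allele homozygotes
    nb <- n - na - h
    lgamma(n + 1) - lgamma(na + 1) - lgamma(h + 1) - lgamma(nb + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }, 1.0)
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- pr[match(counts[2], hets)]
  min(1, sum(pr[pr <= obs + 1e-12]))
}

#' Benjamini-Hochberg step-up selection
#'
#' Indices of hypotheses rejected by the BH step-up procedure controlling the
#' false discovery rate at level `q`.
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @param q FDR level in (0, 1).
#' @return integer vector of rejected indices (empty when none).
#' @export
bh_fdr_select <- function(p_values, q) {
  stopifnot(q > 0, q < 1)
  if (!length(p_values)) return(integer(0))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  which(p.adjust(p_values, method = "BH") <= q)
}

#' SNP quality control
#'
#' Removes SNPs failing, in order: minor allele frequency at or below
#' `maf_min`; call rate at or below `callrate_min`; extreme Hardy-Weinberg
#' departure among the survivors at a Benjamini-Hochberg FDR of `hwe_fdr`.
#' Each SNP is counted against the first rule that removes it. Boundary
#' convention follows the source design: removal at "<=" the MAF and
#' call-rate thresholds.
#'
#' @param genotypes a [geno_matrix()].
#' @param maf_min,callrate_min,hwe_fdr thresholds (defaults 0.01, 0.95, 0.01).
#' @return list `genotypes` (surviving panel) and `report` (class
#'   `qc_report`: per-rule removed counts, removed ids per rule, surviving
#'   dimensions).
#' @export
snp_qc <- function(genotypes, maf_min = 0.01, callrate_min = 0.95,
                   hwe_fdr = 0.01) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  X <- genotypes$codes
  if (!ncol(X) || !nrow(X)) stop("empty genotype matrix")
  freq <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  cr <- colMeans(!is.na(X))
  fail_maf <- maf <= maf_min
  fail_cr <- cr <= callrate_min & !fail_maf
  surv <- !(fail_maf | fail_cr)
  pv <- rep(1, ncol(X))
  for (k in which(surv)) {
    x <- X[, k]
    pv[k] <- hwe_test(c(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                        sum(x == 2, na.rm = TRUE)))
  }
  fail_hwe <- rep(FALSE, ncol(X))
  rej <- bh_fdr_select(pv[surv], hwe_fdr)
  fail_hwe[which(surv)[rej]] <- TRUE
  keep <- surv & !fail_hwe
  if (!any(keep)) stop("all SNPs removed by QC: empty panel")
  removed <- list(maf = colnames(X)[fail_maf], callrate = colnames(X)[fail_cr],
                  hwe = colnames(X)[fail_hwe])
  report <- structure(list(
    class_ = "snp", counts = vapply(removed, length, 1L), removed = removed,
    n_in = ncol(X), n_out = sum(keep)), class = "qc_report")
  out <- geno_matrix(X[, keep, drop = FALSE], genotypes$map[keep, , drop = FALSE])
  list(genotypes = out, report = report)
}

#' Individual quality control
#'
#' Removes animals with call rate at or below `callrate_min`, autosomal
#' heterozygosity at or above `het_max`, and both members of any pair with
#' genomic relationship at or above `rel_max` (duplicate/twin rule; set
#' `duplicate_action = "keep_one"` to retain the first member). Each animal
#' is counted against the first rule that removes it.
#'
#' @param genotypes a post-SNP-QC [geno_matrix()].
#' @param grm optional [compute_grm()] result on the same panel for the
#'   duplicate rule; computed internally when omitted.
#' @param callrate_min,het_max,rel_max thresholds (defaults 0.95, 0.45, 0.95).
#' @param duplicate_action `"both"` (default, literal reading: the pair is
#'   eliminated) or `"keep_one"`.
#' @return list `genotypes` and `report` (class `qc_report`).
#' @export
individual_qc <- function(genotypes, grm = NULL, callrate_min = 0.95,
                          het_max = 0.45, rel_max = 0.95,
                          duplicate_action = c("both", "keep_one")) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  duplicate_action <- match.arg(duplicate_action)
  X <- genotypes$codes
  st <- geno_stats(genotypes)
  fail_cr <- st$animal_callrate <= callrate_min
  fail_het <- st$animal_het >= het_max & !fail_cr
  if (is.null(grm)) {
    imp <- impute_missing(genotypes)
    grm <- compute_grm(imp, allele_frequencies(genotypes))
  }
  G <- if (inherits(grm, "grm")) grm$G else as.matrix(grm)
  stopifnot(nrow(G) == nrow(X))
  fail_dup <- rep(FALSE, nrow(X))
  Gu <- G; Gu[lower.tri(Gu, diag = TRUE)] <- -Inf
  hits <- which(Gu >= rel_max, arr.ind = TRUE)
  if (nrow(hits)) {
    for (r in seq_len(nrow(hits))) {
      i <- hits[r, 1]; j <- hits[r, 2]
      if (duplicate_action == "both") fail_dup[c(i, j)] <- TRUE
      else fail_dup[j] <- TRUE
    }
  }
  fail_dup <- fail_dup & !fail_cr & !fail_het
  keep <- !(fail_cr | fail_het | fail_dup)
  removed <- list(callrate = rownames(X)[fail_cr],
                  heterozygosity = rownames(X)[fail_het],
                  duplicate = rownames(X)[fail_dup])
  report <- structure(list(
    class_ = "animal", counts = vapply(removed, length, 1L), removed = removed,
    n_in = nrow(X), n_out = sum(keep)), class = "qc_report")
  out <- geno_matrix(X[keep, , drop = FALSE], genotypes$map)
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report (%ss): %d in, %d surviving\n", x$class_, x$n_in, x$n_out))
  for (nm in names(x$counts))
    cat(sprintf("  removed by %s: %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Mean-impute missing genotypes
#'
#' Replaces each missing code by the SNP's mean code `2 p_k` computed from
#' the observed calls. Imputed positions are recorded in the `imputed`
#' attribute.
#'
#' @param genotypes a [geno_matrix()].
#' @return a complete [geno_matrix()] (codes become numeric).
#' @export
impute_missing <- function(genotypes) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  X <- genotypes$codes
  miss <- which(is.na(X), arr.ind = TRUE)
  if (!nrow(miss)) return(genotypes)
  mc <- colMeans(X, na.rm = TRUE)
  if (anyNA(mc)) stop("SNP with no observed calls cannot be imputed; run snp_qc first")
  X[miss] <- mc[miss[, 2]]
  out <- geno_matrix(X, genotypes$map)
  attr(out, "imputed") <- miss
  out
}

#' Pre-correct log phenotypes for farm and age
#'
#' Ordinary least squares of `log_value` on farm indicators and age, fitted
#' per trait; the `precorrected` column receives the residuals (mean zero,
#' orthogonal to the design columns). Carcass weight and meat percentage are
#' deliberately not used, as they may be confounded with taint genetics.
#'
#' @param phenotypes a `phenotype_table`.
#' @param design a `study_design` supplying `farm` and `age_days`.
#' @return the phenotype table with `precorrected` filled.
#' @export
precorrect_phenotypes <- function(phenotypes, design) {
  stopifnot(inherits(phenotypes, "data.frame"))
  idx <- match(phenotypes$animal_id, design$animal_id)
  if (anyNA(idx)) stop("phenotyped animals missing from the design")
  farm <- design$farm[idx]; age <- design$age_days[idx]
  if (anyNA(farm) || anyNA(age)) stop("every phenotyped animal needs farm and age")
  singletons <- names(which(table(farm) == 1))
  if (length(singletons))
    warning("farm level(s) with a single animal (residual 0 by construction): ",
            paste(singletons, collapse = ", "))
  for (tr in unique(phenotypes$trait)) {
    sel <- phenotypes$trait == tr
    f <- factor(farm[sel]); a <- age[sel]
    fit <- if (nlevels(f) > 1) lm(phenotypes$log_value[sel] ~ f + a)
           else lm(phenotypes$log_value[sel] ~ a)
    phenotypes$precorrected[sel] <- unname(residuals(fit))
  }
  phenotypes
}
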