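#' In-sample allele frequencies
#'
#' Frequency of the alternative (counted) allele per SNP, computed on the
#' observed (non-missing) calls: `p_k = sum_i x_ik / (2 n_called)`.
#'
#' @param genotypes a [geno_matrix()].
#' @return named numeric vector of frequencies.
#' @export
allele_frequencies <- function(genotypes) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  X <- genotypes$codes
  called <- colSums(!is.na(X))
  if (any(called == 0)) stop("SNP(s) with zero called genotypes: ",
                             paste(colnames(X)[called == 0], collapse = ", "))
  colSums(X, na.rm = TRUE) / (2 * called)
}

#' Genomic relationship matrix with heterozygosity-based diagonals
#'
#' Off-diagonals are the SNP-averaged centred-and-scaled cross-products
#' `g_ij = n^-1 sum_k (x_ik - 2 p_k)(x_jk - 2 p_k) / (2 p_k (1 - p_k))`;
#' diagonals use the heterozygosity deficit
#' `g_ii = 1 + n^-1 sum_k (H_Ek - H_ik) / H_Ek`, where `H_Ek = 2 p_k (1 - p_k)`
#' is the expected heterozygosity and `H_ik` indicates whether animal `i` is
#' heterozygous at `k` (imputed, non-integer codes count as non-heterozygous).
#'
#' @param genotypes a complete (imputed) [geno_matrix()].
#' @param freqs allele frequencies to centre and scale by; defaults to the
#'   in-sample [allele_frequencies()].
#' @return an object of class `grm`: list with the symmetric matrix `G`
#'   (dimnames = animal ids), `n_snps`, and `freqs`.
#' @export
compute_grm <- function(genotypes, freqs = allele_frequencies(genotypes)) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  X <- genotypes$codes
  if (anyNA(X)) stop("genotypes must be complete; run impute_missing() first")
  if (any(freqs <= 0 | freqs >= 1))
    stop("monomorphic SNP(s) reached compute_grm (division by zero); run snp_qc")
  m <- ncol(X)
  he <- 2 * freqs * (1 - freqs)
  W <- sweep(X, 2, 2 * freqs)
  W <- sweep(W, 2, sqrt(he), "/")
  G <- tcrossprod(W) / m
  # g_ii = 1 + mean_k (He_k - H_ik)/He_k = 2 - mean_k H_ik/He_k
  H <- (X == 1)
  diag(G) <- 2 - rowMeans(sweep(H, 2, he, "/"))
  dimnames(G) <- list(rownames(X), rownames(X))
  structure(list(G = G, n_snps = m, freqs = freqs), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d animals from %d SNPs; mean diag %.3f, mean off-diag %.3f\n",
              nrow(x$G), x$n_snps, mean(diag(x$G)),
              mean(x$G[upper.tri(x$G)])))
  invisible(x)
}

#' Cross-relationship block between two sets of animals
#'
#' The validation-by-training block of the same genomic relationship,
#' computed with one shared set of allele frequencies.
#'
#' @param genotypes_a,genotypes_b complete [geno_matrix()] objects on the
#'   same SNP panel.
#' @param freqs shared allele frequencies.
#' @return matrix of relationships, rows = animals of `genotypes_a`.
#' @export
grm_cross <- function(genotypes_a, genotypes_b, freqs) {
  Xa <- genotypes_a$codes; Xb <- genotypes_b$codes
  stopifnot(ncol(Xa) == ncol(Xb), length(freqs) == ncol(Xa))
  he <- 2 * freqs * (1 - freqs)
  Wa <- sweep(sweep(Xa, 2, 2 * freqs), 2, sqrt(he), "/")
  Wb <- sweep(sweep(Xb, 2, 2 * freqs), 2, sqrt(he), "/")
  tcrossprod(Wa, Wb) / ncol(Xa)
}
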