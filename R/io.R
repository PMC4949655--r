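#' Write genotypes as PLINK PED/MAP
#'
#' Text PED (FID IID PAT MAT SEX PHENO + two alleles per SNP, `0 0` for
#' missing) and MAP (chr, snp id, cM, bp). Allele letters come from the SNP
#' map (`allele1` = reference, `allele2` = alternative/counted).
#'
#' @param genotypes a [geno_matrix()].
#' @param prefix output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @param design optional `study_design` supplying sire/dam ids.
#' @return invisibly, the two file paths.
#' @export
write_plink <- function(genotypes, prefix, design = NULL) {
  X <- genotypes$codes
  map <- genotypes$map
  a1 <- map$allele1; a2 <- map$allele2
  ids <- rownames(X)
  sire <- dam <- rep("0", nrow(X))
  if (!is.null(design)) {
    i <- match(ids, design$animal_id)
    sire <- ifelse(is.na(design$sire_id[i]), "0", design$sire_id[i])
    dam <- ifelse(is.na(design$dam_id[i]), "0", design$dam_id[i])
  }
  n <- nrow(X); m <- ncol(X)
  al <- matrix("0", n, 2 * m)
  for (k in seq_len(m)) {
    x <- X[, k]
    c1 <- ifelse(is.na(x), "0", ifelse(x >= 1, a2[k], a1[k]))
    c2 <- ifelse(is.na(x), "0", ifelse(x == 2, a2[k], a1[k]))
    al[, 2 * k - 1] <- c1; al[, 2 * k] <- c2
  }
  ped <- cbind("FAM1", ids, sire, dam, "1", "-9", al)
  pedfile <- paste0(prefix, ".ped"); mapfile <- paste0(prefix, ".map")
  write.table(ped, pedfile, quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(map$chr, map$snp_id, 0, map$pos), mapfile,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(ped = pedfile, map = mapfile))
}

#' Read genotypes from PLINK PED/MAP
#'
#' Inverse of [write_plink()]: alleles are counted against the MAP-implied
#' coding (the second allele observed per SNP column order is not used;
#' counting is of the `allele2` letter recorded in the returned map, taken as
#' the first non-reference letter seen, with `A`/`B` panels read back
#' exactly). Heterozygotes code 1, missing (`0 0`) codes `NA`.
#'
#' @param prefix path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @return a [geno_matrix()].
#' @export
read_plink <- function(prefix) {
  mapfile <- paste0(prefix, ".map"); pedfile <- paste0(prefix, ".ped")
  map <- read.table(mapfile, stringsAsFactors = FALSE)
  names(map) <- c("chr", "snp_id", "cm", "pos")
  ped <- read.table(pedfile, stringsAsFactors = FALSE, colClasses = "character")
  m <- nrow(map)
  stopifnot(ncol(ped) == 6 + 2 * m)
  ids <- ped[[2]]
  X <- matrix(NA_integer_, nrow(ped), m, dimnames = list(ids, map$snp_id))
  a1 <- a2 <- character(m)
  for (k in seq_len(m)) {
    c1 <- ped[[6 + 2 * k - 1]]; c2 <- ped[[6 + 2 * k]]
    obs <- c(c1, c2); obs <- unique(obs[obs != "0"])
    # reference allele: alphabetically first; alternative: the other
    a1[k] <- if (length(obs)) sort(obs)[1] else "A"
    a2[k] <- if (length(obs) > 1) sort(obs)[2] else setdiff(c("A", "B"), a1[k])[1]
    cnt <- (c1 == a2[k]) + (c2 == a2[k])
    cnt[c1 == "0" | c2 == "0"] <- NA
    X[, k] <- cnt
  }
  geno_matrix(X, data.frame(snp_id = map$snp_id, chr = map$chr, pos = map$pos,
                            allele1 = a1, allele2 = a2,
                            stringsAsFactors = FALSE))
}

#' Write / read the TSV genotype dialect
#'
#' Rows = animals, columns = SNP codes (0/1/2, `NA` missing), first column
#' `animal_id`.
#'
#' @param genotypes a [geno_matrix()].
#' @param path file path.
#' @return `write_geno_tsv`: invisibly the path; `read_geno_tsv`: a
#'   [geno_matrix()].
#' @export
write_geno_tsv <- function(genotypes, path) {
  df <- data.frame(animal_id = rownames(genotypes$codes),
                   genotypes$codes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geno_tsv
#' @export
read_geno_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df[[1]]
  geno_matrix(X)
}

#' Write / read a genomic relationship matrix
#'
#' `write_grm()` writes a whitespace-delimited symmetric matrix with an id
#' header line, and optionally a long-format lower triangle (`id1`, `id2`,
#' `g`) TSV alongside.
#'
#' @param grm a [compute_grm()] result.
#' @param path file path for the square matrix.
#' @param long_path optional path for the long-format lower triangle.
#' @return `write_grm`: invisibly the path; `read_grm`: a `grm` object
#'   (without frequencies).
#' @export
write_grm <- function(grm, path, long_path = NULL) {
  G <- grm$G
  con <- file(path, "w")
  writeLines(paste(colnames(G), collapse = " "), con)
  write.table(format(G, digits = 10, trim = TRUE), con, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  close(con)
  if (!is.null(long_path)) {
    lt <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(id1 = rownames(G)[lt[, 1]], id2 = colnames(G)[lt[, 2]],
                     g = G[lt])
    write.table(df, long_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  ids <- strsplit(readLines(path, n = 1), "\\s+")[[1]]
  G <- as.matrix(read.table(path, skip = 1))
  dimnames(G) <- list(ids, ids)
  structure(list(G = G, n_snps = NA_integer_, freqs = NULL), class = "grm")
}

#' Write / read phenotype and design tables as TSV
#'
#' @param x a `phenotype_table` or `study_design` data.frame.
#' @param path file path.
#' @return invisibly the path; readers return the classed data.frame.
#' @export
write_pheno_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pheno_tsv
#' @export
read_pheno_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' @rdname write_pheno_tsv
#' @export
read_design_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  class(df) <- c("study_design", "data.frame")
  df
}
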