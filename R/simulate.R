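#' Genotype matrix container
#'
#' Animals x SNPs matrix of alternative-allele counts (0/1/2, `NA` missing)
#' with a SNP map (id, chromosome, position, alleles).
#'
#' @param codes integer/numeric matrix, rownames = animal ids, colnames = SNP ids.
#' @param map optional data.frame with columns `snp_id`, `chr`, `pos`,
#'   `allele1`, `allele2`; a default map is built when omitted.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(codes, map = NULL) {
  codes <- as.matrix(codes)
  if (is.null(rownames(codes)))
    rownames(codes) <- sprintf("A%05d", seq_len(nrow(codes)))
  if (is.null(colnames(codes)))
    colnames(codes) <- sprintf("SNP%06d", seq_len(ncol(codes)))
  ok <- codes[!is.na(codes)]
  if (length(ok) && (min(ok) < 0 || max(ok) > 2))
    stop("genotype codes must be in {0, 1, 2} or NA")
  if (is.null(map)) {
    m <- ncol(codes)
    map <- data.frame(snp_id = colnames(codes),
                      chr = rep_len(1:18, m),
                      pos = as.integer(seq_len(m)) * 1000L,
                      allele1 = "A", allele2 = "B",
                      stringsAsFactors = FALSE)
  }
  stopifnot(nrow(map) == ncol(codes))
  structure(list(codes = codes, map = map), class = "geno_matrix")
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d animals x %d SNPs (%.2f%% missing)\n",
              nrow(x$codes), ncol(x$codes),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' Per-SNP and per-animal call rates and heterozygosity
#' @param genotypes a [geno_matrix()].
#' @return list with `snp_callrate`, `animal_callrate`, `animal_het` (observed
#'   heterozygosity over non-missing autosomal calls).
#' @export
geno_stats <- function(genotypes) {
  X <- genotypes$codes
  list(snp_callrate = colMeans(!is.na(X)),
       animal_callrate = rowMeans(!is.na(X)),
       animal_het = rowMeans(X == 1, na.rm = TRUE))
}

rnorm_trunc_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a two-generation hierarchical pedigree
#'
#' Dams are nested within sires (each dam mated to a single sire, one litter
#' per dam); litters are assigned whole to farms; slaughter age is drawn
#' Normal(`age_mean`, `age_sd`) truncated at zero. Founders appear in the
#' pedigree with missing parents, farm and age.
#'
#' @param config a [sim_config()].
#' @return a `study_design` data.frame with columns `animal_id`, `sire_id`,
#'   `dam_id`, `litter_id`, `farm`, `age_days`, `role`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$litter_size < 2)
    stop("litter_size must be >= 2 for paired case-control designs")
  set.seed(derive_seed(config$seed, 1L))
  ns <- config$n_sires; nd <- config$n_dams; ls <- config$litter_size
  sires <- sprintf("S%04d", seq_len(ns))
  dams <- sprintf("D%04d", seq_len(nd))
  dam_sire <- sires[rep_len(seq_len(ns), nd)]   # dams nested in sires
  founders <- data.frame(animal_id = c(sires, dams),
                         sire_id = NA_character_, dam_id = NA_character_,
                         litter_id = NA_character_, farm = NA_integer_,
                         age_days = NA_real_, role = "unselected",
                         stringsAsFactors = FALSE)
  litters <- sprintf("L%04d", seq_len(nd))
  farm_of_litter <- sample(rep_len(seq_len(config$n_farms), nd))
  noff <- nd * ls
  off <- data.frame(animal_id = sprintf("A%05d", seq_len(noff)),
                    sire_id = rep(dam_sire, each = ls),
                    dam_id = rep(dams, each = ls),
                    litter_id = rep(litters, each = ls),
                    farm = rep(farm_of_litter, each = ls),
                    age_days = rnorm_trunc_pos(noff, config$age_mean, config$age_sd),
                    role = "unselected", stringsAsFactors = FALSE)
  out <- rbind(founders, off)
  class(out) <- c("study_design", "data.frame")
  out
}

# transmit one gamete per parent-genotype entry (matrix in {0,1,2})
transmit_gamete <- function(P) {
  G <- matrix(0L, nrow(P), ncol(P))
  G[P == 2L] <- 1L
  het <- which(P == 1L)
  G[het] <- rbinom(length(het), 1L, 0.5)
  G
}

#' Gene-drop genotypes through the pedigree
#'
#' Founders are drawn from Hardy-Weinberg proportions at each locus (founder
#' allele frequencies uniform on `maf_range`); each offspring receives one
#' allele per parent by fair Mendelian sampling. Codes count alternative
#' alleles (0/1/2).
#'
#' @param design a `study_design` from [simulate_pedigree()].
#' @param config a [sim_config()].
#' @param freqs optional vector of founder alternative-allele frequencies
#'   (length `n_snps`); drawn from `maf_range` when omitted.
#' @return a [geno_matrix()] for every animal in the pedigree; founder
#'   frequencies attached as attribute `founder_freq`.
#' @export
simulate_genotypes <- function(design, config, freqs = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 2L))
  m <- config$n_snps
  if (is.null(freqs))
    freqs <- runif(m, config$maf_range[1], config$maf_range[2])
  stopifnot(length(freqs) == m, all(freqs >= 0), all(freqs <= 1))
  founder <- is.na(design$sire_id)
  nf <- sum(founder)
  F <- matrix(rbinom(nf * m, 2L, rep(freqs, each = nf)), nf, m)
  rownames(F) <- design$animal_id[founder]
  off <- design[!founder, ]
  S <- F[off$sire_id, , drop = FALSE]
  D <- F[off$dam_id, , drop = FALSE]
  O <- transmit_gamete(S) + transmit_gamete(D)
  rownames(O) <- off$animal_id
  codes <- rbind(F, O)[design$animal_id, , drop = FALSE]
  g <- geno_matrix(codes)
  attr(g, "founder_freq") <- freqs
  g
}

# scale raw QTL effects so the genic variance (2 sum p(1-p) a^2) hits the
# target, honouring an exact major-QTL share or an explicit fraction simplex
scale_qtl_effects <- function(a, p, arch, sigma_g2) {
  w <- 2 * p * (1 - p)
  w <- pmax(w, 1e-8)
  if (!is.null(arch$qtl_variance_fractions)) {
    return(sign(a) * sqrt(arch$qtl_variance_fractions * sigma_g2 / w))
  }
  if (arch$major_qtl_fraction > 0 && length(a) >= 1) {
    a[1] <- sign(a[1]) * sqrt(arch$major_qtl_fraction * sigma_g2 / w[1])
    if (length(a) > 1) {
      rest <- sum(w[-1] * a[-1]^2)
      if (rest <= 0) stop("non-major QTL effects are all zero")
      a[-1] <- a[-1] * sqrt((1 - arch$major_qtl_fraction) * sigma_g2 / rest)
    }
    return(a)
  }
  tot <- sum(w * a^2)
  if (tot <= 0) return(a)
  a * sqrt(sigma_g2 / tot)
}

#' Simulate log-scale phenotypes for both taint traits
#'
#' For each trait, `log_value = intercept + farm effect + age_slope * age +
#' sum_k z_k a_k + e`; `raw_concentration = exp(log_value)`. QTL are genotyped
#' SNP columns shared between the traits; raw per-QTL effects are drawn from a
#' bivariate normal with the configured genetic correlation, then rescaled so
#' each trait's genic variance equals `phen_var * h2` exactly (the major QTL,
#' when configured, takes exactly its share). Residuals are independent
#' between traits with variance `phen_var * (1 - h2)`.
#'
#' @param genotypes a [geno_matrix()] covering the design's animals.
#' @param design a `study_design`; only non-founders receive phenotypes.
#' @param config a [sim_config()].
#' @param qtl_idx optional integer vector of QTL column indices (length >=
#'   the larger trait `n_qtl`); sampled when omitted.
#' @return a `phenotype_table` data.frame (long format: `animal_id`, `trait`,
#'   `raw_concentration`, `log_value`, `precorrected`) with a `truth`
#'   attribute holding the QTL indices, scaled effects, true genetic values
#'   and variance components per trait.
#' @export
simulate_phenotypes <- function(genotypes, design, config, qtl_idx = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(design, "study_design"),
            inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 3L))
  traits <- config$traits
  nq <- vapply(traits, function(t) as.numeric(t$n_qtl), 1.0)
  for (nm in names(traits)) {
    if (traits[[nm]]$major_qtl_fraction > 0 && traits[[nm]]$n_qtl == 0)
      stop("trait '", nm, "': major_qtl_fraction > 0 requires n_qtl > 0")
  }
  nq_max <- max(nq, 1L)
  if (nq_max > ncol(genotypes$codes)) stop("more QTL requested than SNPs")
  if (is.null(qtl_idx)) qtl_idx <- sample.int(ncol(genotypes$codes), nq_max)
  off <- design[!is.na(design$sire_id), ]
  Z <- genotypes$codes[off$animal_id, qtl_idx, drop = FALSE]
  if (anyNA(Z)) stop("QTL columns must be complete")
  p <- colMeans(Z) / 2
  rho <- config$genetic_correlation
  u1 <- rnorm(nq_max)
  u2 <- rho * u1 + sqrt(1 - rho^2) * rnorm(nq_max)
  raw_eff <- cbind(u1, u2)
  out <- NULL
  truth <- list(qtl_idx = qtl_idx)
  for (j in seq_along(traits)) {
    nm <- names(traits)[j]
    arch <- traits[[j]]
    sg2 <- config$phen_var * arch$h2
    se2 <- config$phen_var * (1 - arch$h2)
    a <- numeric(nq_max)
    if (arch$n_qtl > 0) {
      idx <- seq_len(arch$n_qtl)
      a[idx] <- scale_qtl_effects(raw_eff[idx, j], p[idx], arch, sg2)
    }
    g <- as.vector(Z %*% a)
    g <- g - sum(2 * p * a) # centre so log_mean is the trait mean
    farm_eff <- rnorm(config$n_farms, 0, config$farm_sd)
    e <- rnorm(nrow(off), 0, sqrt(se2))
    intercept <- arch$log_mean - config$age_slope * config$age_mean
    logv <- intercept + farm_eff[off$farm] + config$age_slope * off$age_days + g + e
    out <- rbind(out, data.frame(animal_id = off$animal_id, trait = nm,
                                 raw_concentration = exp(logv),
                                 log_value = logv, precorrected = NA_real_,
                                 stringsAsFactors = FALSE))
    truth[[nm]] <- list(effects = a[seq_len(max(arch$n_qtl, 0))],
                        qtl_idx = qtl_idx[seq_len(max(arch$n_qtl, 0))],
                        p = p[seq_len(max(arch$n_qtl, 0))],
                        g = setNames(g, off$animal_id),
                        sigma_g2 = sg2, sigma_e2 = se2)
  }
  class(out) <- c("phenotype_table", "data.frame")
  attr(out, "truth") <- truth
  out
}

#' Apply the abattoir discordant sib-pair selection rule
#'
#' Animals with raw skatole at or above `threshold` are case candidates; each
#' case takes the littermate with the lowest skatole below the threshold as
#' its control (one control serves at most one case; within a litter, cases
#' are paired in descending skatole order; ties broken by animal id). Cases
#' without an eligible littermate become `unpaired_case`. When `targets` is
#' given, the eligible pairs/singletons are subsampled (deterministically
#' under the config-derived seed) to exactly the configured design —
#' emulating the original study, which sampled a fixed number of animals;
#' surplus paired cases can be demoted to `unpaired_case` (littermate "not
#' available"), and `unpaired_control`s are drawn from the lowest-skatole
#' unselected animals below the threshold.
#'
#' @param phenotypes a `phenotype_table` containing the skatole trait.
#' @param design a `study_design`.
#' @param threshold raw skatole case threshold (ug/g, > 0); default 0.3.
#' @param targets optional named vector `c(pairs =, unpaired_cases =,
#'   unpaired_controls =)`.
#' @param seed seed for the subsampling stage (default derived from nothing:
#'   pass one for reproducible target subsampling).
#' @return the `study_design` with roles filled in (`case`, `control`,
#'   `unpaired_case`, `unpaired_control`, `unselected`) and an attribute
#'   `pairs` (data.frame `case`, `control`, `litter_id`).
#' @export
apply_case_control_selection <- function(phenotypes, design, threshold = 0.3,
                                         targets = NULL, seed = NULL) {
  if (threshold <= 0) stop("selection threshold must be > 0")
  stopifnot(inherits(design, "study_design"))
  sk <- phenotypes[phenotypes$trait == "skatole", ]
  if (!nrow(sk)) stop("phenotype table has no skatole records")
  off <- design[!is.na(design$sire_id) & design$animal_id %in% sk$animal_id, ]
  val <- setNames(sk$raw_concentration, sk$animal_id)[off$animal_id]
  ord <- order(off$litter_id, off$animal_id)
  off <- off[ord, ]; val <- val[ord]

  pairs <- list(); unpaired <- character(0)
  for (lit in unique(off$litter_id)) {
    in_lit <- off$litter_id == lit
    ids <- off$animal_id[in_lit]; v <- val[in_lit]
    cases <- ids[v >= threshold][order(-v[v >= threshold], ids[v >= threshold])]
    ctrls <- ids[v < threshold][order(v[v < threshold], ids[v < threshold])]
    np <- min(length(cases), length(ctrls))
    if (np > 0)
      pairs[[lit]] <- data.frame(case = cases[seq_len(np)],
                                 control = ctrls[seq_len(np)],
                                 litter_id = lit, stringsAsFactors = FALSE)
    if (length(cases) > np)
      unpaired <- c(unpaired, if (np > 0) cases[-seq_len(np)] else cases)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(case = character(0), control = character(0),
               litter_id = character(0), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL

  if (!is.null(targets)) {
    tg <- as.list(targets)
    need_p <- tg$pairs %||% 0; need_uc <- tg$unpaired_cases %||% 0
    need_un <- tg$unpaired_controls %||% 0
    if (!is.null(seed)) set.seed(seed)
    if (nrow(pairs) < need_p + max(0, need_uc - length(unpaired)))
      stop("design infeasible: only ", nrow(pairs), " eligible pairs")
    keep <- sort(sample.int(nrow(pairs), need_p))
    surplus <- pairs$case[setdiff(seq_len(nrow(pairs)), keep)]
    pairs <- pairs[keep, ]
    pool_uc <- c(unpaired, surplus)
    if (length(pool_uc) < need_uc) stop("not enough unpaired cases available")
    unpaired <- pool_uc[seq_len(need_uc)]
    taken <- c(pairs$case, pairs$control, unpaired)
    free <- setdiff(off$animal_id[val < threshold], taken)
    free <- free[order(val[free])]
    if (length(free) < need_un) stop("not enough unpaired controls available")
    up_ctrl <- free[seq_len(need_un)]
  } else {
    up_ctrl <- character(0)
  }

  design$role <- "unselected"
  design$role[design$animal_id %in% pairs$case] <- "case"
  design$role[design$animal_id %in% pairs$control] <- "control"
  design$role[design$animal_id %in% unpaired] <- "unpaired_case"
  design$role[design$animal_id %in% up_ctrl] <- "unpaired_control"
  attr(design, "pairs") <- pairs
  design
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plant known QC defects into a genotype matrix
#'
#' Fixture generator for quality-control tests: plants SNPs with extreme-low
#' MAF, low call rate or gross Hardy-Weinberg violation, and animals with low
#' call rate, excess heterozygosity or duplicated genotypes, and returns a
#' manifest naming which entity should fail which rule.
#'
#' @param genotypes a clean [geno_matrix()].
#' @param n_maf,n_callrate_snp,n_hwe numbers of defective SNPs to plant.
#' @param n_callrate_animal,n_het_animal,n_dup_animal numbers of defective
#'   animals (each duplicate consumes two animals: source and copy).
#' @param seed RNG seed for placement.
#' @return list with elements `genotypes` (defective matrix) and `manifest`
#'   (data.frame `entity`, `id`, `rule`; duplicates list both members).
#' @export
inject_qc_defects <- function(genotypes, n_maf = 0, n_callrate_snp = 0,
                              n_hwe = 0, n_callrate_animal = 0,
                              n_het_animal = 0, n_dup_animal = 0, seed = 1L) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  X <- genotypes$codes
  n <- nrow(X); m <- ncol(X)
  ncol_def <- n_maf + n_callrate_snp + n_hwe
  nrow_def <- n_callrate_animal + n_het_animal + 2 * n_dup_animal
  if (ncol_def > m || nrow_def > n) stop("defect counts exceed matrix dimensions")
  set.seed(seed)
  snp_pick <- sample.int(m, ncol_def)
  ani_pick <- sample.int(n, nrow_def)
  i_maf <- snp_pick[seq_len(n_maf)]
  i_crs <- snp_pick[n_maf + seq_len(n_callrate_snp)]
  i_hwe <- snp_pick[n_maf + n_callrate_snp + seq_len(n_hwe)]
  a_cr <- ani_pick[seq_len(n_callrate_animal)]
  a_het <- ani_pick[n_callrate_animal + seq_len(n_het_animal)]
  a_dup <- ani_pick[n_callrate_animal + n_het_animal + seq_len(2 * n_dup_animal)]
  clean_ani <- setdiff(seq_len(n), ani_pick)
  clean_snp <- setdiff(seq_len(m), snp_pick)

  for (k in i_maf) { # one heterozygote in an otherwise monomorphic column
    X[, k] <- 0L
    X[sample(clean_ani, 1), k] <- 1L
  }
  for (k in i_crs) { # ~10% missing
    X[sample(clean_ani, max(1L, ceiling(0.1 * n))), k] <- NA_integer_
  }
  for (k in i_hwe) { # complete heterozygote deficit at p = 0.5
    X[, k] <- rep_len(c(0L, 2L), n)
  }
  for (i in a_cr) { # ~10% of the animal's calls missing
    X[i, sample(clean_snp, max(1L, ceiling(0.1 * m)))] <- NA_integer_
  }
  for (i in a_het) { # heterozygous everywhere off the planted columns
    X[i, clean_snp] <- 1L
  }
  manifest <- data.frame(entity = character(0), id = character(0),
                         rule = character(0), stringsAsFactors = FALSE)
  add <- function(mf, entity, id, rule)
    rbind(mf, data.frame(entity = entity, id = id, rule = rule,
                         stringsAsFactors = FALSE))
  if (n_dup_animal > 0) {
    for (d in seq_len(n_dup_animal)) {
      src <- a_dup[2 * d - 1]; dst <- a_dup[2 * d]
      X[dst, ] <- X[src, ]
      manifest <- add(manifest, "animal", rownames(X)[src], "duplicate")
      manifest <- add(manifest, "animal", rownames(X)[dst], "duplicate")
    }
  }
  if (n_maf) manifest <- add(manifest, "snp", colnames(X)[i_maf], "maf")
  if (n_callrate_snp) manifest <- add(manifest, "snp", colnames(X)[i_crs], "callrate")
  if (n_hwe) manifest <- add(manifest, "snp", colnames(X)[i_hwe], "hwe")
  if (n_callrate_animal) manifest <- add(manifest, "animal", rownames(X)[a_cr], "callrate")
  if (n_het_animal) manifest <- add(manifest, "animal", rownames(X)[a_het], "heterozygosity")
  list(genotypes = geno_matrix(X, genotypes$map), manifest = manifest)
}

#' Simulate a complete discordant sib-pair taint study
#'
#' Convenience wrapper: pedigree, gene-drop genotypes, two-trait phenotypes
#' and case-control selection, then subsets everything to the selected
#' animals. With the default configuration and targets, the selected design
#' holds 421 discordant pairs plus 40 unpaired cases and 56 unpaired controls
#' (938 animals; 461 cases).
#'
#' @param config a [sim_config()].
#' @param targets design targets passed to [apply_case_control_selection()];
#'   `NULL` keeps every animal the raw rule selects.
#' @return list with `design` (selected animals only), `genotypes`,
#'   `phenotypes`, `full_design`, and the selection `pairs`.
#' @export
simulate_taint_study <- function(config = sim_config(),
                                 targets = c(pairs = 421, unpaired_cases = 40,
                                             unpaired_controls = 56)) {
  ped <- simulate_pedigree(config)
  gen <- simulate_genotypes(ped, config)
  phe <- simulate_phenotypes(gen, ped, config)
  sel <- apply_case_control_selection(phe, ped, config$selection_threshold,
                                      targets = targets,
                                      seed = derive_seed(config$seed, 4L))
  keep <- sel$role != "unselected" & !is.na(sel$sire_id)
  if (is.null(targets)) keep <- keep # raw rule: keep whatever was selected
  design <- sel[keep, , drop = FALSE]
  class(design) <- c("study_design", "data.frame")
  attr(design, "pairs") <- attr(sel, "pairs")
  g <- geno_matrix(gen$codes[design$animal_id, , drop = FALSE], gen$map)
  phe_sel <- phe[phe$animal_id %in% design$animal_id, ]
  class(phe_sel) <- c("phenotype_table", "data.frame")
  attr(phe_sel, "truth") <- attr(phe, "truth")
  list(design = design, genotypes = g, phenotypes = phe_sel,
       full_design = sel, pairs = attr(sel, "pairs"))
}
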