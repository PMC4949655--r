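# shared fixture builders (all generated in code; no stored data)

# small family-structured study: pedigree, genotypes, both traits
small_study <- function(n_sires = 20, n_dams = 50, litter_size = 6,
                        n_snps = 300, seed = 7,
                        skatole = trait_arch(min(10, n_snps), 0.3,
                                             major_qtl_fraction = 0.77,
                                             log_mean = log(0.3)),
                        androstenone = trait_arch(min(50, n_snps), 0.3),
                        maf_range = c(0.1, 0.4)) {
  cfg <- sim_config(n_sires = n_sires, n_dams = n_dams,
                    litter_size = litter_size, n_snps = n_snps,
                    maf_range = maf_range, skatole = skatole,
                    androstenone = androstenone, seed = seed)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  phe <- simulate_phenotypes(gen, ped, cfg)
  list(cfg = cfg, ped = ped, gen = gen, phe = phe)
}

# unrelated genotypes in HWE at given frequencies (polymorphic in-sample)
hwe_genotypes <- function(n, m, p_range = c(0.1, 0.4), seed = 1) {
  set.seed(seed)
  p <- runif(m, p_range[1], p_range[2])
  X <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  mono <- function(x) { f <- colMeans(x) / 2; f <= 0 | f >= 1 }
  while (any(bad <- mono(X)))
    X[, bad] <- rbinom(n * sum(bad), 2L, rep(p[bad], each = n))
  geno_matrix(X)
}

# pre-corrected skatole phenotypes + matching genotype rows
precorrected_skatole <- function(st) {
  phe <- precorrect_phenotypes(st$phe, st$ped)
  sk <- phe[phe$trait == "skatole", ]
  list(y = setNames(sk$precorrected, sk$animal_id),
       Z = geno_matrix(st$gen$codes[sk$animal_id, , drop = FALSE]))
}
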