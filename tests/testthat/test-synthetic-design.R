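test_that("pedigree construction hits the configured counts and is deterministic", {
  cfg <- sim_config(n_sires = 128, n_dams = 441, litter_size = 14,
                    n_farms = 14, n_snps = 10, seed = 11)
  ped <- simulate_pedigree(cfg)
  off <- ped[!is.na(ped$sire_id), ]
  expect_equal(nrow(off), 441 * 14)                 # 6174 offspring
  expect_equal(length(unique(off$litter_id)), 441)
  expect_equal(length(unique(off$sire_id)), 128)
  expect_equal(length(unique(off$dam_id)), 441)
  expect_equal(sort(unique(off$farm)), 1:14)
  # littermates share sire and dam; dams nested in sires
  by_lit <- split(off, off$litter_id)
  expect_true(all(vapply(by_lit, function(d)
    length(unique(d$sire_id)) == 1 && length(unique(d$dam_id)) == 1, TRUE)))
  expect_true(all(tapply(off$sire_id, off$dam_id,
                         function(s) length(unique(s))) == 1))
  # determinism
  expect_identical(ped, simulate_pedigree(cfg))

  tiny <- simulate_pedigree(sim_config(n_sires = 1, n_dams = 1,
                                       litter_size = 2, n_snps = 10))
  expect_equal(sum(!is.na(tiny$sire_id)), 2)
  expect_equal(length(unique(tiny$litter_id[!is.na(tiny$litter_id)])), 1)

  expect_error(simulate_pedigree(sim_config(litter_size = 1, n_snps = 10)),
               "litter_size")
})

test_that("gene drop is Mendelian-consistent and reproduces sib relationships", {
  cfg <- sim_config(n_sires = 5, n_dams = 10, litter_size = 4, n_snps = 5000,
                    maf_range = c(0.1, 0.5), seed = 3)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  X <- gen$codes
  off <- ped[!is.na(ped$sire_id), ]
  S <- X[off$sire_id, ]; D <- X[off$dam_id, ]; O <- X[off$animal_id, ]
  # offspring alleles constructible from parents at every locus
  lo <- (S == 2) + (D == 2)            # minimum transmissible alt count
  hi <- 2 - ((S == 0) + (D == 0))      # maximum transmissible alt count
  expect_true(all(O >= lo & O <= hi))
  # fixed locus: founder frequency 1 -> all genotypes 2
  cfg1 <- sim_config(n_sires = 2, n_dams = 4, litter_size = 3, n_snps = 3)
  ped1 <- simulate_pedigree(cfg1)
  gen1 <- simulate_genotypes(ped1, cfg1, freqs = c(1, 0, 0.5))
  expect_true(all(gen1$codes[, 1] == 2))
  expect_true(all(gen1$codes[, 2] == 0))
  # full sibs average relationship ~ 0.5 when centred at the founder
  # (base-population) frequencies
  G <- compute_grm(gen, freqs = attr(gen, "founder_freq"))
  sib_pairs <- do.call(rbind, lapply(split(off$animal_id, off$litter_id),
                                     function(a) t(combn(a, 2))))
  gsib <- mapply(function(i, j) G$G[i, j], sib_pairs[, 1], sib_pairs[, 2])
  expect_lt(abs(mean(gsib) - 0.5), 0.05)
  # determinism
  expect_identical(gen$codes, simulate_genotypes(ped, cfg)$codes)
})

test_that("phenotype simulator realises the configured h2 and QTL shares", {
  cfg <- sim_config(n_sires = 50, n_dams = 250, litter_size = 8, n_snps = 500,
                    skatole = trait_arch(21, 0.3, major_qtl_fraction = 0.77,
                                         log_mean = log(0.3)),
                    androstenone = trait_arch(100, 0.3), seed = 5)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  phe <- simulate_phenotypes(gen, ped, cfg)  # n = 2000 offspring
  truth <- attr(phe, "truth")
  for (tr in c("skatole", "androstenone")) {
    tt <- truth[[tr]]
    genic <- 2 * tt$p * (1 - tt$p) * tt$effects^2
    h2_real <- sum(genic) / (sum(genic) + tt$sigma_e2)
    expect_lt(abs(h2_real - 0.3), 0.05)
  }
  # leading QTL share of genic variance ~ 0.77 for the skatole-like trait
  tt <- truth$skatole
  genic <- 2 * tt$p * (1 - tt$p) * tt$effects^2
  expect_lt(abs(genic[1] / sum(genic) - 0.77), 0.05)
  # raw = exp(log)
  expect_equal(phe$raw_concentration, exp(phe$log_value))
  # all-zero architecture: variance is residual only
  cfg0 <- sim_config(n_sires = 10, n_dams = 30, litter_size = 6, n_snps = 50,
                     skatole = trait_arch(0, 1e-9, log_mean = log(0.3)),
                     androstenone = trait_arch(0, 1e-9), farm_sd = 0,
                     age_slope = 0, seed = 2)
  expect_error(trait_arch(0, 0.3, major_qtl_fraction = 0.5), "n_qtl")
  ped0 <- simulate_pedigree(cfg0)
  gen0 <- simulate_genotypes(ped0, cfg0)
  phe0 <- simulate_phenotypes(gen0, ped0, cfg0)
  sk0 <- phe0[phe0$trait == "skatole", ]
  expect_lt(abs(var(sk0$log_value) - cfg0$phen_var), 0.1)
})

test_that("case-control selection follows the littermate rule", {
  # hand-built design: one litter with values {0.5, 0.2, 0.1}
  mk <- function(vals, litters) {
    n <- length(vals)
    d <- data.frame(animal_id = sprintf("A%02d", 1:n),
                    sire_id = "S1", dam_id = paste0("D", litters),
                    litter_id = paste0("L", litters),
                    farm = 1L, age_days = 160, role = "unselected",
                    stringsAsFactors = FALSE)
    class(d) <- c("study_design", "data.frame")
    p <- data.frame(animal_id = d$animal_id, trait = "skatole",
                    raw_concentration = vals, log_value = log(vals),
                    precorrected = NA_real_, stringsAsFactors = FALSE)
    list(d = d, p = p)
  }
  x <- mk(c(0.5, 0.2, 0.1), c(1, 1, 1))
  sel <- apply_case_control_selection(x$p, x$d, 0.3)
  expect_equal(sel$role, c("case", "unselected", "control")) # lowest is control
  # litter below threshold: no case
  x <- mk(c(0.1, 0.2), c(1, 1))
  sel <- apply_case_control_selection(x$p, x$d, 0.3)
  expect_true(all(sel$role == "unselected"))
  # no eligible littermate control -> unpaired case
  x <- mk(c(0.5, 0.4), c(1, 1))
  sel <- apply_case_control_selection(x$p, x$d, 0.3)
  expect_equal(sel$role, c("unpaired_case", "unpaired_case"))
  expect_error(apply_case_control_selection(x$p, x$d, 0), "threshold")
})

test_that("selection invariants hold on simulated data", {
  st <- small_study(seed = 13)
  sel <- apply_case_control_selection(st$phe, st$ped, 0.3)
  pairs <- attr(sel, "pairs")
  sk <- st$phe[st$phe$trait == "skatole", ]
  val <- setNames(sk$raw_concentration, sk$animal_id)
  lit <- setNames(sel$litter_id, sel$animal_id)
  expect_true(all(val[pairs$case] >= 0.3))
  expect_true(all(val[pairs$control] < 0.3))
  expect_true(all(lit[pairs$case] == lit[pairs$control]))
  expect_equal(sum(sel$role == "case"), sum(sel$role == "control"))
  expect_equal(anyDuplicated(c(pairs$case, pairs$control)), 0L)
})

test_that("planted QC defects are recorded faithfully in the manifest", {
  gm <- hwe_genotypes(120, 400, seed = 9)
  def <- inject_qc_defects(gm, n_maf = 10, n_callrate_snp = 5, n_hwe = 4,
                           n_callrate_animal = 3, n_het_animal = 2,
                           n_dup_animal = 1, seed = 4)
  mf <- def$manifest
  expect_equal(sum(mf$rule == "maf"), 10)
  expect_equal(sum(mf$rule == "duplicate"), 2)
  X <- def$genotypes$codes
  for (id in mf$id[mf$rule == "maf"]) {
    f <- mean(X[, id], na.rm = TRUE) / 2
    expect_lte(min(f, 1 - f), 0.01)
  }
  for (id in mf$id[mf$rule == "callrate" & mf$entity == "snp"])
    expect_lte(mean(!is.na(X[, id])), 0.95)
  dup <- mf$id[mf$rule == "duplicate"]
  expect_identical(X[dup[1], ], X[dup[2], ])
  expect_error(inject_qc_defects(gm, n_maf = 1000), "exceed")
})
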