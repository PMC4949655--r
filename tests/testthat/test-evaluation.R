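test_that("Nadaf genetic variance and heritability follow their formulas", {
  # degenerate chain: PEV all zero -> var(EBV) alone
  g <- c(0.2, -0.1, 0.4, 0.1)
  expect_equal(nadaf_genetic_variance(g, rep(0, 4)), var(g))
  # hand computation: gebv (0,0), pev (1,3) -> 0 + 2
  expect_equal(nadaf_genetic_variance(c(0, 0), c(1, 3)), 2)
  expect_error(nadaf_genetic_variance(1, 1), "at least 2")

  expect_equal(heritability(0.149, 0.333), 0.149 / 0.482)
  expect_equal(round(heritability(0.149, 0.333), 3), 0.309)
  expect_equal(heritability(0, 1), 0)
  expect_equal(heritability(1, 1), 0.5)
  expect_error(heritability(0, 0), "both")
  # conjugate simulation oracle: single-SNP model with known variances
  set.seed(31)
  n <- 300
  z <- rbinom(n, 2, 0.5)
  a <- 0.5
  y <- a * z + rnorm(n, 0, 1)
  fit <- bayes_wgr(y, cbind(z), "BayesC", pi = 1,
                   schedule = chain_schedule(1000, 500, 2),
                   fix = list(sigma_s2 = 10, sigma_e2 = 1), seed = 3)
  sg2 <- nadaf_genetic_variance(fit)
  true_sg2 <- var(a * z)
  # slope-estimation error dominates: sd(beta-hat) ~ 0.06 -> ~3 sd band
  expect_lt(abs(sg2 - true_sg2) / true_sg2, 0.7)
})

test_that("relative accuracy reproduces the published worked examples", {
  # skatole, Bayes SSVS: r = 0.266 over sqrt(mean of the six printed h2)
  expect_equal(relative_accuracy(0.266, c(0.051, 0.094, 0.074, 0.087,
                                          0.106, 0.068)),
               0.940, tolerance = 0.004 / 0.940)
  # androstenone, Bayes B and Bayes A
  h2a <- c(0.307, 0.287, 0.276, 0.281, 0.299, 0.284)
  expect_equal(relative_accuracy(0.310, h2a), 0.577, tolerance = 0.004 / 0.577)
  expect_equal(relative_accuracy(0.301, h2a), 0.559, tolerance = 0.004 / 0.559)
  expect_equal(relative_accuracy(0, h2a), 0)
  expect_error(relative_accuracy(0.3, c(0, 0)), "h2")
})

test_that("chain schedule arithmetic matches the published schedule", {
  expect_equal(chain_total_cycles(chain_schedule(50000, 20000, 50)), 1050000)
  expect_equal(chain_total_cycles(chain_schedule(0, 1, 1)), 1)
  expect_equal(chain_total_cycles(chain_schedule(100, 10, 2)), 120)
  expect_error(chain_schedule(100, 0, 2))
})

test_that("cross-validation folds preserve sib pairs and balance sizes", {
  mkdesign <- function(n_pairs, n_singles) {
    ids <- sprintf("A%04d", seq_len(2 * n_pairs + n_singles))
    d <- data.frame(animal_id = ids, sire_id = "S1", dam_id = "D1",
                    litter_id = "L1", farm = 1L, age_days = 160,
                    role = "unselected", stringsAsFactors = FALSE)
    class(d) <- c("study_design", "data.frame")
    attr(d, "pairs") <- data.frame(
      case = ids[seq_len(n_pairs) * 2 - 1], control = ids[seq_len(n_pairs) * 2],
      litter_id = paste0("L", seq_len(n_pairs)), stringsAsFactors = FALSE)
    d
  }
  # the published design: 421 pairs + 96 singletons -> folds of 187-188
  d <- mkdesign(421, 96)
  f <- make_cv_folds(d, k = 5, seed = 2)
  expect_equal(length(f), 938)
  expect_setequal(names(f), d$animal_id)
  sizes <- as.integer(table(f))
  expect_true(all(sizes %in% c(187, 188)))
  pairs <- attr(d, "pairs")
  expect_true(all(f[pairs$case] == f[pairs$control]))
  # determinism
  expect_identical(f, make_cv_folds(d, k = 5, seed = 2))
  # small case: every pair co-assigned
  d2 <- mkdesign(4, 2)
  f2 <- make_cv_folds(d2, k = 5, seed = 3)
  p2 <- attr(d2, "pairs")
  expect_true(all(f2[p2$case] == f2[p2$control]))
  expect_error(make_cv_folds(mkdesign(1, 1), k = 5), "fewer units")
})

test_that("fold accuracy is the within-fold correlation with affine invariance", {
  set.seed(9)
  ids <- sprintf("A%03d", 1:60)
  y <- setNames(rnorm(60), ids)
  folds <- setNames(rep(1:5, each = 12), ids)
  # GEBV identical to phenotype -> r = 1 in every fold
  acc <- fold_accuracy(y, y, folds)
  expect_equal(unname(acc$r_fold), rep(1, 5))
  expect_equal(acc$mean_r, 1)
  # anti-correlated -> r = -1
  expect_equal(fold_accuracy(-y, y, folds)$mean_r, -1)
  # affine transformation with positive slope leaves r unchanged
  g <- setNames(rnorm(60), ids)
  expect_equal(fold_accuracy(3 * g + 2, y, folds)$r_fold,
               fold_accuracy(g, y, folds)$r_fold)
  # constant fold flagged and excluded
  g2 <- g; g2[folds == 2] <- 5
  expect_warning(a2 <- fold_accuracy(g2, y, folds), "undefined")
  expect_true(is.na(a2$r_fold[2]))
  expect_equal(a2$mean_r, mean(a2$r_fold[-2]))
})

test_that("single-QTL baseline behaves at the extremes and under the null", {
  set.seed(13)
  ids <- sprintf("A%03d", 1:200)
  z <- setNames(rbinom(200, 2, 0.4), ids)
  folds <- setNames(rep(1:5, 40), ids)
  # phenotype exactly linear in the SNP -> r = 1
  y <- setNames(2 + 0.7 * z, ids)
  res <- qtl_only_predict(z, y, folds)
  expect_equal(unname(res$r_fold), rep(1, 5))
  # null SNP: mean r near 0 over replicates
  rs <- vapply(1:10, function(r) {
    set.seed(100 + r)
    yn <- setNames(rnorm(200), ids)
    qtl_only_predict(z, yn, folds)$mean_r
  }, 1.0)
  expect_lt(abs(mean(rs)), 0.08)
  # monomorphic training fold flagged
  z2 <- z; z2[folds != 1] <- 1
  expect_warning(qtl_only_predict(z2, y, folds), "monomorphic")
})

test_that("PCA of method GEBVs places duplicated methods together", {
  set.seed(17)
  n <- 50
  base <- rnorm(n)
  M <- cbind(m1 = base, m2 = base * 2 + 1, m3 = rnorm(n))
  pc <- gebv_pca(M)
  co <- pc$coordinates
  # perfectly correlated methods collocate on both components
  expect_equal(co$PC1[1], co$PC1[2], tolerance = 1e-8)
  expect_equal(co$PC2[1], co$PC2[2], tolerance = 1e-8)
  # the orthogonal method separates on PC2
  expect_gt(abs(co$PC2[3] - co$PC2[1]), 0.1)
  # six identical columns: PC1 explains 100%
  M6 <- matrix(rep(base, 6), n)
  colnames(M6) <- paste0("m", 1:6)
  pc6 <- gebv_pca(M6)
  expect_equal(pc6$var_explained[1], 1, tolerance = 1e-8)
  # constant column errors with the method named
  Mc <- M; Mc[, 2] <- 1
  expect_error(gebv_pca(Mc), "m2")
})

test_that("cv_evaluate ties the machinery together on a small study", {
  st <- small_study(n_sires = 20, n_dams = 60, litter_size = 6, n_snps = 300,
                    seed = 47,
                    skatole = trait_arch(150, 0.5, major_qtl_fraction = 0.2,
                                         log_mean = log(0.3)))
  pc <- precorrected_skatole(st)
  # all phenotyped animals; selection pairs stay co-assigned, the rest are
  # singleton units
  sel <- apply_case_control_selection(st$phe, st$ped, 0.3)
  d <- sel[!is.na(sel$sire_id), ]
  class(d) <- c("study_design", "data.frame")
  attr(d, "pairs") <- attr(sel, "pairs")
  folds <- make_cv_folds(d, k = 3, seed = 5)
  y <- pc$y[names(folds)]
  Z <- pc$Z$codes[names(folds), ]
  rep_ <- cv_evaluate(y, Z, folds, methods = c("GBLUP", "BayesSSVS"),
                      schedule = chain_schedule(400, 150, 2), seed = 21)
  expect_s3_class(rep_, "cv_report")
  expect_true(all(is.finite(rep_$mean_r)))
  expect_true(all(rep_$r_fold >= -1 & rep_$r_fold <= 1))
  expect_true(all(rep_$h2 >= 0 & rep_$h2 <= 1))
  expect_equal(dim(rep_$r_fold), c(3, 2))
  expect_equal(rep_$r_star, rep_$mean_r / sqrt(mean(rep_$h2)))
  # every animal predicted exactly once
  expect_false(anyNA(rep_$gebv))
  # PCA on the CV GEBVs runs end to end
  pca <- gebv_pca(rep_$gebv)
  expect_equal(nrow(pca$coordinates), 2)
})
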