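---
title: "Genomic evaluation of boar-taint compounds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic evaluation of boar-taint compounds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taintsel)
```

## The problem

Boar taint — the offensive odour of meat from intact male pigs — is driven by
fat concentrations of two compounds, androstenone and skatole. Both traits are
heritable but can only be measured on slaughtered males, which makes
conventional selection slow and expensive. Genomic prediction sidesteps this:
SNP genotypes of selection candidates are combined with marker effects
estimated in a phenotyped training population to produce genomic estimated
breeding values (GEBVs). This package implements and compares six
whole-genome evaluation methods for these two traits, together with the
study-design machinery (discordant littermate case-control sampling, SNP and
individual quality control, pair-preserving cross-validation, a single-QTL
baseline) needed to evaluate them end to end on synthetic data.

## Models

### Phenotype pre-correction

Concentrations (ug/g fat) are log-transformed (natural log; the convention in
this literature) and pre-corrected by ordinary least squares for farm (fixed
effect) and slaughter age (covariate). Carcass weight and meat percentage are
deliberately *not* used: they may be confounded with genes affecting taint.
All downstream models work with these residuals, so `mu` in the models below
absorbs only what pre-correction leaves behind.

### GBLUP

`gblup()` fits `y = mu 1 + u + e`, `u ~ MVN(0, sigma_g^2 G)`,
`e ~ MVN(0, sigma_e^2 I)` by REML. `G` is the SNP-derived relationship matrix
with off-diagonals

    g_ij = (1/n) sum_k (x_ik - 2 p_k)(x_jk - 2 p_k) / (2 p_k (1 - p_k))

and heterozygosity-deficit diagonals

    g_ii = 1 + (1/n) sum_k (He_k - H_ik) / He_k,   He_k = 2 p_k (1 - p_k),

with `H_ik` the 0/1 heterozygosity indicator. Allele frequencies are computed
in-sample on the full post-QC data set and reused for fold-level sub-blocks
(a single G per data set; recomputing per training fold is possible by
passing a fold-level `compute_grm()` result).

**Numerical choices.** The REML fit eigendecomposes G once and profiles the
restricted likelihood over the variance ratio `gamma = sigma_g^2 / sigma_e^2`
by one-dimensional bounded optimisation on the log scale (tolerance 1e-10 on
`log gamma`, i.e. far below 1e-8 on `gamma` at the optimum); this is exact and
robust at the study's scale of ~1000 animals. A fit whose optimum sits at the
lower search edge is reported as a boundary fit with `sigma_g^2 = 0` and
`converged = FALSE`.

**Indefinite G.** Replacing the cross-product diagonal with the
heterozygosity-deficit formula makes G *mildly indefinite* in finite samples
— we observe smallest eigenvalues around -0.2 to -0.003 across the scales
used here, shrinking as the SNP count grows. An abort-on-negative-eigenvalue
policy would therefore reject essentially every real data set. `gblup()`
instead clamps negative eigenvalues to zero — the spectral projection onto
the nearest positive semi-definite matrix, keeping eigenvectors — records the
original smallest eigenvalue in the fit (`min_eigenvalue`), and aborts only
when the matrix is grossly invalid (smallest eigenvalue below -0.25 times the
largest). Validation GEBVs use the conditional-expectation predictor
`u_v = sigma_g^2 G_vt V^{-1} (y - mu)`, algebraically equal to
`G_vt G_tt^{-1} u_t` and to the mixed-model equations with validation animals
included at unknown phenotypes (both equalities are tested).

### Bayesian whole-genome regression

`bayes_wgr()` fits `y = mu 1 + Z beta + e` by Gibbs sampling with one of five
priors on the SNP effects `beta_k`:

* **BayesA** — scaled Student's t with scale `lambda` and shape `nu`,
  implemented through the normal-scale-mixture representation
  `beta_k | sigma_k^2 ~ N(0, sigma_k^2)`,
  `sigma_k^2 ~ scaled-inv-chisq(nu, lambda)`. The conditional for
  `sigma_k^2` is `scaled-inv-chisq(nu + 1, (nu lambda + beta_k^2)/(nu + 1))`.
  The (scale, shape) density convention is exactly this parameterisation,
  used consistently throughout.
* **BayesB** — as BayesA, but only a fraction `pi` of SNPs carry effects; the
  zero component is an exact point mass (not a small variance). The
  indicator is sampled from the marginalised two-component likelihood ratio
  with `beta_k` integrated out, then `beta_k` from its conditional normal.
* **BayesC** — non-zero effects `N(0, sigma_s^2)` with mixing proportion
  `pi`, fixed at 0.1 by default (the original study's choice, made because
  the low heritability of skatole caused convergence problems when `pi` was
  free).
* **BayesSSVS** — every effect from a two-component normal mixture with
  variances `sigma_s^2` and `sigma_s^2 / 10 000`; all SNPs stay in the model.
* **BayesLasso** — Laplace prior with scale `lambda` through the
  normal-exponential augmentation; `1/tau_k^2` has an inverse-Gaussian
  conditional and `lambda^2` a gamma-form conditional.

**Hyperparameters.** All are estimated from the data under bounded flat
priors: `lambda`, `sigma_s^2` and `sigma_e^2` are uniform on `(0, B]` with
`B` defaulting to `1e6` (`lambda`) or `1e6 x var(y)` (variances) so the prior
influence is negligible; their conditionals are gamma/scaled-inverse-
chi-square forms truncated to the bound (sampled by inverse-CDF, never
silently clamped). The shape `nu` is bounded in `[0.5, 8]` and updated by
griddy Gibbs on 64 log-spaced grid points (robust, no Metropolis tuning; the
grid size is configurable). `pi` is estimated with a uniform prior (Beta
conditional from the inclusion counts) in BayesB and SSVS — the study fixes
`pi` only for BayesC, and whether B/SSVS estimated it is ambiguous, so both
modes exist via the `pi` argument.

**Schedule and outputs.** The default chain is the study's: 50 000 burn-in
cycles, 20 000 retained realisations separated by 50 cycles — 1 050 000
cycles total. This is a long-running configuration; every example and test
here uses reduced schedules (e.g. 1 000 / 250 / 2), which we verified against
conjugate closed forms. Per-animal genetic values `g_i = sum_k z_ik beta_k`
are accumulated online along the chain, so the full effect chain need not be
stored (`store_beta = TRUE` keeps it for small panels). The posterior mean of
`g_i` is the GEBV; the *sample* variance of `g_i` over retained realisations
is its prediction error variance (PEV) — the sample-variance convention is
documented and tested. Genotype columns are used uncentred (the model has an
explicit mean); a `center` flag exists, and correlation-based accuracies are
invariant to it.

### Heritability

`h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`. For GBLUP both components come
from REML. For the Bayesian fits the genetic variance uses the
chain-based decomposition `sigma_g^2 = var(EBV) + mean(PEV)` over training
animals, with `sigma_e^2` the posterior mean of the residual-variance chain.
Note one documented inconsistency in the published tables this package
emulates: the skatole GBLUP row prints variance components (0.014, 0.466)
whose ratio gives 0.029, not the printed 0.051. `heritability()` computes
strictly by the formula; worked-example tests use the printed inputs and
tolerate only the rounding noise (±0.004 on r*).

### Cross-validation and accuracy

`make_cv_folds()` builds five folds that keep each discordant sib pair
together (pairs are indivisible units; singletons fill the remaining slots,
which bounds the fold-size spread at one animal — 187/188 animals for the
938-animal design). Accuracy `r` is the Pearson correlation between GEBV and
the *pre-corrected* phenotype within each validation fold, averaged over
folds; its SE is the SD of fold accuracies over `sqrt(k)`. The relative
accuracy `r* = r / sqrt(mean h2)` scales by the across-method average of
whole-data-fit heritabilities (per-fold averages via
`h2_for_rstar = "fold_mean"`); it approximates the accuracy of predicting the
breeding value itself. Folds with undefined correlation (constant
predictions, e.g. a boundary GBLUP fit) are excluded from the mean with a
warning rather than failing the run. The single-QTL baseline fits OLS of the
phenotype on one SNP's allele count per training fold and predicts the
validation fold from intercept + slope x code. `gebv_pca()` compares methods
by a PCA of the animals x methods GEBV matrix with columns standardised to
unit variance (methods differ in GEBV variance by construction; raw
covariance PCA via `standardize = FALSE`), component signs fixed so the
largest-magnitude loading is positive.

## The synthetic world

No data from the original study are deposited, so the package carries a
generator whose defaults state the design it emulates:

* **Pedigree**: 128 sires, 441 dams nested within sires, one litter per dam,
  14 farms assigned whole litters; two generations. This is the simplest
  structure producing the full-sib and paternal half-sib classes the design
  relies on. The true litter-size distribution is unreported; the default of
  14 is configurable and only the selected subset matters downstream.
* **Genotypes**: biallelic gene drop; founder allele frequencies uniform on
  the configured MAF range, founders in Hardy-Weinberg proportions, fair
  Mendelian transmission. There is no linkage map and no LD between loci
  (a stated non-goal), which matters for interpretation: a *masked* causal
  locus would be completely untagged here, unlike on a real chip.
* **Phenotypes**: `log value = intercept + farm + age slope x age + sum z a
  + e`. The skatole-like trait carries 21 QTL with the leading one scaled to
  exactly 77% of the genic variance (the share reported for the major
  skatole QTL segregating in this population); the androstenone-like trait
  is polygenic. Both default to h2 = 0.3 — the reported androstenone scale;
  skatole's published estimates (0.05-0.11) come from fits distorted by the
  discordant-pair sampling itself, so the generator states the same
  biological h2 for both and lets selection do the distorting (we reproduce
  exactly that distortion: REML h2 on a selected subset collapses towards
  zero). Trait means: `log(0.3)` for skatole so the 0.3 ug/g threshold
  splits the population, 0 for androstenone. Farm effects N(0, 0.2^2), age
  N(161.3, 1.36) truncated positive with slope 0.02/day, total phenotypic
  variance 0.48 on the log scale (matching the printed variance-component
  sums). Genetic correlation 0.41 between the traits (the cited estimate),
  realised by drawing per-QTL effect pairs from a bivariate normal over a
  shared QTL panel; the major-QTL rescaling is applied to the leading locus
  and the polygenic remainder as groups, so variance shares are exact while
  the realised correlation is approximate.
* **Selection**: every animal at or above 0.3 ug/g raw skatole is a case
  candidate; each case takes its litter's lowest-skatole below-threshold
  animal as control (descending-skatole pairing order within litter, ties by
  animal id for determinism; one control serves one case). The original
  study sampled fixed numbers (421 pairs, 40 high and 56 low singletons,
  938 animals, 461 cases); the generator reproduces those counts by
  deterministic subsampling of the eligible pairs, demoting surplus paired
  cases to unpaired (the study's "littermate not available" cases) and
  drawing unpaired controls from the lowest-skatole unselected animals. How
  often the original controls came "from another litter" is unknown;
  cross-litter pairing is not emulated.

What a green test on this world does *not* establish: real LD structure,
genotyping-error patterns, assay error distinct from the residual, or the
original population's allele-frequency spectrum. The generator's value is
that every structural claim (selection rule, QC boundary conventions, fold
construction, estimator algebra, the GBLUP-vs-variable-selection contrast
under a major QTL) is checked against a world whose truth is known.

## Quality control

Rules and boundary conventions follow the source design: SNPs with MAF <=
0.01, call rate <= 0.95, or extreme Hardy-Weinberg departure at a
Benjamini-Hochberg FDR of 1% (the test statistic was unspecified; we use the
1-df chi-square goodness-of-fit, adequate at n ~ 1000, with the exact
conditional test as an option) are removed, in that order, each SNP counted
against the first rule that removes it. Then animals with call rate <= 0.95
or autosomal heterozygosity >= 0.45 are removed, and any pair with genomic
relationship >= 0.95 is eliminated — both members, reading the source's
"pair ... was eliminated" literally (`duplicate_action = "keep_one"` for the
other reading). The published removal counts do not reconcile by simple
subtraction, so the original overlap accounting is unknowable; the
first-rule convention here is an explicit choice. Missing genotypes are
mean-imputed (2p per SNP) after QC — required by both the G matrix and the
regressions, and unstated in the source.

## Seeds and reproducibility

Every stochastic stage takes a seed; `sim_config()` and the pipeline carry
one master seed from which stage, fold and chain seeds are derived by a
fixed splitting rule (`seed * 1009 + stage * 101 mod 2^31-ish`). Identical
configuration implies bit-identical simulated data and identical chains; the
compiled samplers draw from R's RNG so `set.seed()` governs everything.

## Known limitations

* No pedigree-based (A-matrix) BLUP, multi-trait REML, or dominance terms.
* No LD simulation; the QTL-only baseline therefore sees a perfectly tagged
  QTL, making it stronger here than a real GWAS tag SNP would be.
* The SSVS spike (`sigma_s^2 / 10 000`) keeps all SNPs in the model, which
  adds a little prediction noise on small training sets relative to
  BayesB's exact zeros — visible in the synthetic comparisons.
* Chains at the study's full schedule (1 050 000 cycles at ~43 000 SNPs)
  are a long-running configuration, documented but not exercised in tests.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_sires = 50, n_dams = 150, litter_size = 6, n_snps = 2000,
                  seed = 1)
study <- simulate_taint_study(cfg, targets = c(pairs = 190,
                                               unpaired_cases = 50,
                                               unpaired_controls = 70))
phe <- precorrect_phenotypes(study$phenotypes, study$design)
sk <- phe[phe$trait == "skatole", ]
y <- setNames(sk$precorrected, sk$animal_id)
geno <- impute_missing(study$genotypes)
folds <- make_cv_folds(study$design, k = 5, seed = 2)
cv <- cv_evaluate(y, geno, folds,
                  methods = c("GBLUP", "BayesB", "BayesSSVS"),
                  schedule = chain_schedule(1000, 250, 2), seed = 3)
print(cv)
```
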