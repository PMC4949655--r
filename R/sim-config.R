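#' Trait architecture for the phenotype simulator
#'
#' Describes the additive genetic architecture of one log-scale trait: how many
#' causal loci (QTL) it has, whether a single major QTL takes a fixed share of
#' the genic variance, the heritability, and the trait mean on the log scale.
#'
#' @param n_qtl number of causal loci (columns of the genotype matrix).
#' @param h2 narrow-sense heritability of the log-scale trait, in (0, 1).
#' @param major_qtl_fraction share of the genic variance assigned to the first
#'   (major) QTL, in `[0, 1)`. 0 means a purely polygenic trait.
#' @param qtl_variance_fractions optional explicit per-QTL genic-variance
#'   shares (a simplex of length `n_qtl`); overrides `major_qtl_fraction`.
#' @param log_mean mean of the trait on the natural-log scale. The default for
#'   a skatole-like trait is `log(0.3)` so that the 0.3 ug/g abattoir threshold
#'   splits the population roughly in half.
#' @return an object of class `trait_arch`.
#' @export
trait_arch <- function(n_qtl, h2, major_qtl_fraction = 0,
                       qtl_variance_fractions = NULL, log_mean = 0) {
  stopifnot(n_qtl >= 0, h2 > 0, h2 < 1,
            major_qtl_fraction >= 0, major_qtl_fraction < 1)
  if (!is.null(qtl_variance_fractions)) {
    if (length(qtl_variance_fractions) != n_qtl)
      stop("qtl_variance_fractions must have length n_qtl")
    if (abs(sum(qtl_variance_fractions) - 1) > 1e-8)
      stop("qtl_variance_fractions must sum to 1")
  }
  if (major_qtl_fraction > 0 && n_qtl == 0)
    stop("major_qtl_fraction > 0 requires n_qtl >= 1")
  structure(list(n_qtl = n_qtl, h2 = h2,
                 major_qtl_fraction = major_qtl_fraction,
                 qtl_variance_fractions = qtl_variance_fractions,
                 log_mean = log_mean),
            class = "trait_arch")
}

#' Configuration of the synthetic discordant sib-pair study
#'
#' Collects every knob of the generator. Defaults reproduce the structure of
#' the Danish Landrace design the package emulates: 128 sires, 441 dams (one
#' litter each), 14 farms, slaughter age ~ Normal(161.3, 1.36) days, a 0.3
#' ug/g skatole selection threshold, a skatole-like trait carrying one QTL
#' with 77% of the genic variance and a polygenic androstenone-like trait
#' (h2 = 0.3 each), genetic correlation 0.41 between the traits.
#'
#' @param n_sires,n_dams numbers of founder sires and dams; dams are nested
#'   within sires (each dam mated to one sire, one litter per dam).
#' @param litter_size full sibs per litter (>= 2 for paired selection).
#' @param n_farms farms; litters are assigned whole to farms.
#' @param n_snps SNPs on the simulated panel.
#' @param maf_range founder allele frequencies drawn uniformly on this range.
#' @param skatole,androstenone [trait_arch()] objects for the two traits.
#' @param genetic_correlation correlation of paired QTL effects across traits.
#' @param selection_threshold raw skatole threshold (ug/g) for case status.
#' @param age_mean,age_sd slaughter-age distribution (days), truncated at 0.
#' @param age_slope fixed regression of log phenotype on age (per day).
#' @param farm_sd SD of farm effects on the log scale.
#' @param phen_var total phenotypic variance target on the log scale
#'   (genetic + residual; farm/age effects come on top).
#' @param seed master seed; all stages derive their own sub-seeds from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_sires = 128, n_dams = 441, litter_size = 14,
                       n_farms = 14, n_snps = 1000, maf_range = c(0.05, 0.5),
                       skatole = trait_arch(21, 0.3, major_qtl_fraction = 0.77,
                                            log_mean = log(0.3)),
                       androstenone = trait_arch(300, 0.3, log_mean = 0),
                       genetic_correlation = 0.41,
                       selection_threshold = 0.3,
                       age_mean = 161.3, age_sd = 1.36, age_slope = 0.02,
                       farm_sd = 0.2, phen_var = 0.48, seed = 1L) {
  stopifnot(n_sires >= 1, n_dams >= n_sires, litter_size >= 1, n_farms >= 1,
            n_snps >= 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            abs(genetic_correlation) <= 1, age_mean > 0, phen_var > 0)
  if (selection_threshold <= 0) stop("selection_threshold must be > 0")
  if (!inherits(skatole, "trait_arch") || !inherits(androstenone, "trait_arch"))
    stop("skatole and androstenone must be trait_arch objects")
  structure(list(n_sires = n_sires, n_dams = n_dams, litter_size = litter_size,
                 n_farms = n_farms, n_snps = n_snps, maf_range = maf_range,
                 traits = list(skatole = skatole, androstenone = androstenone),
                 genetic_correlation = genetic_correlation,
                 selection_threshold = selection_threshold,
                 age_mean = age_mean, age_sd = age_sd, age_slope = age_slope,
                 farm_sd = farm_sd, phen_var = phen_var,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' MCMC chain schedule
#'
#' The default matches the study's schedule: 50 000 burn-in cycles, 20 000
#' retained realisations separated by 50 cycles, i.e. 1 050 000 cycles total.
#' Tests and worked examples use much shorter schedules.
#'
#' @param burnin discarded initial cycles.
#' @param n_samples retained realisations.
#' @param thin cycles between consecutive retained realisations.
#' @return an object of class `chain_schedule`.
#' @export
chain_schedule <- function(burnin = 50000, n_samples = 20000, thin = 50) {
  stopifnot(burnin >= 0, n_samples >= 1, thin >= 1)
  structure(list(burnin = as.integer(burnin), n_samples = as.integer(n_samples),
                 thin = as.integer(thin)),
            class = "chain_schedule")
}

#' Total Gibbs cycles implied by a schedule
#'
#' `burnin + n_samples * thin`; the default schedule gives 1 050 000.
#'
#' @param schedule a [chain_schedule()].
#' @return integer-valued cycle count.
#' @export
chain_total_cycles <- function(schedule) {
  stopifnot(inherits(schedule, "chain_schedule"))
  schedule$burnin + as.numeric(schedule$n_samples) * schedule$thin
}
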