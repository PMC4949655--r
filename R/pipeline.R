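#' Assemble a full-run configuration
#'
#' Single structured configuration for [run_taint_study()]: simulation
#' settings, QC thresholds, model list, chain schedule and CV settings, plus
#' one master seed from which every stochastic stage derives its own.
#'
#' @param sim a [sim_config()] (the synthetic-data stage; required for
#'   simulated runs).
#' @param targets case-control design targets (see
#'   [apply_case_control_selection()]); `NULL` keeps the raw rule's output.
#' @param qc list of QC thresholds: `maf_min`, `callrate_min`, `hwe_fdr`,
#'   `het_max`, `rel_max`.
#' @param methods evaluation methods for the CV stage.
#' @param schedule a [chain_schedule()].
#' @param k CV folds.
#' @param trait which trait to evaluate (`"skatole"` or `"androstenone"`).
#' @param seed master seed (required: the pipeline has stochastic stages).
#' @param out_dir output directory (`NULL`: nothing is written).
#' @return an object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), targets = c(pairs = 421,
                                                       unpaired_cases = 40,
                                                       unpaired_controls = 56),
                       qc = list(maf_min = 0.01, callrate_min = 0.95,
                                 hwe_fdr = 0.01, het_max = 0.45,
                                 rel_max = 0.95),
                       methods = c("GBLUP", "BayesA", "BayesB", "BayesC",
                                   "BayesSSVS", "BayesLasso"),
                       schedule = chain_schedule(), k = 5,
                       trait = "skatole", seed = NULL, out_dir = NULL) {
  structure(list(sim = sim, targets = targets, qc = qc, methods = methods,
                 schedule = schedule, k = k, trait = trait, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Returns an ordered list of diagnostics; entries of severity `"error"`
#' block [run_taint_study()].
#'
#' @param config a [run_config()].
#' @return data.frame with columns `severity` and `message` (zero rows when
#'   clean).
#' @export
validate_config <- function(config) {
  out <- data.frame(severity = character(0), message = character(0),
                    stringsAsFactors = FALSE)
  add <- function(sev, msg) rbind(out, data.frame(severity = sev, message = msg,
                                                  stringsAsFactors = FALSE))
  if (!inherits(config, "run_config")) return(add("error", "not a run_config"))
  if (is.null(config$seed))
    out <- add("error", "seed missing but stochastic stages are configured")
  if (!inherits(config$sim, "sim_config"))
    out <- add("error", "sim must be a sim_config")
  if (!inherits(config$schedule, "chain_schedule"))
    out <- add("error", "schedule must be a chain_schedule")
  if (config$k < 2) out <- add("error", "k must be >= 2")
  if (!is.null(config$targets)) {
    tg <- as.list(config$targets)
    units <- (tg$pairs %||% 0) + (tg$unpaired_cases %||% 0) +
      (tg$unpaired_controls %||% 0)
    if (config$k > units)
      out <- add("error", "k exceeds the number of pair/singleton units")
  }
  bad_pi <- function(p) !is.null(p) && (p <= 0 || p > 1)
  if (bad_pi(config$pi)) out <- add("error", "pi must lie in (0, 1]")
  if (!config$trait %in% c("skatole", "androstenone"))
    out <- add("error", "trait must be 'skatole' or 'androstenone'")
  qc <- config$qc
  for (nm in c("maf_min", "callrate_min", "hwe_fdr", "het_max", "rel_max"))
    if (is.null(qc[[nm]])) out <- add("error", paste0("qc$", nm, " missing"))
  out
}

#' Run the full synthetic study pipeline
#'
#' simulate -> select -> QC -> pre-correct -> GRM -> cross-validated
#' evaluation, writing every intermediate artifact plus a machine-readable
#' JSON manifest (stage, outputs, seed, wall time) when `out_dir` is set.
#' Rerunning with the same configuration reproduces all artifacts.
#'
#' @param config a [run_config()] that passes [validate_config()].
#' @return list with `design`, `genotypes` (post-QC), `phenotypes`
#'   (pre-corrected), `grm`, `cv` (a `cv_report`), `qc_reports`, and
#'   `manifest`.
#' @export
run_taint_study <- function(config) {
  diag <- validate_config(config)
  if (any(diag$severity == "error"))
    stop("invalid configuration:\n  ",
         paste(diag$message[diag$severity == "error"], collapse = "\n  "))
  out_dir <- config$out_dir
  manifest <- list()
  emit <- function(stage, t0, outputs = character(0)) {
    manifest[[stage]] <<- list(stage = stage, seed = config$seed,
                               wall_time_s = round(as.numeric(Sys.time()) - t0, 3),
                               outputs = outputs)
  }
  wr <- function(obj, name, writer) {
    if (is.null(out_dir)) return(character(0))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(out_dir, name)
    writer(obj, path)
    path
  }
  cfg <- config$sim
  cfg$seed <- derive_seed(config$seed, 0L)

  t0 <- as.numeric(Sys.time())
  study <- simulate_taint_study(cfg, targets = config$targets)
  emit("simulate", t0, c(wr(study$design, "design.tsv", write_pheno_tsv),
                         wr(study$phenotypes, "phenotypes_raw.tsv", write_pheno_tsv),
                         wr(study$genotypes, "genotypes.tsv", write_geno_tsv)))

  t0 <- as.numeric(Sys.time())
  qc <- config$qc
  s <- snp_qc(study$genotypes, qc$maf_min, qc$callrate_min, qc$hwe_fdr)
  i <- individual_qc(s$genotypes, callrate_min = qc$callrate_min,
                     het_max = qc$het_max, rel_max = qc$rel_max)
  geno <- impute_missing(i$genotypes)
  design <- study$design[study$design$animal_id %in% rownames(geno$codes), ]
  class(design) <- c("study_design", "data.frame")
  attr(design, "pairs") <- attr(study$design, "pairs")
  phe <- study$phenotypes[study$phenotypes$animal_id %in% design$animal_id, ]
  phe <- precorrect_phenotypes(phe, design)
  emit("qc", t0, wr(phe, "phenotypes_precorrected.tsv", write_pheno_tsv))

  t0 <- as.numeric(Sys.time())
  G <- compute_grm(geno)
  emit("grm", t0, wr(G, "grm.txt", write_grm))

  t0 <- as.numeric(Sys.time())
  tr <- phe[phe$trait == config$trait, ]
  y <- setNames(tr$precorrected, tr$animal_id)
  folds <- make_cv_folds(design, k = config$k,
                         seed = derive_seed(config$seed, 5L))
  cv <- cv_evaluate(y, geno, folds, methods = config$methods,
                    schedule = config$schedule, G = G,
                    h2_for_rstar = "fold_mean", seed = config$seed)
  emit("cv", t0, wr(data.frame(method = cv$methods, r = cv$mean_r, se = cv$se,
                               h2 = cv$h2, r_star = cv$r_star),
                    "cv_report.tsv", write_pheno_tsv))

  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(design = design, genotypes = geno, phenotypes = phe, grm = G, cv = cv,
       qc_reports = list(snp = s$report, animal = i$report),
       manifest = manifest)
}
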