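#' Pipeline configuration
#'
#' All tunables of [run_pipeline()] with the conventional defaults:
#' MAF > 0.05, call rate >= 0.90, `tau = 1.00`, `omega = 0.50`, blending
#' `alpha = 0.95`, 10-SNP sliding windows, 50 kb gene search.  The window
#' significance threshold is configurable (`threshold_pct`); the
#' conventional 10%-of-additive-variance rule is very strict on dense
#' maps, so the reporting default is 1% (both are just thresholds on the
#' same window table).
#'
#' @param sim a [sim_config()] describing the synthetic population.
#' @param traits trait column names (from the simulated phenotypes).
#' @param maf_min,call_rate_min,dup_concordance,mendel_max_rate QC
#'   thresholds (see [qc_filter()]).
#' @param tau,omega,alpha single-step parameters (see
#'   [build_H_inverse()], [blend_G()]).
#' @param n_weight_iters WssGBLUP weight iterations.
#' @param window_size,scheme,threshold_pct window-variance settings.
#' @param max_dist gene-search radius in bp.
#' @param n_genes genes simulated for the annotation stage.
#' @param reml_tol,reml_max_iter REML convergence settings.
#' @param corr_on basis of the evaluation-comparison correlation.
#' @param seed master seed (overrides `sim$seed`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            traits = c("trait1", "trait2"),
                            maf_min = 0.05, call_rate_min = 0.90,
                            dup_concordance = 0.99, mendel_max_rate = 0,
                            tau = 1.00, omega = 0.50, alpha = 0.95,
                            n_weight_iters = 2,
                            window_size = 10,
                            scheme = c("sliding", "nonoverlapping"),
                            threshold_pct = 1,
                            max_dist = 50000,
                            n_genes = 300,
                            reml_tol = 1e-6, reml_max_iter = 300,
                            corr_on = c("bv", "accuracy"),
                            seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(
    sim = sim, traits = traits,
    maf_min = maf_min, call_rate_min = call_rate_min,
    dup_concordance = dup_concordance, mendel_max_rate = mendel_max_rate,
    tau = tau, omega = omega, alpha = alpha,
    n_weight_iters = n_weight_iters,
    window_size = window_size, scheme = match.arg(scheme),
    threshold_pct = threshold_pct,
    max_dist = max_dist, n_genes = n_genes,
    reml_tol = reml_tol, reml_max_iter = reml_max_iter,
    corr_on = match.arg(corr_on)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `sim`
#' key holds [sim_config()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  y$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, y)
}

#' Run the full single-step evaluation pipeline
#'
#' Stages: `simulate` (synthetic pedigree, genotypes, phenotypes, gene
#' table, plus true-breeding-value sidecars), `qc`, `reml` (bivariate
#' A-based variance components), `predict` (ABLUP evaluation), `gwas`
#' (weighted single-step GBLUP, SNP effects, window variances,
#' significant SNPs), `evaluate` (EBV vs GEBV comparison), `annotate`
#' (candidate genes and pleiotropy).  Every stage writes tab-separated
#' outputs into `out_dir` and records itself in `manifest.json`
#' (config snapshot, output checksums, package version).
#'
#' A re-run skips stages whose outputs are complete; deleting a stage's
#' outputs re-computes that stage and everything downstream of it.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param force recompute everything regardless of existing outputs.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results
#'   (`pedigree`, `qc`, `vc`, `ebv`, `wss`, `windows`, `comparison`,
#'   `hits`, ...).
#' @export
run_pipeline <- function(config, out_dir, force = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, ...)
  say <- function(...) if (!quiet) message("[pipeline] ", ...)
  stage_files <- list(
    simulate = c("pedigree.tsv", "genotypes.txt", "snp_map.tsv",
                 "phenotypes.tsv", "genes.tsv", "truth_tbv.tsv",
                 "truth_qtl.tsv"),
    qc = c("qc_genotypes.txt", "qc_snp_map.tsv", "qc_stages.tsv",
           "qc_snp_stats.tsv"),
    reml = c("variance_components.tsv", "vc.json"),
    predict = "ebv.tsv",
    gwas = c("gebv.tsv", "snp_effects.tsv", "windows.tsv",
             "significant_windows.tsv", "significant_snps.tsv"),
    evaluate = "comparison.tsv",
    annotate = c("candidate_genes.tsv", "pleiotropy.tsv")
  )
  done <- function(stage) all(file.exists(pth(stage_files[[stage]])))
  # first stale stage: everything from there on is recomputed
  stages <- names(stage_files)
  stale <- if (force) 1L else {
    ix <- which(!vapply(stages, done, TRUE))
    if (length(ix)) min(ix) else length(stages) + 1L
  }
  run_stage <- function(k) k >= stale
  res <- list()

  # --- simulate ------------------------------------------------------------
  if (run_stage(1L)) {
    say("simulate: ", config$sim$n_founders, " founders, ",
        config$sim$n_generations, " generations, ",
        config$sim$n_snps, " SNPs")
    ped <- simulate_pedigree(config$sim)
    geno_all <- simulate_genotypes(ped, config$sim)
    sim <- simulate_phenotypes(ped, geno_all, config$sim)
    panel <- sample_genotype_panel(geno_all, ped, config$sim,
                                   ranking = stats::setNames(
                                     sim$truth$tbv[, 1], ped$animal))
    genes <- simulate_gene_table(geno_all$map, n_genes = config$n_genes,
                                 seed = config$sim$seed)
    write_pedigree(ped, pth("pedigree.tsv"))
    utils::write.table(
      tibble::tibble(animal = ped$animal, sex = ped$sex,
                     generation = ped$generation),
      pth("pedigree_meta.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write_genotypes(panel, pth("genotypes.txt"), dialect = "simple")
    write_snp_map(panel$map, pth("snp_map.tsv"))
    write_phenotypes(sim$phenotypes, pth("phenotypes.tsv"))
    write_gene_table(genes, pth("genes.tsv"))
    write_report(tibble::tibble(animal = rownames(sim$truth$tbv),
                                tbv1 = sim$truth$tbv[, 1],
                                tbv2 = sim$truth$tbv[, 2]),
                 pth("truth_tbv.tsv"))
    write_report(sim$truth$qtl, pth("truth_qtl.tsv"))
  } else {
    say("simulate: reusing existing outputs")
    ped <- read_pedigree(pth("pedigree.tsv"))
    meta <- utils::read.table(pth("pedigree_meta.tsv"), header = TRUE,
                              stringsAsFactors = FALSE)
    ped$sex <- meta$sex[match(ped$animal, meta$animal)]
    panel <- read_genotypes(pth("genotypes.txt"), dialect = "simple",
                            map = read_snp_map(pth("snp_map.tsv")))
    sim <- list(phenotypes = read_phenotypes(pth("phenotypes.tsv")))
    genes <- read_gene_table(pth("genes.tsv"))
  }
  res$pedigree <- ped
  res$phenotypes <- sim$phenotypes

  # --- qc ------------------------------------------------------------------
  if (run_stage(2L)) {
    qc <- qc_filter(panel, ped, maf_min = config$maf_min,
                    call_rate_min = config$call_rate_min,
                    dup_concordance = config$dup_concordance,
                    mendel_max_rate = config$mendel_max_rate)
    say("qc: animals ", qc$report$n_animals_in, " -> ",
        qc$report$n_animals_out, "; SNPs ", qc$report$n_snps_in, " -> ",
        qc$report$n_snps_out)
    write_genotypes(qc$genotypes, pth("qc_genotypes.txt"), dialect = "simple")
    write_snp_map(qc$genotypes$map, pth("qc_snp_map.tsv"))
    write_report(qc$report$stages, pth("qc_stages.tsv"))
    write_report(qc$report$snp_stats, pth("qc_snp_stats.tsv"))
    geno <- qc$genotypes
  } else {
    say("qc: reusing existing outputs")
    geno <- read_genotypes(pth("qc_genotypes.txt"), dialect = "simple",
                           map = read_snp_map(pth("qc_snp_map.tsv")))
  }
  res$genotypes <- geno

  # --- reml ----------------------------------------------------------------
  a_inv <- build_A_inverse(ped)
  if (run_stage(3L)) {
    say("reml: bivariate A-based variance components")
    fit <- reml_estimate(sim$phenotypes, config$traits, a_inv,
                         tol = config$reml_tol,
                         max_iter = config$reml_max_iter)
    write_report(tidy(fit), pth("variance_components.tsv"))
    jsonlite::write_json(list(G0 = fit$G0, R0 = fit$R0,
                              h2 = fit$h2, rg = fit$rg, rp = fit$rp,
                              converged = fit$converged),
                         pth("vc.json"), digits = NA)
    vc <- list(G0 = fit$G0, R0 = fit$R0)
    res$reml <- fit
  } else {
    say("reml: reusing existing outputs")
    v <- jsonlite::read_json(pth("vc.json"), simplifyVector = TRUE)
    vc <- list(G0 = matrix(unlist(v$G0), 2, 2),
               R0 = matrix(unlist(v$R0), 2, 2))
  }
  res$vc <- vc

  # --- predict (ABLUP) -----------------------------------------------------
  if (run_stage(4L)) {
    say("predict: ABLUP evaluation")
    ebv <- solve_mme(sim$phenotypes, config$traits, a_inv, vc,
                     pedigree = ped, method = "ablup")
    write_report(ebv$predictions, pth("ebv.tsv"))
  } else {
    say("predict: reusing existing outputs")
    ebv <- structure(list(predictions = read_report(pth("ebv.tsv")),
                          method = "ablup", traits = config$traits),
                     class = "blup_fit")
  }
  res$ebv <- ebv

  # --- gwas (WssGBLUP + windows) ------------------------------------------
  if (run_stage(5L)) {
    say("gwas: weighted single-step loop (", config$n_weight_iters,
        " weight iteration(s))")
    wss <- wssgblup(sim$phenotypes, config$traits, ped, geno, vc,
                    tau = config$tau, omega = config$omega,
                    alpha = config$alpha,
                    n_weight_iters = config$n_weight_iters)
    write_report(wss$evaluation$predictions, pth("gebv.tsv"))
    write_report(wss$effects, pth("snp_effects.tsv"))
    wins <- dplyr::bind_rows(lapply(config$traits, function(tr) {
      dplyr::mutate(
        tibble::as_tibble(wssgwas_windows(
          wss, tr, window_size = config$window_size,
          scheme = config$scheme)),
        trait = tr)
    }))
    write_report(wins, pth("windows.tsv"))
    sig <- wins[wins$variance_pct >= config$threshold_pct, ]
    write_report(sig, pth("significant_windows.tsv"))
    sig_snps <- dplyr::bind_rows(lapply(config$traits, function(tr) {
      s <- sig[sig$trait == tr, ]
      if (!nrow(s)) return(NULL)
      dplyr::mutate(window_snps(s, geno$map), trait = tr)
    }))
    if (is.null(sig_snps) || !nrow(sig_snps)) {
      sig_snps <- tibble::tibble(snp = character(), chr = character(),
                                 pos = numeric(), trait = character())
    }
    write_report(sig_snps, pth("significant_snps.tsv"))
    gebv <- wss$evaluation
    res$wss <- wss
    res$windows <- wins
  } else {
    say("gwas: reusing existing outputs")
    gebv <- structure(list(predictions = read_report(pth("gebv.tsv")),
                           method = "wssgblup", traits = config$traits),
                      class = "blup_fit")
    sig_snps <- read_report(pth("significant_snps.tsv"))
    res$windows <- read_report(pth("windows.tsv"))
  }
  res$gebv <- gebv
  res$significant_snps <- sig_snps

  # --- evaluate ------------------------------------------------------------
  if (run_stage(6L)) {
    say("evaluate: EBV vs GEBV comparison metrics")
    sex_tbl <- if ("sex" %in% names(ped)) {
      tibble::tibble(animal = ped$animal, sex = ped$sex)
    } else NULL
    comparison <- dplyr::bind_rows(lapply(config$traits, function(tr) {
      dplyr::mutate(
        compare_evaluations(ebv, gebv, tr,
                            animals = rownames(geno$calls),
                            sex = sex_tbl, corr_on = config$corr_on),
        trait = tr)
    }))
    write_report(comparison, pth("comparison.tsv"))
  } else {
    say("evaluate: reusing existing outputs")
    comparison <- read_report(pth("comparison.tsv"))
  }
  res$comparison <- comparison

  # --- annotate ------------------------------------------------------------
  if (run_stage(7L)) {
    say("annotate: genes within ", config$max_dist, " bp of significant SNPs")
    hits <- annotate_candidates(sig_snps, genes, max_dist = config$max_dist)
    write_report(hits, pth("candidate_genes.tsv"))
    write_report(pleiotropy_summary(hits), pth("pleiotropy.tsv"))
    res$hits <- hits
  } else {
    say("annotate: reusing existing outputs")
    res$hits <- read_report(pth("candidate_genes.tsv"))
  }

  # --- manifest ------------------------------------------------------------
  all_files <- unlist(stage_files, use.names = FALSE)
  sums <- tools::md5sum(pth(all_files[file.exists(pth(all_files))]))
  manifest <- list(
    package = "stepblup",
    version = as.character(utils::packageVersion("stepblup")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass_config(config),
    resumed_from_stage = stages[min(stale, length(stages))],
    outputs = as.list(stats::setNames(unname(sums), basename(names(sums))))
  )
  jsonlite::write_json(manifest, pth("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", out_dir)
  invisible(res)
}

unclass_config <- function(config) {
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  cfg
}
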