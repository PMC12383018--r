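small_cfg <- function(...) {
  args <- list(n_founders = 20, n_generations = 3, offspring_per_mating = 2,
               unknown_parent_rate = 0, n_snps = 60, n_chr = 3,
               n_qtl = 5, qtl_variance_fraction = 0.3,
               n_contemporary_groups = 4, prop_phenotyped = 0.8,
               prop_genotyped = 0.5, missing_rate = 0.02, seed = 11)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(sim_config, args)
}

test_that("pedigree generator: founders only, ordering, determinism", {
  cfg0 <- sim_config(n_founders = 10, n_generations = 0, seed = 1)
  ped0 <- simulate_pedigree(cfg0)
  expect_equal(nrow(ped0), 10)
  expect_true(all(is.na(ped0$sire) & is.na(ped0$dam)))

  cfg <- small_cfg()
  ped <- simulate_pedigree(cfg)
  pos <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  for (i in seq_len(nrow(ped))) { # exhaustive parents-precede-offspring scan
    for (p in c(ped$sire[i], ped$dam[i])) {
      if (!is.na(p)) expect_lt(pos[[p]], i)
    }
  }
  expect_identical(simulate_pedigree(cfg), simulate_pedigree(cfg))
  expect_error(sim_config(n_founders = 1), "founders")
})

test_that("gene dropping is Mendelian-consistent and deterministic", {
  cfg <- small_cfg()
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  expect_identical(geno$calls, simulate_genotypes(ped, cfg)$calls)
  expect_equal(rownames(geno$calls), ped$animal)
  expect_false(anyNA(geno$calls))
  # exhaustive opposing-homozygote scan over all known parent-offspring pairs
  idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  for (i in seq_len(nrow(ped))) {
    for (p in c(ped$sire[i], ped$dam[i])) {
      if (is.na(p)) next
      expect_equal(sum(abs(geno$calls[i, ] - geno$calls[idx[[p]], ]) == 2), 0)
    }
  }
  # fixation: both parents 2 => offspring 2
  both2 <- which(!is.na(ped$sire) & !is.na(ped$dam))
  for (i in both2) {
    fix <- geno$calls[idx[[ped$sire[i]]], ] == 2 & geno$calls[idx[[ped$dam[i]]], ] == 2
    expect_true(all(geno$calls[i, fix] == 2))
  }
})

test_that("founder allele frequencies track the configured range", {
  cfg <- sim_config(n_founders = 500, n_generations = 0, n_snps = 5000,
                    founder_maf_range = c(0.3, 0.3), seed = 5)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  expect_lt(abs(mean(allele_freq(geno)) - 0.3), 0.02)
})

test_that("phenotypes: no-noise limit, null architecture, record subset", {
  cfg <- small_cfg(h2 = c(0.999, 0.999), cg_sd = 0)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  sim <- simulate_phenotypes(ped, geno, cfg)
  ph <- sim$phenotypes
  tbv <- sim$truth$tbv[ph$animal, ]
  resid_sd <- sqrt((1 - cfg$h2) * cfg$trait_sds^2)
  expect_lt(max(abs(ph$trait1 - cfg$trait_means[1] - tbv[, 1])), 6 * resid_sd[1])
  expect_lt(max(abs(ph$trait2 - cfg$trait_means[2] - tbv[, 2])), 6 * resid_sd[2])

  cfg0 <- small_cfg(qtl_variance_fraction = 0)
  sim0 <- simulate_phenotypes(ped, simulate_genotypes(ped, cfg0), cfg0)
  expect_equal(nrow(sim0$truth$qtl), 0)

  expect_equal(nrow(ph), round(cfg$prop_phenotyped * nrow(ped)))
  expect_identical(sim$phenotypes,
                   simulate_phenotypes(ped, geno, cfg)$phenotypes)
})

test_that("realized TBV variance and cross-trait correlation hit their targets", {
  # moderate-size replicate study: Var(TBV) within 3 MC SE of sigma_a^2
  reps <- 12
  v1 <- v2 <- rg <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_founders = 120, n_generations = 2,
                      offspring_per_mating = 3, n_snps = 400, n_qtl = 20,
                      qtl_variance_fraction = 0.3, unknown_parent_rate = 0,
                      prop_phenotyped = 1, seed = 100 + r)
    ped <- simulate_pedigree(cfg)
    sim <- simulate_phenotypes(ped, simulate_genotypes(ped, cfg), cfg)
    v1[r] <- stats::var(sim$truth$tbv[, 1])
    v2[r] <- stats::var(sim$truth$tbv[, 2])
    rg[r] <- stats::cor(sim$truth$tbv[, 1], sim$truth$tbv[, 2])
  }
  G0 <- stepblup:::sim_G0(sim_config())
  expect_lt(abs(mean(v1) - G0[1, 1]), 3 * stats::sd(v1) / sqrt(reps))
  expect_lt(abs(mean(v2) - G0[2, 2]), 3 * stats::sd(v2) / sqrt(reps))
  expect_lt(abs(mean(rg) - 0.495), 3 * stats::sd(rg) / sqrt(reps))
})

test_that("genotype panel sampling subsets, injects missingness, stratifies", {
  cfg <- small_cfg()
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  panel <- sample_genotype_panel(geno, ped, cfg)
  expect_equal(nrow(panel$calls), round(cfg$prop_genotyped * nrow(ped)))
  expect_gt(sum(is.na(panel$calls)), 0)
  expect_true(all(rownames(panel$calls) %in% ped$animal))

  cfg_s <- small_cfg(genotyped_sampling = "ebv_stratified")
  rk <- stats::setNames(stats::rnorm(nrow(ped)), ped$animal)
  panel_s <- sample_genotype_panel(geno, ped, cfg_s, ranking = rk)
  expect_equal(nrow(panel_s$calls), round(cfg$prop_genotyped * nrow(ped)))
})
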