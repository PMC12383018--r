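# small GBLUP instance: more SNPs than animals so raw G is invertible
gblup_instance <- function(n = 30, m = 120, seed = 10) {
  set.seed(seed - 1)
  p_true <- stats::runif(m, 0.15, 0.5)
  geno <- hwe_geno(n = n, m = m, p = p_true, seed = seed)
  ids <- rownames(geno$calls)
  set.seed(seed + 1)
  ph <- tibble::tibble(animal = ids, cg = "g1", y = rnorm(n, 4))
  w <- g_weights(p_true)
  Z <- center_genotypes(geno, w$p)
  G <- build_G(geno, w)
  Ginv <- stepblup:::sym_inverse(G)
  dimnames(Ginv) <- list(ids, ids)
  fit <- solve_mme(ph, "y", Ginv, list(G0 = matrix(0.6, 1, 1),
                                       R0 = matrix(0.4, 1, 1)))
  gebv <- stats::setNames(fit$predictions$bv, fit$predictions$animal)[ids]
  list(geno = geno, ph = ph, w = w, Z = Z, G = G, Ginv = Ginv, gebv = gebv)
}

test_that("back-solved SNP effects reproduce the GEBVs when G is unblended", {
  gi <- gblup_instance()
  eff <- backsolve_snp_effects(gi$gebv, gi$Z, gi$w, gi$Ginv)
  expect_lt(max(abs(drop(gi$Z %*% eff$effect) - gi$gebv)), 1e-8)
  # zero GEBVs give zero effects
  eff0 <- backsolve_snp_effects(rep(0, length(gi$gebv)), gi$Z, gi$w, gi$Ginv)
  expect_equal(eff0$effect, rep(0, ncol(gi$Z)))
  expect_error(backsolve_snp_effects(gi$gebv[-1], gi$Z, gi$w, gi$Ginv),
               "dimension")
})

test_that("scaling all weights by a constant leaves the back-solve unchanged", {
  gi <- gblup_instance(seed = 12)
  w1 <- g_weights(gi$w$p, rep(1, ncol(gi$Z)), normalize = FALSE)
  w3 <- g_weights(gi$w$p, rep(3, ncol(gi$Z)), normalize = FALSE)
  G3 <- build_G(gi$geno, w3)
  eff1 <- backsolve_snp_effects(gi$gebv, gi$Z, w1,
                                stepblup:::sym_inverse(build_G(gi$geno, w1)))
  eff3 <- backsolve_snp_effects(gi$gebv, gi$Z, w3,
                                stepblup:::sym_inverse(G3))
  expect_equal(eff3$effect, eff1$effect, tolerance = 1e-10)
})

test_that("weight updates follow s^2 2p(1-p) and renormalise to m", {
  p <- c(0.2, 0.3, 0.5, 0.4)
  w <- g_weights(p)
  # equal effects, equal frequencies -> all weights 1
  weq <- update_weights(tibble::tibble(effect = rep(2, 3)),
                        g_weights(rep(0.25, 3)))
  expect_equal(weq$d, rep(1, 3))
  # sum-to-m contract on random inputs
  set.seed(8)
  for (r in 1:5) {
    eff <- tibble::tibble(effect = rnorm(4))
    w2 <- update_weights(eff, w)
    expect_equal(sum(w2$d), 4)
    expect_equal(w2$d / w2$d[1],
                 (eff$effect^2 * 2 * p * (1 - p)) /
                   (eff$effect[1]^2 * 2 * p[1] * (1 - p[1])))
  }
  expect_warning(wz <- update_weights(tibble::tibble(effect = rep(0, 4)), w),
                 "zero")
  expect_equal(wz$d, rep(1, 4))
})

test_that("a whole-chromosome window recovers Var(gebv)/sigma_a2", {
  gi <- gblup_instance(n = 25, m = 40, seed = 14)
  eff <- backsolve_snp_effects(gi$gebv, gi$Z, gi$w, gi$Ginv)
  sa2 <- 0.6
  expect_warning(
    wr <- window_variance(eff, gi$Z, gi$geno$map, sa2, window_size = 100),
    "whole-chromosome")
  expect_equal(nrow(wr), 1)
  expect_equal(wr$variance_pct, 100 * stats::var(gi$gebv) / sa2,
               tolerance = 1e-8)
  # the 1/phi scaling cancels: the literal unscaled formula gives the same
  s_lit <- gi$w$d * drop(crossprod(gi$Z, gi$Ginv %*% gi$gebv))
  wv_lit <- 100 * stats::var(drop(gi$Z %*% s_lit)) /
    (sa2 * gi$w$phi^2) # unscaled effects are phi times larger
  expect_equal(wr$variance_pct, wv_lit, tolerance = 1e-8)

  # zero effects -> all windows 0
  eff0 <- dplyr::mutate(eff, effect = 0)
  wr0 <- window_variance(eff0, gi$Z, gi$geno$map, sa2, window_size = 5)
  expect_true(all(wr0$variance_pct == 0))
})

test_that("window schemes tile or slide within chromosomes only", {
  gi <- gblup_instance(n = 20, m = 60, seed = 16)
  map <- gi$geno$map
  map$chr <- rep(c("C1", "C2", "C3"), each = 20)
  eff <- backsolve_snp_effects(gi$gebv, gi$Z, gi$w, gi$Ginv)
  sl <- window_variance(eff, gi$Z, map, 1, window_size = 5, scheme = "sliding")
  no <- window_variance(eff, gi$Z, map, 1, window_size = 5,
                        scheme = "nonoverlapping")
  expect_equal(nrow(sl), 3 * (20 - 5 + 1))
  expect_equal(nrow(no), 3 * 4)
  expect_true(all(sl$variance_pct >= 0))
  # windows never span chromosomes
  for (w in list(sl, no)) {
    expect_true(all(map$chr[w$start_idx] == map$chr[w$end_idx]))
  }
  # significance filter: inclusive threshold, order preserved
  sig <- significant_windows(sl, threshold_pct = 10)
  expect_true(all(sig$variance_pct >= 10))
  expect_equal(significant_windows(sl, 0)$variance_pct, sl$variance_pct)
  thr <- sort(sl$variance_pct, decreasing = TRUE)[3]
  sig3 <- significant_windows(sl, thr)
  expect_equal(nrow(sig3), 3)
  expect_false(is.unsorted(match(sig3$start_idx, sl$start_idx)))
  snps <- window_snps(sig3, map)
  expect_true(all(snps$snp %in% map$snp))
})

test_that("the weighted single-step loop is stable and finds a planted QTL", {
  cfg <- sim_config(n_founders = 60, n_generations = 2,
                    offspring_per_mating = 2, unknown_parent_rate = 0,
                    n_snps = 300, n_chr = 3, n_qtl = 1,
                    qtl_variance_fraction = 0.4,
                    h2 = c(0.5, 0.1), rg = 0.5, re = 0.3,
                    trait_means = c(0, 0), trait_sds = c(1, 1),
                    prop_phenotyped = 1, prop_genotyped = 0.6,
                    missing_rate = 0, seed = 33)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  sim <- simulate_phenotypes(ped, geno, cfg)
  panel <- sample_genotype_panel(geno, ped, cfg)
  qc <- qc_filter(panel, ped, dup_min_shared = 50)
  vc <- list(G0 = diag(c(0.5, 0.1)), R0 = diag(c(0.5, 0.9)))
  wfit <- wssgblup(sim$phenotypes, c("trait1", "trait2"), ped,
                   qc$genotypes, vc, n_weight_iters = 2)
  expect_equal(sum(wfit$weights$d), ncol(wfit$Z))
  expect_true(all(is.finite(wfit$evaluation$predictions$bv)))
  expect_gt(wfit$history[[2]]$cor_with_previous, 0.9)
  wr <- wssgwas_windows(wfit, "trait1", window_size = 10)
  expect_true(all(is.finite(wr$variance_pct)))
  # the planted QTL (40% of additive variance) should rank highly
  qtl_snp <- sim$truth$qtl$snp[1]
  if (qtl_snp %in% wfit$map$snp) {
    qtl_ix <- match(qtl_snp, wfit$map$snp)
    hit <- wr$start_idx <= qtl_ix & wr$end_idx >= qtl_ix
    top10 <- rank(-wr$variance_pct) <= 10
    expect_true(any(hit & top10))
  }
})
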