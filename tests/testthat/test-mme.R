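uni_vc <- function(sa, se) list(G0 = matrix(sa, 1, 1), R0 = matrix(se, 1, 1))

test_that("unphenotyped progeny-less animals get the parent average", {
  ped <- as_pedigree(tibble::tibble(
    animal = c("s", "d", "u", "v", "o"),
    sire = c(NA, NA, NA, NA, "s"),
    dam = c(NA, NA, NA, NA, "d")))
  set.seed(2)
  ph <- tibble::tibble(animal = c("s", "d", "u", "v"),
                       cg = "g1", y = rnorm(4, 10))
  fit <- solve_mme(ph, "y", build_A_inverse(ped), uni_vc(1, 1),
                   pedigree = ped)
  bv <- stats::setNames(fit$predictions$bv, fit$predictions$animal)
  expect_equal(bv[["o"]], (bv[["s"]] + bv[["d"]]) / 2, tolerance = 1e-8)
})

test_that("founders-only BLUP matches a direct GLS oracle", {
  n <- 20
  ids <- sprintf("A%02d", 1:n)
  ped <- as_pedigree(tibble::tibble(animal = ids, sire = NA, dam = NA))
  set.seed(3)
  ph <- tibble::tibble(animal = ids,
                       cg = rep(c("g1", "g2"), each = n / 2),
                       y = rnorm(n, 5))
  sa <- 0.7; se <- 1.3
  fit <- solve_mme(ph, "y", build_A_inverse(ped), uni_vc(sa, se),
                   pedigree = ped)
  # oracle: V = sa ZZ' + se I; beta = (X'V^-1X)^-1 X'V^-1 y; u = sa Z'V^-1 (y - X beta)
  X <- stats::model.matrix(~ 0 + cg, data = ph)
  V <- sa * diag(n) + se * diag(n)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% ph$y)
  u <- sa * Vi %*% (ph$y - X %*% beta)
  bv <- fit$predictions$bv[match(ids, fit$predictions$animal)]
  expect_equal(bv, drop(u), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("accuracy limits: 0 for unlinked unphenotyped, near 1 as h2 -> 1", {
  ids <- c(sprintf("A%02d", 1:20), "lone")
  ped <- as_pedigree(tibble::tibble(animal = ids, sire = NA, dam = NA))
  set.seed(11)
  ph <- tibble::tibble(animal = ids[1:20], cg = "g1", y = rnorm(20))
  fit_lo <- solve_mme(ph, "y", build_A_inverse(ped), uni_vc(0.5, 0.5),
                      pedigree = ped)
  acc <- stats::setNames(fit_lo$predictions$accuracy,
                         fit_lo$predictions$animal)
  expect_equal(acc[["lone"]], 0, tolerance = 1e-6)
  fit_hi <- solve_mme(ph, "y", build_A_inverse(ped), uni_vc(0.999, 0.001),
                      pedigree = ped)
  acc_hi <- stats::setNames(fit_hi$predictions$accuracy,
                            fit_hi$predictions$animal)
  expect_gt(acc_hi[["A01"]], 0.95)
  expect_true(all(fit_hi$predictions$pev >= 0))
})

test_that("predictions are invariant to a constant shift within a fixed-effect level", {
  ped <- random_pedigree(n = 40, n_founders = 8, seed = 21)
  set.seed(21)
  ph <- tibble::tibble(animal = sample(ped$animal, 25),
                       cg = sample(c("g1", "g2", "g3"), 25, replace = TRUE),
                       y = rnorm(25, 3))
  kinv <- build_A_inverse(ped)
  f1 <- solve_mme(ph, "y", kinv, uni_vc(0.4, 0.6), pedigree = ped)
  ph2 <- ph
  ph2$y[ph2$cg == "g2"] <- ph2$y[ph2$cg == "g2"] + 100
  f2 <- solve_mme(ph2, "y", kinv, uni_vc(0.4, 0.6), pedigree = ped)
  expect_equal(f2$predictions$bv, f1$predictions$bv, tolerance = 1e-8)
})

test_that("bivariate evaluation agrees with two univariate fits when traits are independent", {
  ped <- random_pedigree(n = 60, n_founders = 10, seed = 31)
  set.seed(31)
  ids <- sample(ped$animal, 40)
  ph <- tibble::tibble(animal = ids, cg = sample(c("g1", "g2"), 40, TRUE),
                       t1 = rnorm(40), t2 = rnorm(40, 5))
  kinv <- build_A_inverse(ped)
  vc2 <- list(G0 = diag(c(0.5, 0.8)), R0 = diag(c(0.5, 1.2)))
  fb <- solve_mme(ph, c("t1", "t2"), kinv, vc2, pedigree = ped)
  f1 <- solve_mme(ph, "t1", kinv, uni_vc(0.5, 0.5), pedigree = ped)
  b_bi <- fb$predictions[fb$predictions$trait == "t1", ]
  expect_equal(b_bi$bv, f1$predictions$bv, tolerance = 1e-8)
  expect_equal(b_bi$accuracy, f1$predictions$accuracy, tolerance = 1e-8)
})

test_that("GBLUP equals SNP-BLUP and the back-solve reproduces GEBVs", {
  set.seed(4)
  p_true <- stats::runif(200, 0.15, 0.5)
  geno <- hwe_geno(n = 50, m = 200, p = p_true, seed = 4)
  ids <- rownames(geno$calls)
  set.seed(5)
  ph <- tibble::tibble(animal = ids,
                       cg = sample(c("g1", "g2"), 50, TRUE),
                       y = rnorm(50, 2))
  chk <- gblup_equivalence_check(geno, ph, "y",
                                 vc = list(sigma2_a = 0.5, sigma2_e = 0.5),
                                 p = p_true, fixed = "cg")
  expect_lt(chk$max_abs_diff, 1e-6)
  expect_lt(chk$max_backsolve_diff, 1e-8)

  # infinite shrinkage: sigma2_a -> 0 sends all GEBVs to 0
  chk0 <- gblup_equivalence_check(geno, ph, "y",
                                  vc = list(sigma2_a = 1e-8, sigma2_e = 1),
                                  p = p_true, fixed = "cg")
  expect_lt(max(abs(chk0$gebv)), 1e-4)
})

test_that("duplicated genotype rows receive identical GEBVs", {
  set.seed(6)
  geno <- hwe_geno(n = 12, m = 60, seed = 6)
  calls <- rbind(geno$calls, D1 = geno$calls[1, ], D2 = geno$calls[1, ])
  gdup <- geno_from_matrix(calls)
  ids <- rownames(calls)
  G <- blend_G(build_G(gdup), diag(nrow(calls)), alpha = 0.9)
  Ginv <- stepblup:::sym_inverse(G)
  dimnames(Ginv) <- list(ids, ids)
  set.seed(7)
  ph <- tibble::tibble(animal = ids[2:12], cg = "g1", y = rnorm(11))
  fit <- solve_mme(ph, "y", Ginv, uni_vc(0.6, 0.4))
  bv <- stats::setNames(fit$predictions$bv, fit$predictions$animal)
  expect_equal(bv[["D1"]], bv[["D2"]], tolerance = 1e-10)
})
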