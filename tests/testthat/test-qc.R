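test_that("MAF is the folded mean allele count", {
  expect_equal(compute_maf(c(0, 0, 1, 1)), 0.25)
  expect_equal(compute_maf(c(2, 2, 2)), 0)
  expect_equal(compute_maf(c(2, 2, 0, 0)), 0.5)
  expect_equal(compute_maf(c(0, 1, NA, 2)), 0.5)
  m <- cbind(a = c(0, 0, 1, 1), b = c(2, 2, 2, 2))
  expect_equal(unname(compute_maf(m)), c(0.25, 0))
})

test_that("threshold semantics: MAF strict, call rate inclusive", {
  # MAF boundary, complete data: p = 0.05 exactly is NOT > 0.05
  set.seed(8)
  n <- 10
  clean <- sapply(rep(0.4, 4), function(p) stats::rbinom(n, 2, p))
  calls <- cbind(maf_eq = c(1L, rep(0L, 9)),   # p = 0.05 -> removed
                 maf_gt = c(1L, 1L, rep(0L, 8)), # p = 0.10 -> retained
                 clean)
  rownames(calls) <- sprintf("A%02d", 1:n)
  res <- qc_filter(geno_from_matrix(calls), pedigree = NULL,
                   dup_min_shared = 3)
  expect_false("S0001" %in% res$genotypes$map$snp)
  expect_true("S0002" %in% res$genotypes$map$snp)

  # call-rate boundary: 0.9 exactly is retained, below is removed;
  # NA pattern keeps every animal at >= 0.95 so the animal filter is inert
  set.seed(9)
  calls <- sapply(rep(0.4, 20), function(p) stats::rbinom(n, 2, p))
  rownames(calls) <- sprintf("A%02d", 1:n)
  calls[1:3, 1] <- NA   # call rate 0.7 -> removed
  calls[4, 2] <- NA     # call rate 0.9 -> retained
  res <- qc_filter(geno_from_matrix(calls), pedigree = NULL,
                   dup_min_shared = 3)
  expect_false("S0001" %in% res$genotypes$map$snp)
  expect_true("S0002" %in% res$genotypes$map$snp)
  expect_equal(res$report$n_animals_out, n)
})

test_that("constructed 10x12 fixture survives QC exactly as hand-enumerated", {
  fx <- qc_fixture()
  res <- qc_filter(fx$genotypes, fx$pedigree, dup_min_shared = 10)
  expect_equal(rownames(res$genotypes$calls), fx$expected_animals)
  expect_equal(res$genotypes$map$snp, fx$expected_snps)
  st <- dplyr::filter(res$report$stages, pass == 1)
  expect_equal(st$n_removed,
               c(1, 1, 1, 1, 1)) # A08, A10, S03, S01, S05 in stage order
  expect_equal(res$report$duplicates$dropped, "A10")
  # idempotence on the fixture
  res2 <- qc_filter(res$genotypes, fx$pedigree, dup_min_shared = 10)
  expect_equal(res2$genotypes$calls, res$genotypes$calls)
})

test_that("duplicate animals: later-listed member dropped, exactly one kept", {
  set.seed(1)
  base <- hwe_geno(n = 6, m = 120, seed = 1)
  calls <- rbind(base$calls, DUP = base$calls[3, ])
  geno <- geno_from_matrix(calls)
  res <- qc_filter(geno, pedigree = NULL)
  expect_false("DUP" %in% rownames(res$genotypes$calls))
  expect_true(rownames(base$calls)[3] %in% rownames(res$genotypes$calls))
  expect_equal(res$report$duplicates$dropped, "DUP")
})

test_that("opposing-homozygote SNPs are removed under zero tolerance", {
  set.seed(2)
  geno <- hwe_geno(n = 4, m = 60, seed = 2, p = rep(0.5, 60))
  rownames(geno$calls) <- c("sire", "dam", "kid", "other")
  # force a conflict at SNP 1: sire 0, kid 2
  geno$calls[, 1] <- c(0L, 1L, 2L, 1L)
  geno$calls[, 2] <- c(1L, 1L, 1L, 1L) # monomorphic -> MAF filter takes it
  ped <- as_pedigree(tibble::tibble(animal = c("sire", "dam", "kid", "other"),
                                    sire = c(NA, NA, "sire", NA),
                                    dam = c(NA, NA, "dam", NA)))
  res <- qc_filter(geno, ped, dup_min_shared = 5)
  expect_false(geno$map$snp[1] %in% res$genotypes$map$snp)
  expect_true(nrow(res$report$mendel) >= 1)
  expect_equal(res$report$mendel$snp[1], geno$map$snp[1])
})

test_that("qc_filter is idempotent and stage counts are consistent", {
  set.seed(3)
  geno <- hwe_geno(n = 30, m = 80, seed = 3)
  geno$calls[sample(length(geno$calls), 150)] <- NA
  geno$calls[, 5] <- 0L # monomorphic
  res1 <- qc_filter(geno, pedigree = NULL, dup_min_shared = 10)
  res2 <- qc_filter(res1$genotypes, pedigree = NULL, dup_min_shared = 10)
  expect_equal(res2$genotypes$calls, res1$genotypes$calls)
  expect_equal(res2$genotypes$map, res1$genotypes$map)
  expect_equal(sum(res2$report$stages$n_removed), 0)
  # removal counts sum to the set differences
  st <- res1$report$stages
  expect_equal(sum(st$n_removed[st$axis == "snp"]),
               res1$report$n_snps_in - res1$report$n_snps_out)
  expect_equal(sum(st$n_removed[st$axis == "animal"]),
               res1$report$n_animals_in - res1$report$n_animals_out)
  expect_error(qc_filter(res1$genotypes, maf_min = 0.6), "relax")
})
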