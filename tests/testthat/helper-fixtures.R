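# Shared fixtures: random pedigrees (with inbreeding loops) and small
# genotype sets, all built in code under explicit seeds.

random_pedigree <- function(n = 50, n_founders = 10, unknown_rate = 0.1,
                            seed = 1) {
  set.seed(seed)
  animal <- sprintf("P%03d", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in seq(n_founders + 1, length.out = max(0, n - n_founders))) {
    pars <- sample(i - 1, 2) # may be related -> inbreeding loops
    if (stats::runif(1) > unknown_rate) sire[i] <- animal[pars[1]]
    if (stats::runif(1) > unknown_rate) dam[i] <- animal[pars[2]]
  }
  as_pedigree(tibble::tibble(animal = animal, sire = sire, dam = dam))
}

# founders-only geno_set with HWE genotypes at given frequencies
hwe_geno <- function(n = 50, m = 100, p = NULL, seed = 1, chr = 1) {
  set.seed(seed)
  if (is.null(p)) p <- stats::runif(m, 0.1, 0.5)
  calls <- sapply(p, function(pp) stats::rbinom(n, 2, pp))
  rownames(calls) <- sprintf("P%03d", seq_len(n))
  map <- tibble::tibble(snp = sprintf("S%04d", seq_len(m)),
                        chr = paste0("C", rep_len(chr, m)),
                        pos = seq_len(m) * 1000L)
  geno_set(calls, map)
}

# Hand-enumerated 10-animal x 12-SNP QC fixture.  Expected outcome:
#   animal call rate: A08 dropped (2 NAs of 12 -> 0.833 < 0.9)
#   duplicates:       A10 dropped (identical to A09, later-listed)
#   SNP call rate:    S03 dropped (A05 missing -> 7/8 = 0.875 < 0.9)
#   MAF:              S01 dropped (monomorphic, MAF 0, not > 0.05)
#   Mendelian:        S05 dropped (A01 = 0 vs offspring A03 = 2)
# Survivors: animals A01-A07 + A09; SNPs S02, S04, S06..S12.
qc_fixture <- function() {
  rows <- list(
    A01 = c(0, 0, 1, 0, 0, 1, 1, 0, 1, 2, 1, 0),
    A02 = c(0, 1, 0, 1, 1, 1, 0, 1, 2, 1, 0, 1),
    A03 = c(0, 0, 1, 1, 2, 1, 1, 0, 1, 2, 2, 1),
    A04 = c(0, 0, 2, 1, 1, 0, 1, 2, 0, 1, 1, 2),
    A05 = c(0, 0, NA, 0, 0, 1, 2, 1, 1, 0, 2, 1),
    A06 = c(0, 0, 1, 2, 1, 2, 0, 1, 1, 1, 0, 1),
    A07 = c(0, 0, 0, 1, 2, 1, 1, 2, 2, 1, 1, 0),
    A08 = c(0, 0, 1, 1, 1, NA, NA, 1, 1, 1, 1, 1),
    A09 = c(0, 0, 1, 1, 1, 0, 1, 1, 0, 2, 1, 1),
    A10 = c(0, 0, 1, 1, 1, 0, 1, 1, 0, 2, 1, 1)
  )
  calls <- do.call(rbind, rows)
  map <- tibble::tibble(snp = sprintf("S%02d", 1:12), chr = "C1",
                        pos = seq_len(12) * 10000L)
  ped <- as_pedigree(tibble::tibble(
    animal = names(rows),
    sire = c(NA, NA, "A01", rep(NA, 7)),
    dam = rep(NA_character_, 10)))
  list(genotypes = geno_set(calls, map), pedigree = ped,
       expected_animals = c(paste0("A0", 1:7), "A09"),
       expected_snps = sprintf("S%02d", c(2, 4, 6:12)))
}

# tiny geno_set from an explicit matrix
geno_from_matrix <- function(calls, chr = "C1") {
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("P%03d", seq_len(nrow(calls)))
  }
  map <- tibble::tibble(snp = sprintf("S%04d", seq_len(ncol(calls))),
                        chr = rep_len(chr, ncol(calls)),
                        pos = seq_len(ncol(calls)) * 1000L)
  geno_set(calls, map)
}
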