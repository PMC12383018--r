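#' Minor allele frequency
#'
#' `p` is the mean allele count over non-missing calls divided by 2; the
#' MAF is `min(p, 1 - p)`.  For a matrix, one value per column (SNP).
#'
#' @param calls numeric vector of 0/1/2 calls (`NA` = missing) for one
#'   SNP, or an animals x SNPs matrix.
#' @return MAF value(s); `NaN` for an all-missing SNP (such a SNP always
#'   fails the call-rate filter instead).
#' @export
compute_maf <- function(calls) {
  if (is.matrix(calls)) {
    p <- colMeans(calls, na.rm = TRUE) / 2
  } else {
    p <- mean(calls, na.rm = TRUE) / 2
  }
  pmin(p, 1 - p)
}

#' Marker and animal quality control
#'
#' Applies, in order: animal call-rate filter, duplicate-animal removal,
#' SNP call-rate filter, MAF filter, Mendelian-conflict filter.  The MAF
#' rule is strict (`MAF > maf_min`), call rates are inclusive
#' (`>= call_rate_min`), mirroring the usual "> 5% MAF, >= 90% call rate"
#' phrasing.  Duplicates are animal pairs whose non-missing concordance
#' exceeds `dup_concordance` on at least `dup_min_shared` shared calls;
#' the later-listed animal is dropped.  Mendelian conflicts are opposing
#' homozygotes (0 vs 2) in genotyped parent--offspring pairs; a SNP is
#' removed when its conflict rate over checkable pairs exceeds
#' `mendel_max_rate` (default: any conflict).
#'
#' @param genotypes a [geno_set()].
#' @param pedigree a `pedigree`, used for parent--offspring pairs (may be
#'   `NULL` to skip the Mendelian filter).
#' @param maf_min MAF threshold (strict).
#' @param call_rate_min call-rate threshold (inclusive), applied to both
#'   animals and markers.
#' @param dup_concordance duplicate-pair concordance threshold (strict).
#' @param dup_min_shared minimum shared non-missing calls for the
#'   duplicate check.
#' @param mendel_max_rate maximum tolerated per-SNP conflict rate.
#' @return A list with `genotypes` (filtered [geno_set()]) and `report`
#'   (a `qc_report` list: stage-by-stage counts, per-SNP and per-animal
#'   statistics, duplicate pairs, Mendelian-conflict table).
#' @export
qc_filter <- function(genotypes, pedigree = NULL,
                      maf_min = 0.05, call_rate_min = 0.90,
                      dup_concordance = 0.99, dup_min_shared = 100,
                      mendel_max_rate = 0) {
  geno <- genotypes
  stopifnot(inherits(geno, "geno_set"), nrow(geno$calls) > 0)
  stages <- list()
  acr <- rowMeans(!is.na(geno$calls))
  dup_all <- NULL
  mendel_all <- NULL
  pass <- 0L
  # the 5-stage pass is repeated until a fixed point so that the filter
  # is idempotent (removing low-call-rate SNPs can change animal call
  # rates and vice versa); almost always 1-2 passes
  repeat {
    pass <- pass + 1L
    n_before <- sum(dim(geno$calls))
    note <- function(axis, stage, removed) {
      stages[[length(stages) + 1]] <<- tibble::tibble(
        pass = pass, axis = axis, stage = stage, n_removed = length(removed))
    }

    # 1. animal call rate
    cr_a <- rowMeans(!is.na(geno$calls))
    drop_a <- rownames(geno$calls)[cr_a < call_rate_min]
    note("animal", "call_rate", drop_a)
    geno <- geno_subset(geno, animals = setdiff(rownames(geno$calls), drop_a))

    # 2. duplicate animals (later-listed member dropped)
    dup <- find_duplicates(geno$calls, dup_concordance, dup_min_shared)
    if (is.null(dup_all)) dup_all <- dup
    note("animal", "duplicate", unique(dup$dropped))
    geno <- geno_subset(geno, animals = setdiff(rownames(geno$calls),
                                                unique(dup$dropped)))

    # 3. SNP call rate
    scr <- colMeans(!is.na(geno$calls))
    drop_cr <- geno$map$snp[scr < call_rate_min]
    note("snp", "call_rate", drop_cr)
    geno <- geno_subset(geno, snps = setdiff(geno$map$snp, drop_cr))

    # 4. MAF (strict >)
    maf <- compute_maf(geno$calls)
    drop_maf <- geno$map$snp[!(maf > maf_min)]
    note("snp", "maf", drop_maf)
    geno <- geno_subset(geno, snps = setdiff(geno$map$snp, drop_maf))

    # 5. Mendelian conflicts
    mendel <- mendel_conflicts(geno, pedigree)
    if (is.null(mendel_all)) mendel_all <- mendel
    if (nrow(mendel$per_snp)) {
      drop_m <- mendel$per_snp$snp[mendel$per_snp$rate > mendel_max_rate]
    } else {
      drop_m <- character(0)
    }
    note("snp", "mendel", drop_m)
    geno <- geno_subset(geno, snps = setdiff(geno$map$snp, drop_m))

    if (nrow(geno$calls) == 0 || ncol(geno$calls) == 0) {
      stop("QC removed everything; relax maf_min/call_rate_min")
    }
    if (sum(dim(geno$calls)) == n_before) break
  }
  dup <- dup_all
  mendel <- mendel_all
  report <- structure(list(
    n_animals_in = nrow(genotypes$calls), n_animals_out = nrow(geno$calls),
    n_snps_in = ncol(genotypes$calls), n_snps_out = ncol(geno$calls),
    stages = dplyr::bind_rows(stages),
    snp_stats = tibble::tibble(snp = genotypes$map$snp,
                               maf = compute_maf(genotypes$calls),
                               call_rate = colMeans(!is.na(genotypes$calls))),
    animal_call_rate = tibble::tibble(animal = rownames(genotypes$calls),
                                      call_rate = acr),
    duplicates = dup,
    mendel = mendel$conflicts
  ), class = "qc_report")
  list(genotypes = geno, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> animals ", x$n_animals_in, " -> ", x$n_animals_out,
      "; SNPs ", x$n_snps_in, " -> ", x$n_snps_out, "\n", sep = "")
  print(x$stages)
  invisible(x)
}

# pairwise concordance over shared non-missing calls, via indicator
# cross-products (one dgemm per genotype class instead of an n^2 loop)
find_duplicates <- function(calls, threshold, min_shared) {
  n <- nrow(calls)
  out <- tibble::tibble(kept = character(), dropped = character(),
                        concordance = numeric(), shared = integer())
  if (n < 2) return(out)
  ids <- rownames(calls)
  obs <- !is.na(calls)
  shared <- tcrossprod(obs * 1)
  matches <- matrix(0, n, n)
  for (g in 0:2) {
    ind <- (obs & calls == g) * 1
    ind[is.na(ind)] <- 0
    matches <- matches + tcrossprod(ind)
  }
  conc <- matches / pmax(shared, 1)
  hit <- which(upper.tri(conc) & shared >= min_shared & conc > threshold,
               arr.ind = TRUE)
  if (nrow(hit)) {
    # row index < col index in the upper triangle: keep the earlier-listed
    out <- tibble::tibble(kept = ids[hit[, 1]], dropped = ids[hit[, 2]],
                          concordance = conc[hit],
                          shared = as.integer(shared[hit]))
  }
  out
}

# opposing homozygotes over genotyped parent-offspring pairs
mendel_conflicts <- function(geno, pedigree) {
  empty <- list(
    conflicts = tibble::tibble(snp = character(), parent = character(),
                               offspring = character()),
    per_snp = tibble::tibble(snp = character(), n_conflicts = integer(),
                             n_pairs = integer(), rate = numeric())
  )
  if (is.null(pedigree)) return(empty)
  ped <- ensure_pedigree(pedigree)
  ids <- rownames(geno$calls)
  pairs <- dplyr::bind_rows(
    tibble::tibble(offspring = ped$animal, parent = ped$sire),
    tibble::tibble(offspring = ped$animal, parent = ped$dam)
  )
  pairs <- pairs[!is.na(pairs$parent) &
                   pairs$offspring %in% ids & pairs$parent %in% ids, ]
  if (!nrow(pairs)) return(empty)
  po <- geno$calls[pairs$offspring, , drop = FALSE]
  pp <- geno$calls[pairs$parent, , drop = FALSE]
  opp <- !is.na(po) & !is.na(pp) & abs(po - pp) == 2L
  checkable <- !is.na(po) & !is.na(pp)
  hits <- which(opp, arr.ind = TRUE)
  conflicts <- tibble::tibble(
    snp = geno$map$snp[hits[, 2]],
    parent = pairs$parent[hits[, 1]],
    offspring = pairs$offspring[hits[, 1]]
  )
  per_snp <- tibble::tibble(
    snp = geno$map$snp,
    n_conflicts = colSums(opp),
    n_pairs = colSums(checkable)
  )
  per_snp$rate <- ifelse(per_snp$n_pairs > 0,
                         per_snp$n_conflicts / per_snp$n_pairs, 0)
  list(conflicts = conflicts, per_snp = per_snp)
}
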