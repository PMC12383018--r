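#' Simulation configuration
#'
#' Bundles every tunable of the gene-dropping simulator with defaults that
#' emulate a smallholder buffalo breeding population: a three-generation
#' pedigree of about 2,850 animals with roughly 36% phenotyped and 16%
#' genotyped, two reproductive traits shaped like age at first calving
#' (months) and calving interval (days) with moderate/low heritability and
#' a positive genetic correlation.
#'
#' Heritabilities, correlations, trait means and SDs define the generative
#' genetic (`G0`) and residual (`R0`) covariance matrices:
#' \eqn{\sigma^2_{a,t} = h^2_t \sigma^2_{p,t}} and
#' \eqn{\sigma^2_{e,t} = (1 - h^2_t) \sigma^2_{p,t}}, with off-diagonals
#' from `rg` and `re`.  Both matrices must be positive definite.
#'
#' @param n_founders number of founder animals (>= 2, mixed sexes).
#' @param n_generations number of descendant generations (>= 0).
#' @param offspring_per_mating offspring per mating pair.
#' @param unknown_parent_rate fraction of non-founders recorded with
#'   unknown parents (recording gaps; such parents are treated as unknown
#'   everywhere, including gene dropping).
#' @param n_snps number of SNPs (spread uniformly over `n_chr` chromosomes).
#' @param n_chr number of chromosomes.
#' @param chr_length_bp chromosome length in bp for map positions.
#' @param founder_maf_range range (low, high) in (0, 0.5] from which each
#'   SNP's founder allele frequency is drawn.
#' @param n_qtl number of QTL among the SNPs (<= n_snps).
#' @param qtl_variance_fraction fraction of the additive variance carried
#'   by the QTL (the rest is polygenic), in [0, 1].
#' @param qtl_equal_variance if `TRUE`, each QTL is scaled to explain the
#'   same share (`qtl_variance_fraction / n_qtl`) of the additive
#'   variance; if `FALSE` (default) QTL effects are drawn i.i.d. normal,
#'   so realized shares vary around the mean.
#' @param h2 length-2 heritabilities in (0, 1).
#' @param rg genetic correlation in (-1, 1).
#' @param re residual correlation in (-1, 1).
#' @param trait_means,trait_sds length-2 phenotypic means and SDs.
#' @param n_contemporary_groups number of contemporary-group levels
#'   (herd-month-year analogue).
#' @param cg_sd SD of contemporary-group effects, as a fraction of each
#'   trait's phenotypic SD.
#' @param prop_phenotyped fraction of animals with records (drawn from
#'   non-founders when possible).
#' @param prop_genotyped fraction of animals on the genotyping panel.
#' @param genotyped_sampling `"random"` or `"ebv_stratified"` (stratified
#'   over high/medium/low true-breeding-value terciles, both sexes).
#' @param missing_rate missing-call rate injected into the panel.
#' @param seed integer seed; every generator derives its stream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 713,
                       n_generations = 3,
                       offspring_per_mating = 2,
                       unknown_parent_rate = 0.048,
                       n_snps = 3000,
                       n_chr = 10,
                       chr_length_bp = 1e8,
                       founder_maf_range = c(0.05, 0.5),
                       n_qtl = 30,
                       qtl_variance_fraction = 0.3,
                       qtl_equal_variance = FALSE,
                       h2 = c(0.36, 0.051),
                       rg = 0.495,
                       re = 0.513,
                       trait_means = c(46.31, 520.87),
                       trait_sds = c(10.01, 103.68),
                       n_contemporary_groups = 30,
                       cg_sd = 0.5,
                       prop_phenotyped = 0.364,
                       prop_genotyped = 0.163,
                       genotyped_sampling = c("random", "ebv_stratified"),
                       missing_rate = 0.01,
                       seed = 1L) {
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    offspring_per_mating = as.integer(offspring_per_mating),
    unknown_parent_rate = unknown_parent_rate,
    n_snps = as.integer(n_snps),
    n_chr = as.integer(n_chr),
    chr_length_bp = chr_length_bp,
    founder_maf_range = founder_maf_range,
    n_qtl = as.integer(n_qtl),
    qtl_variance_fraction = qtl_variance_fraction,
    qtl_equal_variance = isTRUE(qtl_equal_variance),
    h2 = h2, rg = rg, re = re,
    trait_means = trait_means, trait_sds = trait_sds,
    n_contemporary_groups = as.integer(n_contemporary_groups),
    cg_sd = cg_sd,
    prop_phenotyped = prop_phenotyped,
    prop_genotyped = prop_genotyped,
    genotyped_sampling = match.arg(genotyped_sampling),
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_founders < 2) stop("config error: need at least 2 founders (one of each sex)")
    if (n_generations < 0) stop("config error: n_generations must be >= 0")
    if (length(h2) != 2 || any(h2 <= 0) || any(h2 >= 1)) {
      stop("config error: h2 must be two values in (0, 1)")
    }
    if (abs(rg) >= 1 || abs(re) >= 1) stop("config error: |rg|, |re| must be < 1")
    if (any(trait_sds <= 0)) stop("config error: trait_sds must be positive")
    if (qtl_variance_fraction < 0 || qtl_variance_fraction > 1) {
      stop("config error: qtl_variance_fraction must be in [0, 1]")
    }
    if (n_qtl > n_snps) stop("config error: n_qtl exceeds n_snps")
    if (founder_maf_range[1] <= 0 || founder_maf_range[2] > 0.5 ||
        founder_maf_range[1] > founder_maf_range[2]) {
      stop("config error: founder_maf_range must lie in (0, 0.5]")
    }
    for (p in c(unknown_parent_rate, prop_phenotyped, prop_genotyped,
                missing_rate)) {
      if (p < 0 || p > 1) stop("config error: proportions must be in [0, 1]")
    }
  })
  g0 <- sim_G0(cfg)
  r0 <- sim_R0(cfg)
  if (min(eigen(g0, symmetric = TRUE, only.values = TRUE)$values) <= 0 ||
      min(eigen(r0, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("config error: implied genetic/residual covariance not positive definite")
  }
  invisible(cfg)
}

# generative covariance matrices implied by (h2, rg, re, trait_sds)
sim_G0 <- function(cfg) {
  sa <- sqrt(cfg$h2) * cfg$trait_sds
  matrix(c(sa[1]^2, cfg$rg * sa[1] * sa[2],
           cfg$rg * sa[1] * sa[2], sa[2]^2), 2, 2)
}

sim_R0 <- function(cfg) {
  se <- sqrt(1 - cfg$h2) * cfg$trait_sds
  matrix(c(se[1]^2, cfg$re * se[1] * se[2],
           cfg$re * se[1] * se[2], se[2]^2), 2, 2)
}

# run expr under a derived seed, restoring the caller's RNG state
with_sim_seed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  expr
}

#' Simulate a pedigree
#'
#' Discrete generations: founders (unknown parents, alternating sexes),
#' then for each generation matings between sires drawn with replacement
#' from the previous generation's males and dams drawn without replacement
#' from its females, each producing `offspring_per_mating` offspring of
#' random sex.  A fraction `unknown_parent_rate` of non-founders is
#' recorded with unknown parents (a recording gap: those parents are
#' unknown for all downstream purposes).
#'
#' @param config a [sim_config()].
#' @return A `pedigree` tibble `(animal, sire, dam, sex, generation)`,
#'   parents before offspring.
#' @export
simulate_pedigree <- function(config) {
  cfg <- config
  with_sim_seed(cfg$seed, 1L, {
    n0 <- cfg$n_founders
    sex <- rep(c("M", "F"), length.out = n0)
    animal <- sprintf("A%05d", seq_len(n0))
    sire <- rep(NA_character_, n0)
    dam <- rep(NA_character_, n0)
    gen <- rep(0L, n0)
    nxt <- n0 + 1L
    prev <- seq_len(n0)
    for (g in seq_len(cfg$n_generations)) {
      males <- prev[sex[prev] == "M"]
      females <- prev[sex[prev] == "F"]
      if (!length(males) || !length(females)) {
        stop("config error: a generation has no available ",
             if (!length(males)) "sires" else "dams")
      }
      n_matings <- length(females)
      s_idx <- sample(males, n_matings, replace = TRUE)
      d_idx <- sample(females, n_matings, replace = FALSE)
      new_idx <- integer(0)
      for (m in seq_len(n_matings)) {
        for (k in seq_len(cfg$offspring_per_mating)) {
          id <- sprintf("A%05d", nxt)
          animal <- c(animal, id)
          masked <- stats::runif(1) < cfg$unknown_parent_rate
          sire <- c(sire, if (masked) NA_character_ else animal[s_idx[m]])
          dam <- c(dam, if (masked) NA_character_ else animal[d_idx[m]])
          sex <- c(sex, sample(c("M", "F"), 1))
          gen <- c(gen, g)
          new_idx <- c(new_idx, nxt)
          nxt <- nxt + 1L
        }
      }
      prev <- new_idx
    }
    out <- tibble::tibble(animal = animal, sire = sire, dam = dam,
                          sex = sex, generation = gen)
    class(out) <- c("pedigree", class(out))
    out
  })
}

#' Simulate genotypes by gene dropping
#'
#' Draws one founder allele frequency per SNP from `founder_maf_range`,
#' founder genotypes under Hardy--Weinberg, and offspring genotypes by
#' Mendelian transmission (one allele from each parent, SNPs independent —
#' no linkage).  An unknown parent's allele is drawn from the founder
#' frequency.  All pedigree animals are genotyped here without missing
#' calls; [sample_genotype_panel()] extracts the study's genotyped subset
#' and injects missingness.
#'
#' @param pedigree a `pedigree` (parents before offspring).
#' @param config a [sim_config()].
#' @return A [geno_set()] covering every pedigree animal, plus attribute
#'   `founder_freq` (the per-SNP founder allele frequencies).
#' @export
simulate_genotypes <- function(pedigree, config) {
  cfg <- config
  ped <- ensure_pedigree(pedigree)
  pp <- ped_parents(ped)
  n <- nrow(ped)
  m <- cfg$n_snps
  with_sim_seed(cfg$seed, 2L, {
    p <- stats::runif(m, cfg$founder_maf_range[1], cfg$founder_maf_range[2])
    # two allele matrices, filled in pedigree order
    a1 <- matrix(0L, n, m)
    a2 <- matrix(0L, n, m)
    for (i in seq_len(n)) {
      a1[i, ] <- drop_gamete(pp$s[i], a1, a2, p)
      a2[i, ] <- drop_gamete(pp$d[i], a1, a2, p)
    }
    calls <- a1 + a2
    rownames(calls) <- ped$animal
    map <- sim_snp_map(cfg)
    out <- geno_set(calls, map)
    attr(out, "founder_freq") <- p
    out
  })
}

# gamete from parent row `par` (0 = unknown -> population draw)
drop_gamete <- function(par, a1, a2, p) {
  m <- length(p)
  if (par == 0L) {
    return(as.integer(stats::runif(m) < p))
  }
  pick <- stats::runif(m) < 0.5
  ifelse(pick, a1[par, ], a2[par, ])
}

sim_snp_map <- function(cfg) {
  m <- cfg$n_snps
  chr <- sort(rep_len(seq_len(cfg$n_chr), m))
  pos <- unlist(lapply(split(seq_len(m), chr), function(ix) {
    sort(sample.int(cfg$chr_length_bp, length(ix)))
  }), use.names = FALSE)
  tibble::tibble(snp = sprintf("SNP%05d", seq_len(m)),
                 chr = paste0("C", chr), pos = pos)
}

#' Simulate bivariate phenotypes with known true breeding values
#'
#' True breeding values are the sum of a QTL genomic value (a
#' `qtl_variance_fraction` share of the additive variance, from centred
#' allele counts at `n_qtl` SNPs with effects correlated `rg` across
#' traits) and an infinitesimal polygenic value bred down the pedigree
#' (parent average plus a Mendelian-sampling deviation with variance
#' \eqn{(0.5 - 0.25 (F_s + F_d))} times the polygenic covariance).  Both
#' components are rescaled per trait so the realized population variance
#' of the true breeding values equals the target additive variance (the
#' usual calibration in simulation studies; scaling preserves the
#' relationship-matrix covariance structure up to a constant).
#' Phenotypes add the trait mean, a contemporary-group effect and a
#' residual with correlation `re`; only `prop_phenotyped` animals
#' (non-founders first) receive records, on both traits.
#'
#' @param pedigree a `pedigree`.
#' @param genotypes full-pedigree [geno_set()] from [simulate_genotypes()].
#' @param config a [sim_config()].
#' @return A list with `phenotypes` (tibble `animal, cg, trait1, trait2`)
#'   and `truth` (list: `tbv` matrix for all animals, `qtl` tibble of
#'   SNP names and scaled per-trait effects, `cg_effects`).
#' @export
simulate_phenotypes <- function(pedigree, genotypes, config) {
  cfg <- config
  ped <- ensure_pedigree(pedigree)
  n <- nrow(ped)
  G0 <- sim_G0(cfg)
  R0 <- sim_R0(cfg)
  if (cfg$qtl_variance_fraction > 1) {
    stop("config error: QTL variance exceeds the additive variance")
  }
  with_sim_seed(cfg$seed, 3L, {
    # --- QTL genomic values ---
    qvf <- cfg$qtl_variance_fraction
    if (cfg$n_qtl > 0 && qvf > 0) {
      qtl_ix <- sort(sample.int(cfg$n_snps, cfg$n_qtl))
      M <- genotypes$calls[ped$animal, qtl_ix, drop = FALSE]
      Cq <- scale(M, center = TRUE, scale = FALSE)
      alpha <- rmvn2(cfg$n_qtl, matrix(c(1, cfg$rg, cfg$rg, 1), 2, 2))
      if (cfg$qtl_equal_variance) {
        # each QTL carries the same variance share; signs keep the drawn
        # cross-trait pattern
        share <- qvf * diag(G0) / cfg$n_qtl
        cv <- apply(Cq, 2, stats::var)
        cv[cv == 0] <- Inf # monomorphic QTL contributes nothing
        for (t in 1:2) {
          alpha[, t] <- sign(alpha[, t]) * sqrt(share[t] / cv)
        }
      }
      gv <- Cq %*% alpha
      for (t in 1:2) {
        v <- stats::var(gv[, t])
        target <- qvf * G0[t, t]
        sc <- if (v > 0) sqrt(target / v) else 0
        gv[, t] <- gv[, t] * sc
        alpha[, t] <- alpha[, t] * sc
      }
      qtl <- tibble::tibble(snp = genotypes$map$snp[qtl_ix],
                            index = qtl_ix,
                            effect1 = alpha[, 1], effect2 = alpha[, 2])
    } else {
      gv <- matrix(0, n, 2)
      qtl <- tibble::tibble(snp = character(), index = integer(),
                            effect1 = numeric(), effect2 = numeric())
    }
    # --- polygenic values down the pedigree ---
    G0p <- (1 - qvf) * G0
    Lp <- chol_or_zero(G0p)
    pp <- ped_parents(ped)
    f <- ml_inbreeding(pp$s, pp$d)
    fpar <- function(p) if (p == 0L) -1 else f[p]
    u <- matrix(0, n, 2)
    z <- matrix(stats::rnorm(2 * n), n, 2)
    for (i in seq_len(n)) {
      pa <- numeric(2)
      if (pp$s[i] > 0L) pa <- pa + 0.5 * u[pp$s[i], ]
      if (pp$d[i] > 0L) pa <- pa + 0.5 * u[pp$d[i], ]
      msv <- 0.5 - 0.25 * (fpar(pp$s[i]) + fpar(pp$d[i]))
      u[i, ] <- pa + sqrt(msv) * drop(z[i, ] %*% Lp)
    }
    # calibrate: rescale each trait so the realized population variance
    # of the polygenic values equals its target (scaling preserves the
    # pedigree covariance structure up to a constant)
    if (n > 1) {
      for (t in 1:2) {
        v <- stats::var(u[, t])
        if (v > 0 && G0p[t, t] > 0) u[, t] <- u[, t] * sqrt(G0p[t, t] / v)
      }
    }
    tbv <- gv + u
    rownames(tbv) <- ped$animal
    colnames(tbv) <- c("trait1", "trait2")
    # --- fixed effects, residuals, records ---
    cg <- sample.int(cfg$n_contemporary_groups, n, replace = TRUE)
    cg_eff <- matrix(stats::rnorm(2 * cfg$n_contemporary_groups), ncol = 2) %*%
      diag(cfg$cg_sd * cfg$trait_sds)
    e <- rmvn2(n, R0)
    y <- sweep(tbv + e + cg_eff[cg, ], 2, cfg$trait_means, `+`)
    n_rec <- round(cfg$prop_phenotyped * n)
    nonf <- which(!(is.na(ped$sire) & is.na(ped$dam)) |
                    (if ("generation" %in% names(ped)) ped$generation > 0 else FALSE))
    pool <- if (length(nonf) >= n_rec) nonf else seq_len(n)
    rec <- sort(sample(pool, min(n_rec, length(pool))))
    phenotypes <- tibble::tibble(
      animal = ped$animal[rec],
      cg = sprintf("CG%02d", cg[rec]),
      trait1 = y[rec, 1],
      trait2 = y[rec, 2]
    )
    list(phenotypes = phenotypes,
         truth = list(tbv = tbv, qtl = qtl, cg_effects = cg_eff))
  })
}

chol_or_zero <- function(S) {
  if (all(abs(S) < .Machine$double.eps)) return(matrix(0, nrow(S), ncol(S)))
  chol(S)
}

# n draws from a bivariate normal with covariance S (rows = draws)
rmvn2 <- function(n, S) {
  matrix(stats::rnorm(2 * n), n, 2) %*% chol_or_zero(S)
}

#' Extract the genotyped panel
#'
#' Samples `prop_genotyped` of the pedigree animals — at random, or
#' stratified over high/medium/low breeding-value terciles within each sex
#' (`genotyped_sampling = "ebv_stratified"`, using the supplied ranking
#' values) — and injects missing calls at `missing_rate`.
#'
#' @param genotypes full-pedigree [geno_set()].
#' @param pedigree the `pedigree`.
#' @param config a [sim_config()].
#' @param ranking optional named numeric vector (e.g. EBVs or true
#'   breeding values) used for the stratified mode.
#' @return A [geno_set()] for the sampled panel.
#' @export
sample_genotype_panel <- function(genotypes, pedigree, config, ranking = NULL) {
  cfg <- config
  ped <- ensure_pedigree(pedigree)
  with_sim_seed(cfg$seed, 4L, {
    n_panel <- max(2L, round(cfg$prop_genotyped * nrow(ped)))
    if (cfg$genotyped_sampling == "ebv_stratified" && !is.null(ranking)) {
      strata <- split(ped$animal, list(
        sex = if ("sex" %in% names(ped)) ped$sex else "U",
        tercile = dplyr::ntile(ranking[ped$animal], 3)
      ), drop = TRUE)
      per <- ceiling(n_panel / length(strata))
      chosen <- unlist(lapply(strata, function(a) {
        sample(a, min(per, length(a)))
      }), use.names = FALSE)
      chosen <- utils::head(chosen, n_panel)
    } else {
      chosen <- sample(ped$animal, n_panel)
    }
    chosen <- ped$animal[ped$animal %in% chosen] # pedigree order
    out <- geno_subset(genotypes, animals = chosen)
    if (cfg$missing_rate > 0) {
      mask <- matrix(stats::runif(length(out$calls)) < cfg$missing_rate,
                     nrow(out$calls))
      out$calls[mask] <- NA
    }
    out
  })
}

#' Simulate a gene table
#'
#' Places genes of random span uniformly along the chromosomes of a SNP
#' map (1-based inclusive coordinates), for exercising the candidate-gene
#' annotation stage.
#'
#' @param map SNP map tibble `(snp, chr, pos)` (defines the chromosomes).
#' @param n_genes number of genes.
#' @param span_range min/max gene length in bp.
#' @param seed integer seed.
#' @return A tibble `(gene, chr, start, end)`.
#' @export
simulate_gene_table <- function(map, n_genes = 200,
                                span_range = c(2e3, 2e5), seed = 1L) {
  with_sim_seed(seed, 5L, {
    chrs <- unique(map$chr)
    chr <- sample(chrs, n_genes, replace = TRUE)
    hi <- vapply(split(map$pos, map$chr), max, numeric(1))[chr]
    start <- floor(stats::runif(n_genes, 1, pmax(2, hi)))
    len <- floor(stats::runif(n_genes, span_range[1], span_range[2]))
    out <- tibble::tibble(gene = sprintf("GENE%04d", seq_len(n_genes)),
                          chr = chr, start = start, end = start + len)
    dplyr::arrange(out, .data$chr, .data$start)
  })
}
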