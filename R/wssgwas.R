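#' Back-solve SNP effects from genomic breeding values
#'
#' \deqn{\hat s = \frac{1}{\phi} D Z' G^{-1} \hat u}
#' The `1/phi` factor makes the conversion exactly consistent with
#' `G = Z D Z' / phi`, so that `Z %*% s_hat = u_hat` when G is unblended;
#' it cancels in every variance-percentage output.
#'
#' @param gebv numeric vector of genomic breeding values for the
#'   genotyped animals (same order as the rows of `Z`).
#' @param Z centred genotype matrix from [center_genotypes()].
#' @param weights the [g_weights()] used to build G.
#' @param G_inv inverse of the (possibly blended) G for the same animals.
#' @return A tibble `(snp, effect, weight)`; SNP names from the columns
#'   of `Z`.
#' @export
backsolve_snp_effects <- function(gebv, Z, weights, G_inv) {
  if (length(gebv) != nrow(Z) || !all(dim(G_inv) == nrow(Z))) {
    stop("dimension mismatch between gebv, Z and G_inv")
  }
  if (ncol(Z) != length(weights$d)) {
    stop("dimension mismatch between Z and the SNP weights")
  }
  s <- unname((weights$d / weights$phi) *
                drop(crossprod(Z, G_inv %*% gebv)))
  tibble::tibble(
    snp = colnames(Z) %||% sprintf("SNP%05d", seq_len(ncol(Z))),
    effect = s, weight = weights$d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Update SNP weights from estimated effects
#'
#' The iterative weighting rule: `d_i = s_i^2 * 2 p_i (1 - p_i)`, then
#' normalised so the weights sum to the number of SNPs.  All-zero effects
#' reset the weights to 1 with a warning.
#'
#' @param effects tibble from [backsolve_snp_effects()] (column `effect`).
#' @param weights the current [g_weights()] (supplies `p`).
#' @return A new [g_weights()] with updated, normalised `d`.
#' @export
update_weights <- function(effects, weights) {
  s <- effects$effect
  p <- weights$p
  stopifnot(length(s) == length(p))
  d <- s^2 * 2 * p * (1 - p)
  g_weights(p, d, normalize = TRUE)
}

#' Genomic-window variance percentages
#'
#' For each window of `window_size` consecutive SNPs within a chromosome,
#' the variance across genotyped animals of the window genomic value
#' \eqn{\sum_k z_k \hat s_k}, expressed as a percentage of the additive
#' genetic variance.  Windows never span chromosomes; a chromosome with
#' fewer SNPs than `window_size` becomes a single whole-chromosome window
#' with a warning.
#'
#' @param effects tibble from [backsolve_snp_effects()], aligned with the
#'   columns of `Z` and the rows of `map`.
#' @param Z centred genotype matrix (animals x SNPs).
#' @param map SNP map tibble `(snp, chr, pos)` in the column order of `Z`.
#' @param sigma_a2 additive genetic variance (e.g. from the REML fit).
#' @param window_size number of consecutive SNPs per window.
#' @param scheme `"sliding"` (step 1) or `"nonoverlapping"` (tiling).
#' @return A tibble of class `window_result`: `chr`, `window`,
#'   `start_idx`, `end_idx` (column indices into `map`), `start_bp`,
#'   `end_bp`, `n_snps`, `variance_pct`, ordered by genome position.
#' @export
window_variance <- function(effects, Z, map, sigma_a2, window_size = 10,
                            scheme = c("sliding", "nonoverlapping")) {
  scheme <- match.arg(scheme)
  stopifnot(sigma_a2 > 0, nrow(map) == ncol(Z),
            nrow(effects) == ncol(Z))
  s <- effects$effect
  out <- list()
  for (ch in unique(map$chr)) {
    ix <- which(map$chr == ch)
    m_chr <- length(ix)
    ws <- window_size
    if (ws > m_chr) {
      warning("window size ", ws, " exceeds the ", m_chr, " SNPs on ",
              ch, "; using one whole-chromosome window")
      ws <- m_chr
    }
    starts <- if (scheme == "sliding") seq_len(m_chr - ws + 1L)
              else seq(1L, m_chr - ws + 1L, by = ws)
    # cumulative window genomic values: one matrix product per chromosome
    gv <- Z[, ix, drop = FALSE] %*% s[ix]
    # incremental: value of window j = rowSums over its columns; do it
    # via cumulative sums of per-SNP contributions
    contrib <- sweep(Z[, ix, drop = FALSE], 2, s[ix], `*`)
    cs <- cbind(0, t(apply(contrib, 1, cumsum)))
    vp <- vapply(starts, function(j) {
      wv <- cs[, j + ws] - cs[, j]
      100 * stats::var(wv) / sigma_a2
    }, 0)
    out[[length(out) + 1]] <- tibble::tibble(
      chr = ch,
      window = seq_along(starts),
      start_idx = ix[starts],
      end_idx = ix[starts + ws - 1L],
      start_bp = map$pos[ix[starts]],
      end_bp = map$pos[ix[starts + ws - 1L]],
      n_snps = ws,
      variance_pct = vp)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "scheme") <- scheme
  attr(res, "window_size") <- window_size
  attr(res, "sigma_a2") <- sigma_a2
  class(res) <- c("window_result", class(res))
  res
}

#' Select significant windows
#'
#' Windows explaining at least `threshold_pct` of the additive genetic
#' variance, preserving genome order.
#'
#' @param wr a [window_variance()] result.
#' @param threshold_pct inclusive threshold in percent.
#' @return The qualifying subset of `wr` (same class and attributes).
#' @export
significant_windows <- function(wr, threshold_pct = 10) {
  out <- wr[wr$variance_pct >= threshold_pct, ]
  attr(out, "scheme") <- attr(wr, "scheme")
  attr(out, "window_size") <- attr(wr, "window_size")
  attr(out, "sigma_a2") <- attr(wr, "sigma_a2")
  attr(out, "threshold_pct") <- threshold_pct
  out
}

#' SNPs inside significant windows
#'
#' @param wr a (possibly filtered) [window_variance()] result.
#' @param map the SNP map used to build it.
#' @return A tibble `(snp, chr, pos)` of the distinct SNPs covered by the
#'   windows of `wr`, in map order.
#' @export
window_snps <- function(wr, map) {
  ix <- sort(unique(unlist(
    Map(function(a, b) seq(a, b), wr$start_idx, wr$end_idx))))
  map[ix, c("snp", "chr", "pos")]
}

#' Weighted single-step GBLUP with iterative SNP weighting
#'
#' Runs the full weighted single-step loop: build the (blended) genomic
#' relationship matrix with the current SNP weights, assemble the
#' single-step H-inverse, solve the mixed-model equations, back-solve SNP
#' effects from the genotyped animals' GEBVs, re-weight SNPs by
#' `s^2 2p(1-p)`, and repeat.  Two weight iterations are the default.
#'
#' @inheritParams reml_estimate
#' @param pedigree the full `pedigree`.
#' @param genotypes post-QC [geno_set()] for the genotyped subset.
#' @param vc variance components (list with `G0`, `R0`, e.g. a
#'   [reml_estimate()] fit).  Used unchanged at every iteration.
#' @param tau,omega H-inverse scaling factors.
#' @param alpha G blending weight (1 = no blending).
#' @param n_weight_iters number of weight iterations (1 = unweighted
#'   single-step GBLUP).
#' @param weight_trait trait whose back-solved effects drive the weight
#'   updates (default: first trait).
#' @return An object of class `wssgblup_fit`: final `evaluation`
#'   ([solve_mme()] result), per-trait `effects` tibble, final `weights`,
#'   `Z`, `map`, `genotyped` ids, iteration `history` (per-iteration
#'   effects and the GEBV correlation with the previous iteration).
#' @export
wssgblup <- function(phenotypes, traits, pedigree, genotypes, vc,
                     tau = 1.00, omega = 0.50, alpha = 0.95,
                     n_weight_iters = 2, weight_trait = traits[1],
                     fixed = "cg") {
  ped <- ensure_pedigree(pedigree)
  gen_ids <- rownames(genotypes$calls)
  stopifnot(weight_trait %in% traits)
  A_inv <- build_A_inverse(ped)
  A22 <- build_A(ped, subset = gen_ids)
  A22_inv <- sym_inverse(A22)
  w <- g_weights(allele_freq(genotypes))
  Z <- center_genotypes(genotypes, w$p)
  history <- list()
  prev_gebv <- NULL
  fit <- NULL
  eff <- NULL
  for (it in seq_len(n_weight_iters)) {
    G <- blend_G(build_G(genotypes, w), A22, alpha = alpha)
    G_inv <- sym_inverse(G)
    H_inv <- build_H_inverse(as.matrix(A_inv), A22_inv, G_inv, gen_ids,
                             tau = tau, omega = omega)
    fit <- solve_mme(phenotypes, traits, H_inv, vc, pedigree = ped,
                     fixed = fixed, method = "wssgblup")
    eff <- lapply(traits, function(tr) {
      gebv <- fit$predictions$bv[fit$predictions$trait == tr]
      names(gebv) <- fit$predictions$animal[fit$predictions$trait == tr]
      dplyr::mutate(
        backsolve_snp_effects(gebv[gen_ids], Z, w, G_inv),
        trait = tr, iteration = it)
    })
    names(eff) <- traits
    gebv_w <- fit$predictions$bv[fit$predictions$trait == weight_trait]
    cor_prev <- if (is.null(prev_gebv)) NA_real_ else
      stats::cor(gebv_w, prev_gebv)
    prev_gebv <- gebv_w
    history[[it]] <- list(effects = dplyr::bind_rows(eff),
                          cor_with_previous = cor_prev)
    if (it < n_weight_iters) {
      w <- update_weights(eff[[weight_trait]], w)
    }
  }
  structure(list(
    evaluation = fit,
    effects = dplyr::bind_rows(eff),
    weights = w,
    Z = Z, map = genotypes$map, genotyped = gen_ids,
    vc = list(G0 = vc$G0, R0 = vc$R0),
    history = history,
    tau = tau, omega = omega, alpha = alpha
  ), class = "wssgblup_fit")
}

#' @export
print.wssgblup_fit <- function(x, ...) {
  cat("<wssgblup_fit> ", length(x$genotyped), " genotyped animals, ",
      ncol(x$Z), " SNPs, ", length(x$history), " weight iteration(s)\n",
      sep = "")
  print(x$evaluation)
  invisible(x)
}

#' Window-variance GWAS from a weighted single-step fit
#'
#' Convenience wrapper: back-solved effects of one trait are summarised
#' into window variance percentages.
#'
#' @param wfit a [wssgblup()] fit.
#' @param trait trait name (default: first trait in the fit).
#' @param sigma_a2 additive variance; defaults to the fit's value for
#'   that trait.
#' @inheritParams window_variance
#' @return A [window_variance()] tibble.
#' @export
wssgwas_windows <- function(wfit, trait = NULL, window_size = 10,
                            scheme = c("sliding", "nonoverlapping"),
                            sigma_a2 = NULL) {
  trait <- trait %||% wfit$effects$trait[1]
  eff <- wfit$effects[wfit$effects$trait == trait, ]
  if (!nrow(eff)) stop("trait '", trait, "' not found in the fit")
  t_ix <- match(trait, wfit$evaluation$traits)
  sigma_a2 <- sigma_a2 %||% wfit$vc$G0[t_ix, t_ix]
  window_variance(eff, wfit$Z, wfit$map, sigma_a2,
                  window_size = window_size, scheme = match.arg(scheme))
}
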