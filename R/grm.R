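#' SNP weights for the weighted genomic relationship matrix
#'
#' Bundles per-SNP weights `d`, allele frequencies `p`, and the VanRaden
#' scaling factor `phi = 2 * sum(p * (1 - p))`.  Weights are normalised so
#' they sum to the number of SNPs; `phi` is always computed from `p` (not
#' the weights), so re-weighting never rescales G overall.
#'
#' @param p per-SNP allele frequencies in (0, 1).
#' @param d per-SNP non-negative weights (default: all 1).
#' @param normalize normalise `d` to sum to the number of SNPs.
#' @return A list of class `g_weights` with `d`, `p`, `phi`.
#' @export
g_weights <- function(p, d = rep(1, length(p)), normalize = TRUE) {
  stopifnot(length(d) == length(p), all(d >= 0))
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic SNP (p = 0 or 1); remove it in QC before building G")
  }
  if (normalize) {
    if (sum(d) == 0) {
      warning("all-zero SNP weights; resetting to 1")
      d <- rep(1, length(p))
    }
    d <- d * length(d) / sum(d)
  }
  phi <- 2 * sum(p * (1 - p))
  structure(list(d = d, p = p, phi = phi), class = "g_weights")
}

#' Centred genotype matrix Z
#'
#' Mean-imputes missing calls to `2p` and centres each column by `2p`.
#'
#' @param genotypes a [geno_set()] (post-QC).
#' @param p per-SNP allele frequencies (default: observed).
#' @return Dense numeric matrix Z (animals x SNPs).
#' @export
center_genotypes <- function(genotypes, p = allele_freq(genotypes)) {
  M <- genotypes$calls
  stopifnot(length(p) == ncol(M))
  for (j in which(colSums(is.na(M)) > 0)) {
    M[is.na(M[, j]), j] <- 2 * p[j]
  }
  sweep(M, 2, 2 * p)
}

#' Genomic relationship matrix (weighted VanRaden)
#'
#' \eqn{G = Z D Z' / \phi} with Z the centred allele counts,
#' D = diag(weights) and \eqn{\phi = 2\sum_i p_i (1 - p_i)}.  With unit
#' weights and observed frequencies this is VanRaden's method 1.
#'
#' @param genotypes a [geno_set()] (post-QC; no monomorphic SNPs).
#' @param weights a [g_weights()]; default unit weights at observed
#'   frequencies.
#' @return Dense symmetric matrix with animal ids as dimnames.
#' @export
build_G <- function(genotypes, weights = NULL) {
  if (is.null(weights)) weights <- g_weights(allele_freq(genotypes))
  Z <- center_genotypes(genotypes, weights$p)
  G <- tcrossprod(sweep(Z, 2, weights$d, `*`), Z) / weights$phi
  (G + t(G)) / 2
}

#' Blend G with its pedigree counterpart
#'
#' `alpha * G + (1 - alpha) * A22`, the usual guard against a singular G
#' when markers are fewer than animals or lines are duplicated.
#' `alpha = 1` disables blending.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationship matrix for the same animals, in the
#'   same order.
#' @param alpha blending weight in (0, 1].
#' @param min_rcond reciprocal-condition-number floor below which the
#'   blended matrix is declared singular.
#' @return Blended dense matrix.
#' @export
blend_G <- function(G, A22, alpha = 0.95, min_rcond = 1e-12) {
  stopifnot(all(dim(G) == dim(A22)))
  if (alpha == 1) return(G) # blending disabled
  Gb <- alpha * G + (1 - alpha) * A22
  if (rcond(Gb) < min_rcond) {
    stop("blended G is numerically singular; use a smaller alpha")
  }
  Gb
}

#' Single-step H-inverse
#'
#' \deqn{H^{-1} = A^{-1} + \begin{pmatrix} 0 & 0 \\ 0 & \tau G^{-1} -
#'   \omega A_{22}^{-1} \end{pmatrix}}
#' on the genotyped block.  The non-genotyped blocks of the result equal
#' the corresponding blocks of `A_inv` exactly.
#'
#' @param A_inv inverse pedigree relationship matrix (all animals, with
#'   dimnames).
#' @param A22_inv inverse of the genotyped block of A.
#' @param G_inv inverse (possibly blended) genomic relationship matrix.
#' @param genotyped character vector of genotyped animal ids, matching
#'   the row order of `G_inv` and `A22_inv`.
#' @param tau,omega scaling factors on `G_inv` and `A22_inv`
#'   (defaults 1.00 and 0.50).
#' @return Dense symmetric matrix with the full animal set as dimnames.
#' @export
build_H_inverse <- function(A_inv, A22_inv, G_inv, genotyped,
                            tau = 1.00, omega = 0.50) {
  H <- as.matrix(A_inv)
  if (length(genotyped)) {
    if (!all(genotyped %in% rownames(H))) {
      stop("genotyped animals missing from A_inv")
    }
    if (!all(dim(G_inv) == length(genotyped)) ||
        !all(dim(A22_inv) == length(genotyped))) {
      stop("G_inv/A22_inv dimensions do not match the genotyped set")
    }
    ix <- match(genotyped, rownames(H))
    H[ix, ix] <- H[ix, ix] + tau * as.matrix(G_inv) -
      omega * as.matrix(A22_inv)
  }
  H
}

# symmetric positive-definite inverse via Cholesky
sym_inverse <- function(S) {
  out <- chol2inv(chol(S))
  dimnames(out) <- dimnames(S)
  out
}
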