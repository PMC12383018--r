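#' Validate and order a pedigree
#'
#' Takes a data frame whose first three columns (or the named columns) give
#' animal, sire and dam identifiers, validates it, and returns a pedigree
#' tibble in topological order: every known parent appears before its
#' offspring.  Unknown parents may be coded `NA`, `""` or `"0"`.
#'
#' Parents that are referenced but never declared as animals are added as
#' founders with a warning.  An animal that is its own ancestor (including a
#' self-parent) is an error; the offending cycle is named in the message.
#'
#' @param df data frame with animal, sire and dam identifier columns.
#' @param animal,sire,dam column names (defaults: first three columns).
#' @return A tibble of class `pedigree` with character columns `animal`,
#'   `sire`, `dam` (`NA` = unknown parent), topologically ordered.
#' @examples
#' ped <- as_pedigree(data.frame(animal = c("C", "A", "B"),
#'                               sire   = c("A", NA, NA),
#'                               dam    = c("B", NA, NA)))
#' @export
as_pedigree <- function(df, animal = names(df)[1], sire = names(df)[2],
                        dam = names(df)[3]) {
  stopifnot(is.data.frame(df), nrow(df) > 0)
  norm <- function(x) {
    x <- trimws(as.character(x))
    x[x %in% c("", "0", "NA")] <- NA_character_
    x
  }
  an <- norm(df[[animal]])
  si <- norm(df[[sire]])
  da <- norm(df[[dam]])
  if (anyNA(an)) stop("missing animal identifier in pedigree")
  if (anyDuplicated(an)) {
    stop("duplicated animal identifier(s): ",
         paste(unique(an[duplicated(an)]), collapse = ", "))
  }
  self <- which(!is.na(si) & si == an | !is.na(da) & da == an)
  if (length(self)) {
    stop("pedigree cycle: animal ", an[self[1]], " is its own parent")
  }
  undeclared <- setdiff(stats::na.omit(c(si, da)), an)
  if (length(undeclared)) {
    warning(length(undeclared), " parent(s) not declared as animals; ",
            "added as founders: ",
            paste(utils::head(undeclared, 5), collapse = ", "),
            if (length(undeclared) > 5) ", ..." else "")
    an <- c(undeclared, an)
    si <- c(rep(NA_character_, length(undeclared)), si)
    da <- c(rep(NA_character_, length(undeclared)), da)
  }
  n <- length(an)
  idx <- stats::setNames(seq_len(n), an)
  s <- ifelse(is.na(si), 0L, idx[si])
  d <- ifelse(is.na(da), 0L, idx[da])

  ord <- ped_toposort(s, d, an)
  out <- tibble::tibble(animal = an[ord], sire = si[ord], dam = da[ord])
  class(out) <- c("pedigree", class(out))
  out
}

# Kahn's algorithm; on failure names one animal inside a cycle.
ped_toposort <- function(s, d, ids) {
  n <- length(s)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(s[i], d[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    # pop the smallest index: a pedigree that is already topologically
    # sorted round-trips in identical order
    v <- min(queue)
    queue <- queue[queue != v]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    bad <- setdiff(seq_len(n), ord)
    stop("pedigree cycle involving: ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  }
  ord
}

# Integer parent indices (0 = unknown) for an ordered pedigree.
ped_parents <- function(ped) {
  idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  list(
    s = ifelse(is.na(ped$sire), 0L, unname(idx[ped$sire])),
    d = ifelse(is.na(ped$dam), 0L, unname(idx[ped$dam]))
  )
}

#' Inbreeding coefficients
#'
#' Computes per-animal inbreeding coefficients F by the Meuwissen--Luo
#' algorithm (ancestor traversal accumulating \eqn{a_{ii} = \sum_j L_{ij}^2
#' d_j}), without forming the dense relationship matrix.
#'
#' @param ped a `pedigree` from [as_pedigree()].
#' @return A tibble `(animal, f)` in pedigree order.
#' @export
inbreeding <- function(ped) {
  ped <- ensure_pedigree(ped)
  pp <- ped_parents(ped)
  tibble::tibble(animal = ped$animal, f = ml_inbreeding(pp$s, pp$d))
}

# Meuwissen & Luo traversal.  F of an unknown parent enters the
# Mendelian-sampling variance as -1 so that d = 0.5 - 0.25 (F_s + F_d)
# covers the one- and no-parent cases (0.75 - 0.25 F and 1).
ml_inbreeding <- function(s, d) {
  n <- length(s)
  f <- numeric(n)
  ms <- numeric(n) # Mendelian-sampling variance d_i
  fpar <- function(p) if (p == 0L) -1 else f[p]
  L <- numeric(n)
  for (i in seq_len(n)) {
    ms[i] <- 0.5 - 0.25 * (fpar(s[i]) + fpar(d[i]))
    if (s[i] == 0L || d[i] == 0L) {
      f[i] <- 0
      next
    }
    L[i] <- 1
    active <- i
    aii <- 0
    while (length(active)) {
      j <- max(active)
      active <- active[active != j]
      lj <- L[j]
      for (p in c(s[j], d[j])) {
        if (p > 0L) {
          if (L[p] == 0) active <- c(active, p)
          L[p] <- L[p] + 0.5 * lj
        }
      }
      aii <- aii + lj * lj * ms[j]
      L[j] <- 0
    }
    f[i] <- aii - 1
  }
  f
}

ensure_pedigree <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- as_pedigree(ped)
  ped
}

#' Pedigree relationship matrix A
#'
#' Builds the additive (numerator) relationship matrix by the tabular
#' method, with inbreeding.  When `subset` is given the corresponding
#' sub-matrix is returned (e.g. `A22` when `subset` is the genotyped
#' animals); the full recursion still runs over all ancestors, so the
#' subset matrix is exact.
#'
#' @param ped a `pedigree` (see [as_pedigree()]).
#' @param subset optional character vector of animal ids to keep.
#' @return A dense symmetric matrix with animal ids as dimnames.
#' @export
build_A <- function(ped, subset = NULL) {
  ped <- ensure_pedigree(ped)
  pp <- ped_parents(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    si <- pp$s[i]
    di <- pp$d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (si > 0L) row <- row + 0.5 * A[si, j]
      if (di > 0L) row <- row + 0.5 * A[di, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (si > 0L && di > 0L) 0.5 * A[si, di] else 0
  }
  if (!is.null(subset)) {
    missing <- setdiff(subset, ped$animal)
    if (length(missing)) {
      stop("subset animals absent from pedigree: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    A <- A[subset, subset, drop = FALSE]
  }
  A
}

#' Sparse inverse of the pedigree relationship matrix
#'
#' Assembles A-inverse directly by Henderson's rules, with
#' Mendelian-sampling variances from Meuwissen--Luo inbreeding
#' coefficients.  The dense A is never formed.
#'
#' @param ped a `pedigree` (see [as_pedigree()]).
#' @return A sparse symmetric `Matrix` with animal ids as dimnames.
#' @export
build_A_inverse <- function(ped) {
  ped <- ensure_pedigree(ped)
  pp <- ped_parents(ped)
  n <- nrow(ped)
  f <- ml_inbreeding(pp$s, pp$d)
  fpar <- function(p) if (p == 0L) -1 else f[p]
  # at most 9 triplets per animal: (i,i), 4 parent crossings, 2x2 parent block
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  k <- 0L
  for (i in seq_len(n)) {
    ms <- 0.5 - 0.25 * (fpar(pp$s[i]) + fpar(pp$d[i]))
    b <- 1 / ms
    par <- c(pp$s[i], pp$d[i])
    par <- par[par > 0L]
    ti <- c(i, rep(i, length(par)), par, rep(par, each = length(par)))
    tj <- c(i, par, rep(i, length(par)), rep(par, times = length(par)))
    tv <- c(b, rep(-b / 2, 2L * length(par)),
            rep(b / 4, length(par)^2))
    idx <- k + seq_along(ti)
    ii[idx] <- ti; jj[idx] <- tj; xx[idx] <- tv
    k <- k + length(ti)
  }
  ii <- ii[seq_len(k)]; jj <- jj[seq_len(k)]; xx <- xx[seq_len(k)]
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(Ainv)
}
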