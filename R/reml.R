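#' Estimate variance components by EM-REML for an animal model
#'
#' Fits the univariate or bivariate animal model `y = Xb + Za + e` with a
#' contemporary-group fixed effect and additive genetic effects
#' `a ~ N(0, G0 x K)`, where K is the relationship matrix whose inverse
#' (`kinv`: pedigree A-inverse or single-step H-inverse) is supplied.
#' Residuals are correlated across traits within animal
#' (`e ~ N(0, R0)` per animal); records missing one trait are handled by
#' trait-specific incidence (no imputation).
#'
#' The EM algorithm iterates Henderson's mixed-model equations and updates
#' `G0` from `a' K^-1 a` plus its trace correction and `R0` from the
#' conditional residual cross-products (animals missing a trait contribute
#' their conditional expectations, so the update is a proper EM step and
#' the restricted log-likelihood never decreases).  When both traits are
#' recorded on exactly the same animals with the same fixed-effect design,
#' a canonical transformation decouples the traits and each iteration
#' solves two univariate systems instead of one bivariate system — same
#' EM map, much cheaper.  An optional step-lengthening acceleration tries
#' extrapolated updates and keeps them only when the log-likelihood
#' improves, preserving monotonicity.
#'
#' @param phenotypes tibble with columns `animal`, the fixed-effect column
#'   (default `cg`), and the trait columns; at most one record per animal.
#' @param traits character vector (length 1 or 2) of trait column names.
#' @param kinv relationship inverse (dense or `Matrix`) with animal ids as
#'   dimnames; defines the animal-effect vector.
#' @param fixed name of the fixed-effect column, or `NULL` for an
#'   intercept-only model.
#' @param max_iter iteration cap.
#' @param tol convergence threshold: iteration stops when the maximum
#'   parameter change (normalised by the phenotypic covariance scale)
#'   falls below `tol`, or the absolute log-likelihood gain of an EM step
#'   falls below `tol`.
#' @param accelerate use guarded step-lengthening.
#' @param se compute approximate standard errors (average-information
#'   matrix at the optimum) for the (co)variances.
#' @param verbose print the likelihood trace.
#' @return An object of class `reml_fit`: `G0`, `R0`, `h2`, `rg`, `rp`,
#'   `loglik` (trace of the restricted log-likelihood), `converged`,
#'   `n_iter`, `vcov_theta` (asymptotic covariance of the parameters, if
#'   `se`), and the model bookkeeping needed by [reml_standard_errors()]
#'   and [solve_mme()].
#' @seealso [tidy.reml_fit()], [glance.reml_fit()]
#' @export
reml_estimate <- function(phenotypes, traits, kinv, fixed = "cg",
                          max_iter = 500L, tol = 1e-8,
                          accelerate = TRUE, se = TRUE, verbose = FALSE) {
  des <- mme_design(phenotypes, traits, kinv, fixed)
  nt <- des$nt
  # neutral start: half the phenotypic variance to each component
  vy <- vapply(seq_len(nt), function(t) stats::var(des$y[[t]]), 0)
  G0 <- diag(vy / 2, nt)
  R0 <- diag(vy / 2, nt)
  ll_trace <- numeric(0)
  converged <- FALSE
  use_canonical <- nt == 2 && des$equal_design
  if (use_canonical) des$cdes_cache <- canonical_design(des)
  em_step <- function(G0, R0) {
    if (use_canonical) em_step_canonical(des, G0, R0)
    else em_step_general(des, G0, R0)
  }
  ll_of <- function(G0, R0) {
    if (use_canonical) reml_loglik_canonical(des, G0, R0)
    else reml_loglik_general(des, G0, R0)
  }
  iter <- 0L
  vec_of <- function(G, R) c(G[upper.tri(G, diag = TRUE)],
                             R[upper.tri(R, diag = TRUE)])
  unvec <- function(v) {
    k <- nt * (nt + 1) / 2
    G <- matrix(0, nt, nt); R <- matrix(0, nt, nt)
    G[upper.tri(G, diag = TRUE)] <- v[seq_len(k)]
    R[upper.tri(R, diag = TRUE)] <- v[k + seq_len(k)]
    G[lower.tri(G)] <- t(G)[lower.tri(G)]
    R[lower.tri(R)] <- t(R)[lower.tri(R)]
    list(G0 = G, R0 = R)
  }
  # parameter changes are judged on the phenotypic-covariance scale so
  # that vanishing components (boundary estimates) can still converge
  scale_of <- function(G, R) {
    p <- diag(G) + diag(R)
    s <- sqrt(outer(p, p))
    c(s[upper.tri(s, diag = TRUE)], s[upper.tri(s, diag = TRUE)])
  }
  ll_prev <- -Inf
  # Warm-up: SQUAREM-type EM cycles (two EM steps then an extrapolated
  # jump kept only when it does not lower the likelihood).  Main phase:
  # average-information (AI) updates from the EM-step score via the
  # Fisher identity, with step halving and an EM fallback so the
  # restricted log-likelihood never decreases.
  warmup_cycles <- 2L
  cycle <- 0L
  while (iter < max_iter) {
    th0 <- vec_of(G0, R0)
    st1 <- em_step(G0, R0)
    iter <- iter + 1L
    cycle <- cycle + 1L
    p1 <- list(G0 = bend_pd(st1$G0), R0 = bend_pd(st1$R0))
    th1 <- vec_of(p1$G0, p1$R0)
    ll_trace <- c(ll_trace, st1$loglik)
    if (verbose) message(sprintf("iter %3d  logL = %.6f", iter, st1$loglik))
    r <- th1 - th0
    delta <- max(abs(r) / scale_of(p1$G0, p1$R0))
    dll <- st1$loglik - ll_prev
    ll_prev <- st1$loglik
    if (delta < tol || (iter > 2L && abs(dll) < tol)) {
      G0 <- p1$G0; R0 <- p1$R0
      converged <- TRUE
      break
    }
    if (accelerate && cycle > warmup_cycles) {
      # AI step from the current point
      sc <- reml_score(des, G0, R0, st1$G0, st1$R0)
      AI <- tryCatch(ai_information(des, G0, R0), error = function(e) NULL)
      move <- if (!is.null(AI)) {
        tryCatch(solve(AI, sc), error = function(e) NULL)
      }
      accepted <- FALSE
      if (!is.null(move) && all(is.finite(move))) {
        th <- theta_pack(G0, R0)
        for (h in 0:4) {
          cand <- theta_unpack(th + move / 2^h)
          # keep candidates well inside the parameter space: the
          # log-likelihood is numerically unreliable at near-singular
          # covariance matrices, so correlations are clamped to 0.995
          # (bending); non-positive variances force a shorter step
          if (any(diag(cand$G0) <= 0) || any(diag(cand$R0) <= 0)) next
          cand$G0 <- clamp_cor(cand$G0)
          cand$R0 <- clamp_cor(cand$R0)
          ll_c <- tryCatch(ll_of(cand$G0, cand$R0), error = function(e) -Inf)
          if (is.finite(ll_c) && ll_c >= st1$loglik) {
            G0 <- cand$G0; R0 <- cand$R0
            accepted <- TRUE
            break
          }
        }
      }
      if (!accepted) {
        G0 <- p1$G0; R0 <- p1$R0 # plain EM fallback (monotone)
      }
      next
    }
    # warm-up: second EM step + guarded extrapolation
    st2 <- em_step(p1$G0, p1$R0)
    iter <- iter + 1L
    p2 <- list(G0 = bend_pd(st2$G0), R0 = bend_pd(st2$R0))
    th2 <- vec_of(p2$G0, p2$R0)
    ll_trace <- c(ll_trace, st2$loglik)
    ll_prev <- st2$loglik
    nxt <- p2
    if (accelerate) {
      v <- th2 - 2 * th1 + th0
      if (sum(v^2) > 0) {
        alpha <- max(-sqrt(sum(r^2) / sum(v^2)), -64)
        if (alpha < -1) {
          cand <- unvec(th0 - 2 * alpha * r + alpha^2 * v)
          cand$G0 <- bend_pd(cand$G0)
          cand$R0 <- bend_pd(cand$R0)
          ll_cand <- tryCatch(ll_of(cand$G0, cand$R0),
                              error = function(e) -Inf)
          ll_p2 <- ll_of(p2$G0, p2$R0)
          if (is.finite(ll_cand) && ll_cand >= ll_p2) nxt <- cand
        }
      }
    }
    G0 <- nxt$G0
    R0 <- nxt$R0
  }
  if (!converged) {
    warning("EM-REML did not converge in ", max_iter,
            " iterations; returning the last iterate")
  }
  ll_final <- ll_of(G0, R0)
  ll_trace <- c(ll_trace, ll_final)

  h2 <- diag(G0) / (diag(G0) + diag(R0))
  rg <- if (nt == 2) G0[1, 2] / sqrt(G0[1, 1] * G0[2, 2]) else NA_real_
  P0 <- G0 + R0
  rp <- if (nt == 2) P0[1, 2] / sqrt(P0[1, 1] * P0[2, 2]) else NA_real_
  fit <- structure(list(
    G0 = G0, R0 = R0, h2 = h2, rg = rg, rp = rp,
    loglik = ll_trace, converged = converged, n_iter = iter,
    traits = des$traits, n_records = des$n_records, n_animals = des$q,
    design = des
  ), class = "reml_fit")
  if (se) {
    fit$vcov_theta <- ai_vcov(des, G0, R0)
    ses <- reml_standard_errors(fit)
    fit$se_h2 <- ses$se_h2
    fit$se_rg <- ses$se_rg
  }
  fit
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("<reml_fit> ", length(x$traits), " trait(s), ", x$n_records,
      " records, ", x$n_animals, " animals; ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$n_iter, " iterations\n", sep = "")
  for (t in seq_along(x$traits)) {
    cat(sprintf("  %s: sigma2_a = %.4g, sigma2_e = %.4g, h2 = %.3f%s\n",
                x$traits[t], x$G0[t, t], x$R0[t, t], x$h2[t],
                if (!is.null(x$se_h2)) sprintf(" (SE %.3f)", x$se_h2[t]) else ""))
  }
  if (length(x$traits) == 2) {
    cat(sprintf("  rg = %.3f%s, rp = %.3f\n", x$rg,
                if (!is.null(x$se_rg) && is.finite(x$se_rg))
                  sprintf(" (SE %.3f)", x$se_rg) else "", x$rp))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# design assembly

# One record per animal; per-trait observation sets; sparse incidences.
mme_design <- function(phenotypes, traits, kinv, fixed) {
  ph <- tibble::as_tibble(phenotypes)
  stopifnot(all(c("animal", traits) %in% names(ph)))
  if (!is.null(fixed) && !fixed %in% names(ph)) {
    stop("fixed-effect column '", fixed, "' not found")
  }
  if (anyDuplicated(ph$animal)) {
    stop("repeated records per animal are not supported by the animal model")
  }
  ids <- rownames(kinv)
  if (is.null(ids)) stop("kinv must carry animal ids as dimnames")
  missing <- setdiff(ph$animal, ids)
  if (length(missing)) {
    stop("phenotyped animals absent from the relationship matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  nt <- length(traits)
  stopifnot(nt %in% 1:2)
  q <- length(ids)
  lev <- if (is.null(fixed)) rep("(intercept)", nrow(ph)) else as.character(ph[[fixed]])
  obs <- lapply(seq_len(nt), function(t) which(!is.na(ph[[traits[t]]])))
  y <- lapply(seq_len(nt), function(t) ph[[traits[t]]][obs[[t]]])
  aidx <- lapply(seq_len(nt), function(t) match(ph$animal[obs[[t]]], ids))
  cg <- lapply(seq_len(nt), function(t) factor(lev[obs[[t]]]))
  for (t in seq_len(nt)) {
    if (!nlevels(cg[[t]])) stop("no fixed-effect levels for trait ", traits[t])
  }
  f <- vapply(cg, nlevels, 0L)
  # column layout: [beta_1 | beta_2 | a_1 | a_2]
  beta_off <- c(0L, cumsum(f))[seq_len(nt)]
  a_off <- sum(f) + (seq_len(nt) - 1L) * q
  P <- sum(f) + nt * q
  n_t <- lengths(obs)
  rec_off <- c(0L, cumsum(n_t))[seq_len(nt)]
  N <- sum(n_t)
  Ui <- integer(0); Uj <- integer(0)
  for (t in seq_len(nt)) {
    r <- rec_off[t] + seq_len(n_t[t])
    Ui <- c(Ui, r, r)
    Uj <- c(Uj, beta_off[t] + as.integer(cg[[t]]), a_off[t] + aidx[[t]])
  }
  U <- Matrix::sparseMatrix(i = Ui, j = Uj, x = 1, dims = c(N, P))
  equal_design <- nt == 2 && length(obs[[1]]) == length(obs[[2]]) &&
    all(obs[[1]] == obs[[2]]) && identical(levels(cg[[1]]), levels(cg[[2]]))
  # pattern partition over phenotyped animals (row index within ph)
  in_t <- lapply(seq_len(nt), function(t) !is.na(ph[[traits[t]]]))
  pat_both <- if (nt == 2) which(in_t[[1]] & in_t[[2]]) else integer(0)
  pat_only <- lapply(seq_len(nt), function(t) {
    if (nt == 2) which(in_t[[t]] & !in_t[[3 - t]]) else which(in_t[[t]])
  })
  # map: ph row -> record index, per trait
  map_t <- lapply(seq_len(nt), function(t) {
    m <- rep(NA_integer_, nrow(ph))
    m[obs[[t]]] <- rec_off[t] + seq_along(obs[[t]])
    m
  })
  Kinv <- Matrix::Matrix(kinv, sparse = TRUE)
  Kinv <- Matrix::forceSymmetric(Kinv)
  ldet_Kinv <- as.numeric(Matrix::determinant(Kinv, logarithm = TRUE)$modulus)
  list(ph = ph, traits = traits, nt = nt, ids = ids, q = q,
       y = y, obs = obs, aidx = aidx, cg = cg, f = f,
       beta_off = beta_off, a_off = a_off, P = P, n_t = n_t,
       rec_off = rec_off, N = N, U = U, map_t = map_t,
       equal_design = equal_design,
       pat_both = pat_both, pat_only = pat_only,
       Kinv = Kinv, ldet_Kinv = ldet_Kinv,
       n_records = sum(n_t),
       n_pheno_animals = sum(Reduce(`|`, in_t)))
}

# ---------------------------------------------------------------------------
# general path: one bivariate (or univariate) MME with per-animal R blocks

# sparse record-space R^-1 and log|R| for current R0
build_rinv <- function(des, R0) {
  nt <- des$nt
  map_t <- des$map_t
  if (nt == 1) {
    Rinv <- Matrix::Diagonal(des$N, 1 / R0[1, 1])
    return(list(Rinv = Rinv, ldet = des$N * log(R0[1, 1]), map_t = map_t))
  }
  W <- solve(R0)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  b <- des$pat_both
  if (length(b)) {
    r1 <- map_t[[1]][b]; r2 <- map_t[[2]][b]
    ii <- c(ii, r1, r2, r1, r2)
    jj <- c(jj, r1, r2, r2, r1)
    xx <- c(xx, rep(W[1, 1], length(b)), rep(W[2, 2], length(b)),
            rep(W[1, 2], length(b)), rep(W[2, 1], length(b)))
  }
  for (t in seq_len(nt)) {
    o <- des$pat_only[[t]]
    if (length(o)) {
      r <- map_t[[t]][o]
      ii <- c(ii, r); jj <- c(jj, r); xx <- c(xx, rep(1 / R0[t, t], length(o)))
    }
  }
  Rinv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                               dims = c(des$N, des$N))
  ldet <- length(b) * as.numeric(determinant(R0, logarithm = TRUE)$modulus) +
    sum(vapply(seq_len(nt), function(t) {
      length(des$pat_only[[t]]) * log(R0[t, t])
    }, 0))
  list(Rinv = Rinv, ldet = ldet, map_t = map_t)
}

# genetic prior block G0^-1 (x) Kinv as sparse, padded to the full MME
genetic_block <- function(des, G0) {
  G0inv <- solve(G0)
  if (des$nt == 1) {
    blk <- des$Kinv * G0inv[1, 1]
  } else {
    blk <- rbind(
      cbind(G0inv[1, 1] * des$Kinv, G0inv[1, 2] * des$Kinv),
      cbind(G0inv[2, 1] * des$Kinv, G0inv[2, 2] * des$Kinv)
    )
  }
  nf <- sum(des$f)
  Matrix::bdiag(Matrix::Matrix(0, nf, nf), blk)
}

assemble_mme_general <- function(des, G0, R0) {
  rr <- build_rinv(des, R0)
  yy <- unlist(des$y)
  RU <- rr$Rinv %*% des$U
  M <- Matrix::crossprod(des$U, RU) + genetic_block(des, G0)
  rhs <- as.numeric(Matrix::crossprod(RU, yy))
  list(M = as.matrix(Matrix::forceSymmetric(M)), rhs = rhs, rr = rr, yy = yy)
}

# -2 logL_R = log|R| + log|G| + log|C| + y'Py (all constants included)
reml_loglik_general <- function(des, G0, R0, parts = NULL) {
  if (is.null(parts)) parts <- assemble_mme_general(des, G0, R0)
  L <- chol_safe(parts$M)
  theta <- backsolve(L, forwardsolve(t(L), parts$rhs))
  yRy <- sum(parts$yy * as.numeric(parts$rr$Rinv %*% parts$yy))
  yPy <- yRy - sum(theta * parts$rhs)
  ldet_M <- 2 * sum(log(diag(L)))
  ldet_G <- des$q * as.numeric(determinant(G0, logarithm = TRUE)$modulus) -
    des$nt * des$ldet_Kinv
  -0.5 * (parts$rr$ldet + ldet_G + ldet_M + yPy)
}

em_step_general <- function(des, G0, R0) {
  parts <- assemble_mme_general(des, G0, R0)
  L <- chol_safe(parts$M)
  Cmat <- chol2inv(L)
  theta <- drop(Cmat %*% parts$rhs)
  nt <- des$nt
  q <- des$q
  # genetic update
  S_a <- matrix(0, nt, nt)
  a_hat <- lapply(seq_len(nt), function(t) theta[des$a_off[t] + seq_len(q)])
  for (i in seq_len(nt)) {
    for (j in i:nt) {
      Cij <- Cmat[des$a_off[i] + seq_len(q), des$a_off[j] + seq_len(q)]
      S_a[i, j] <- S_a[j, i] <-
        sum(a_hat[[i]] * as.numeric(des$Kinv %*% a_hat[[j]])) +
        sum(des$Kinv * Cij)
    }
  }
  G0_new <- S_a / q
  # residual update (conditional expectations for missing traits)
  fitted <- as.numeric(des$U %*% theta)
  ehat <- unlist(des$y) - fitted
  map_t <- parts$rr$map_t
  # design-column indices per ph row per trait
  colix <- lapply(seq_len(nt), function(t) {
    ci <- matrix(NA_integer_, nrow(des$ph), 2)
    ci[des$obs[[t]], 1] <- des$beta_off[t] + as.integer(des$cg[[t]])
    ci[des$obs[[t]], 2] <- des$a_off[t] + des$aidx[[t]]
    ci
  })
  hblock <- function(rows, t1, t2) {
    # (W C W') entries for the (t1, t2) record pair of the given ph rows
    c1 <- colix[[t1]][rows, , drop = FALSE]
    c2 <- colix[[t2]][rows, , drop = FALSE]
    Cmat[cbind(c1[, 1], c2[, 1])] + Cmat[cbind(c1[, 1], c2[, 2])] +
      Cmat[cbind(c1[, 2], c2[, 1])] + Cmat[cbind(c1[, 2], c2[, 2])]
  }
  S_e <- matrix(0, nt, nt)
  b <- des$pat_both
  if (length(b)) {
    e1 <- ehat[map_t[[1]][b]]
    e2 <- ehat[map_t[[2]][b]]
    S_e[1, 1] <- S_e[1, 1] + sum(e1^2 + hblock(b, 1, 1))
    S_e[2, 2] <- S_e[2, 2] + sum(e2^2 + hblock(b, 2, 2))
    cross <- sum(e1 * e2 + hblock(b, 1, 2))
    S_e[1, 2] <- S_e[1, 2] + cross
    S_e[2, 1] <- S_e[2, 1] + cross
  }
  for (t in seq_len(nt)) {
    o <- des$pat_only[[t]]
    if (!length(o)) next
    et <- ehat[map_t[[t]][o]]
    m2 <- et^2 + hblock(o, t, t)
    S_e[t, t] <- S_e[t, t] + sum(m2)
    if (nt == 2) {
      s <- 3 - t
      ratio <- R0[t, s] / R0[t, t]
      cross <- ratio * sum(m2)
      S_e[t, s] <- S_e[t, s] + cross
      S_e[s, t] <- S_e[s, t] + cross
      S_e[s, s] <- S_e[s, s] +
        length(o) * (R0[s, s] - R0[t, s]^2 / R0[t, t]) + ratio^2 * sum(m2)
    }
  }
  R0_new <- S_e / des$n_pheno_animals
  ll <- {
    yRy <- sum(parts$yy * as.numeric(parts$rr$Rinv %*% parts$yy))
    yPy <- yRy - sum(theta * parts$rhs)
    ldet_M <- 2 * sum(log(diag(L)))
    ldet_G <- des$q * as.numeric(determinant(G0, logarithm = TRUE)$modulus) -
      des$nt * des$ldet_Kinv
    -0.5 * (parts$rr$ldet + ldet_G + ldet_M + yPy)
  }
  list(G0 = G0_new, R0 = R0_new, loglik = ll, theta = theta, Cmat = Cmat,
       Lchol = L, parts = parts)
}

# ---------------------------------------------------------------------------
# canonical path (equal design, two traits): transform to independent
# univariate problems with unit residual variance

canonical_transform <- function(G0, R0) {
  Lr <- chol(R0) # R0 = Lr' Lr
  Lri <- backsolve(Lr, diag(2))
  B <- t(Lri) %*% G0 %*% Lri
  eb <- eigen((B + t(B)) / 2, symmetric = TRUE)
  Qt <- t(eb$vectors) %*% t(Lri) # y* = Qt y : Qt R0 Qt' = I, Qt G0 Qt' = diag
  list(Q = Qt, lambda = pmax(eb$values, 1e-12), Qinv = solve(Qt))
}

canonical_design <- function(des) {
  # univariate skeleton shared by both canonical traits
  rows <- des$obs[[1]]
  n <- length(rows)
  q <- des$q
  f <- des$f[1]
  Wi <- c(seq_len(n), seq_len(n))
  Wj <- c(as.integer(des$cg[[1]]), f + des$aidx[[1]])
  W <- Matrix::sparseMatrix(i = Wi, j = Wj, x = 1, dims = c(n, f + q))
  list(W = W, WtW = Matrix::crossprod(W), n = n, f = f, q = q,
       cgcol = as.integer(des$cg[[1]]), acol = f + des$aidx[[1]])
}

get_cdes <- function(des) {
  if (is.null(des$cdes_cache)) canonical_design(des) else des$cdes_cache
}

# solve one canonical univariate MME; return what EM and logL need
canonical_solve <- function(cdes, Kinv, lambda, ystar, want_inverse = TRUE) {
  f <- cdes$f
  q <- cdes$q
  M <- cdes$WtW + Matrix::bdiag(Matrix::Matrix(0, f, f), Kinv / lambda)
  M <- as.matrix(Matrix::forceSymmetric(M))
  rhs <- as.numeric(Matrix::crossprod(cdes$W, ystar))
  L <- chol_safe(M)
  theta <- backsolve(L, forwardsolve(t(L), rhs))
  out <- list(theta = theta, L = L, rhs = rhs,
              yPy = sum(ystar^2) - sum(theta * rhs),
              ldet_M = 2 * sum(log(diag(L))))
  if (want_inverse) out$Cmat <- chol2inv(L)
  out
}

em_step_canonical <- function(des, G0, R0) {
  ct <- canonical_transform(G0, R0)
  cdes <- get_cdes(des)
  q <- des$q
  n <- cdes$n
  f <- cdes$f
  y1 <- des$y[[1]]
  y2 <- des$y[[2]]
  a_hat <- vector("list", 2)
  stats_t <- vector("list", 2)
  ll <- 0
  for (t in 1:2) {
    ystar <- ct$Q[t, 1] * y1 + ct$Q[t, 2] * y2
    sol <- canonical_solve(cdes, des$Kinv, ct$lambda[t], ystar)
    ahat <- sol$theta[f + seq_len(q)]
    Caa <- sol$Cmat[f + seq_len(q), f + seq_len(q)]
    tr_KC <- sum(des$Kinv * Caa)
    ehat <- ystar - as.numeric(cdes$W %*% sol$theta)
    hrr <- sol$Cmat[cbind(cdes$cgcol, cdes$cgcol)] +
      2 * sol$Cmat[cbind(cdes$cgcol, cdes$acol)] +
      sol$Cmat[cbind(cdes$acol, cdes$acol)]
    a_hat[[t]] <- ahat
    stats_t[[t]] <- list(
      S_a = sum(ahat * as.numeric(des$Kinv %*% ahat)) + tr_KC,
      S_e = sum(ehat^2) + sum(hrr),
      ehat = ehat
    )
    # univariate -2logL pieces: log|R*| = 0
    ll <- ll + q * log(ct$lambda[t]) - des$ldet_Kinv + sol$ldet_M + sol$yPy
  }
  # cross terms: canonical traits are independent given y, so no traces
  s12 <- sum(a_hat[[1]] * as.numeric(des$Kinv %*% a_hat[[2]]))
  S_a <- matrix(c(stats_t[[1]]$S_a, s12, s12, stats_t[[2]]$S_a), 2, 2)
  S_e <- matrix(c(stats_t[[1]]$S_e,
                  sum(stats_t[[1]]$ehat * stats_t[[2]]$ehat),
                  sum(stats_t[[1]]$ehat * stats_t[[2]]$ehat),
                  stats_t[[2]]$S_e), 2, 2)
  G0_new <- ct$Qinv %*% (S_a / q) %*% t(ct$Qinv)
  R0_new <- ct$Qinv %*% (S_e / n) %*% t(ct$Qinv)
  # back to the original scale: Jacobian of the (n - f) error contrasts
  ldetQ <- as.numeric(determinant(ct$Q, logarithm = TRUE)$modulus)
  ll_orig <- -0.5 * (ll - 2 * (n - f) * ldetQ)
  list(G0 = (G0_new + t(G0_new)) / 2, R0 = (R0_new + t(R0_new)) / 2,
       loglik = ll_orig)
}

reml_loglik_canonical <- function(des, G0, R0) {
  ct <- canonical_transform(G0, R0)
  cdes <- get_cdes(des)
  f <- cdes$f
  n <- cdes$n
  ll <- 0
  for (t in 1:2) {
    ystar <- ct$Q[t, 1] * des$y[[1]] + ct$Q[t, 2] * des$y[[2]]
    sol <- canonical_solve(cdes, des$Kinv, ct$lambda[t], ystar,
                           want_inverse = FALSE)
    ll <- ll + des$q * log(ct$lambda[t]) - des$ldet_Kinv + sol$ldet_M + sol$yPy
  }
  ldetQ <- as.numeric(determinant(ct$Q, logarithm = TRUE)$modulus)
  -0.5 * (ll - 2 * (n - f) * ldetQ)
}

# ---------------------------------------------------------------------------
# shared numerics

chol_safe <- function(M) {
  out <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(out)) {
    out <- chol(M + diag(1e-8 * mean(diag(M)), nrow(M)))
  }
  out
}

# clamp the off-diagonal so that |correlation| <= max_cor (bending)
clamp_cor <- function(S, max_cor = 0.995) {
  if (nrow(S) == 1) return(S)
  lim <- max_cor * sqrt(S[1, 1] * S[2, 2])
  S[1, 2] <- S[2, 1] <- max(min(S[1, 2], lim), -lim)
  S
}

# eigenvalue floor ("bending") keeps covariance updates positive definite
bend_pd <- function(S, floor = 1e-8) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= floor * max(abs(e$values))) return(S)
  v <- pmax(e$values, floor * max(abs(e$values)))
  e$vectors %*% diag(v, length(v)) %*% t(e$vectors)
}

# ---------------------------------------------------------------------------
# average-information matrix and standard errors

# asymptotic covariance of (g11, g12, g22, r11, r12, r22) — or the
# univariate pair — from the average-information matrix at the optimum
ai_vcov <- function(des, G0, R0) {
  AI <- ai_information(des, G0, R0)
  np <- nrow(AI)
  V <- tryCatch(solve(AI), error = function(e) NULL)
  if (is.null(V)) {
    warning("singular average-information matrix; standard errors undefined")
    V <- matrix(NA_real_, np, np)
  }
  nm <- if (np == 6) c("g11", "g12", "g22", "r11", "r12", "r22") else c("g11", "r11")
  dimnames(V) <- list(nm, nm)
  V
}

# average-information matrix AI_ij = y'P V_i P V_j P y / 2 at (G0, R0);
# reuses an existing MME factorization when supplied
ai_information <- function(des, G0, R0, parts = NULL, L = NULL,
                           theta = NULL) {
  if (is.null(parts)) parts <- assemble_mme_general(des, G0, R0)
  if (is.null(L)) L <- chol_safe(parts$M)
  if (is.null(theta)) theta <- backsolve(L, forwardsolve(t(L), parts$rhs))
  Py <- as.numeric(parts$rr$Rinv %*% (parts$yy - as.numeric(des$U %*% theta)))
  nt <- des$nt
  map_t <- parts$rr$map_t
  pairs <- if (nt == 2) list(c(1, 1), c(1, 2), c(2, 2)) else list(c(1, 1))
  # genetic derivative directions: V_g Py = Z (E_ij x K) Z' Py
  ZtPy <- lapply(seq_len(nt), function(t) {
    v <- numeric(des$q)
    vals <- Py[des$rec_off[t] + seq_along(des$obs[[t]])]
    tapply_add(v, des$aidx[[t]], vals)
  })
  KZtPy <- lapply(ZtPy, function(v) {
    as.numeric(Matrix::solve(des$Kinv, v))
  })
  fvec <- list()
  for (pr in pairs) {
    i <- pr[1]; j <- pr[2]
    v <- numeric(des$N)
    for (t in seq_len(nt)) {
      contrib <- numeric(des$q)
      if (t == i) contrib <- contrib + KZtPy[[j]]
      if (t == j && i != j) contrib <- contrib + KZtPy[[i]]
      if (i == j && t == i) contrib <- KZtPy[[i]]
      if (any(contrib != 0)) {
        v[des$rec_off[t] + seq_along(des$obs[[t]])] <-
          contrib[des$aidx[[t]]]
      }
    }
    fvec[[length(fvec) + 1]] <- v
  }
  # residual derivative directions: V_r Py on matching record pairs
  for (pr in pairs) {
    i <- pr[1]; j <- pr[2]
    v <- numeric(des$N)
    # records observed for BOTH i and j (for i == j: all records of i)
    rows <- if (i == j) des$obs[[i]] else intersect(des$obs[[i]], des$obs[[j]])
    if (length(rows)) {
      ri <- map_t[[i]][rows]
      rj <- map_t[[j]][rows]
      v[ri] <- v[ri] + Py[rj]
      if (i != j) v[rj] <- v[rj] + Py[ri]
    }
    fvec[[length(fvec) + 1]] <- v
  }
  np <- length(fvec)
  # P f = Rinv (f - U C U' Rinv f)
  Pf <- lapply(fvec, function(fv) {
    rf <- as.numeric(parts$rr$Rinv %*% fv)
    rhs2 <- as.numeric(Matrix::crossprod(des$U, rf))
    th2 <- backsolve(L, forwardsolve(t(L), rhs2))
    as.numeric(parts$rr$Rinv %*% (fv - as.numeric(des$U %*% th2)))
  })
  AI <- matrix(0, np, np)
  for (a in seq_len(np)) {
    for (b in a:np) {
      AI[a, b] <- AI[b, a] <- 0.5 * sum(fvec[[a]] * Pf[[b]])
    }
  }
  AI
}

# REML score in the (g11, g12, g22, r11, r12, r22) basis via the Fisher
# identity: dl/dG0 = -(q G0^-1 - G0^-1 S_a G0^-1)/2 with S_a = q * G0_new
# from the EM step, and likewise for R0
reml_score <- function(des, G0, R0, G0_new, R0_new) {
  nt <- des$nt
  G0i <- solve(G0)
  R0i <- solve(R0)
  sg <- -0.5 * (des$q * G0i - G0i %*% (des$q * G0_new) %*% G0i)
  n_a <- des$n_pheno_animals
  sr <- -0.5 * (n_a * R0i - R0i %*% (n_a * R0_new) %*% R0i)
  if (nt == 1) return(c(sg[1, 1], sr[1, 1]))
  c(sg[1, 1], 2 * sg[1, 2], sg[2, 2], sr[1, 1], 2 * sr[1, 2], sr[2, 2])
}

theta_pack <- function(G0, R0) {
  if (nrow(G0) == 1) return(c(G0[1, 1], R0[1, 1]))
  c(G0[1, 1], G0[1, 2], G0[2, 2], R0[1, 1], R0[1, 2], R0[2, 2])
}

theta_unpack <- function(v) {
  if (length(v) == 2) {
    return(list(G0 = matrix(v[1], 1, 1), R0 = matrix(v[2], 1, 1)))
  }
  list(G0 = matrix(c(v[1], v[2], v[2], v[3]), 2, 2),
       R0 = matrix(c(v[4], v[5], v[5], v[6]), 2, 2))
}

tapply_add <- function(v, idx, vals) {
  s <- rowsum(vals, idx)
  v[as.integer(rownames(s))] <- v[as.integer(rownames(s))] + s[, 1]
  v
}

#' Approximate standard errors of heritability and genetic correlation
#'
#' Delta-method propagation of the average-information asymptotic
#' covariance of the variance components to `h2` (per trait) and `rg`.
#'
#' @param fit a converged [reml_estimate()] fit with `vcov_theta`.
#' @return A list with `se_h2` (per trait) and `se_rg`.
#' @export
reml_standard_errors <- function(fit) {
  V <- fit$vcov_theta
  if (is.null(V)) {
    fit$vcov_theta <- ai_vcov(fit$design, fit$G0, fit$R0)
    V <- fit$vcov_theta
  }
  nt <- length(fit$traits)
  if (anyNA(V)) {
    return(list(se_h2 = rep(NA_real_, nt), se_rg = NA_real_))
  }
  G0 <- fit$G0
  R0 <- fit$R0
  se_h2 <- numeric(nt)
  for (t in seq_len(nt)) {
    g <- G0[t, t]; r <- R0[t, t]
    # h2 = g/(g + r): gradient in (g, r)
    grad <- stats::setNames(numeric(ncol(V)), colnames(V))
    gname <- if (nt == 2) paste0("g", t, t) else "g11"
    rname <- if (nt == 2) paste0("r", t, t) else "r11"
    grad[gname] <- r / (g + r)^2
    grad[rname] <- -g / (g + r)^2
    se_h2[t] <- sqrt(drop(t(grad) %*% V %*% grad))
  }
  se_rg <- NA_real_
  if (nt == 2) {
    g11 <- G0[1, 1]; g22 <- G0[2, 2]; g12 <- G0[1, 2]
    grad <- stats::setNames(numeric(ncol(V)), colnames(V))
    grad["g12"] <- 1 / sqrt(g11 * g22)
    grad["g11"] <- -0.5 * g12 / (g11^1.5 * sqrt(g22))
    grad["g22"] <- -0.5 * g12 / (g22^1.5 * sqrt(g11))
    se_rg <- sqrt(drop(t(grad) %*% V %*% grad))
  }
  list(se_h2 = se_h2, se_rg = se_rg)
}
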