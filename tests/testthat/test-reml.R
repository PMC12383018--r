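# direct-V oracle for the restricted log-likelihood on small instances:
# -2 logL = log|V| + log|X'V^-1 X| + y'Py with V = Z G Z' + R assembled
# densely on the original scale
direct_reml_loglik <- function(ph, traits, kinv, G0, R0, fixed = "cg") {
  nt <- length(traits)
  K <- solve(as.matrix(kinv))
  ids <- rownames(kinv)
  obs <- lapply(seq_len(nt), function(t) which(!is.na(ph[[traits[t]]])))
  y <- unlist(lapply(seq_len(nt), function(t) ph[[traits[t]]][obs[[t]]]))
  Xs <- list(); Zs <- list()
  for (t in seq_len(nt)) {
    cg <- factor(ph[[fixed]][obs[[t]]])
    Xs[[t]] <- stats::model.matrix(~ 0 + cg)
    Z <- matrix(0, length(obs[[t]]), length(ids))
    Z[cbind(seq_along(obs[[t]]), match(ph$animal[obs[[t]]], ids))] <- 1
    Zs[[t]] <- Z
  }
  X <- Matrix::.bdiag(Xs)
  X <- as.matrix(X)
  n_t <- lengths(obs)
  V <- matrix(0, sum(n_t), sum(n_t))
  off <- c(0, cumsum(n_t))
  for (t1 in seq_len(nt)) {
    for (t2 in seq_len(nt)) {
      r1 <- off[t1] + seq_len(n_t[t1])
      r2 <- off[t2] + seq_len(n_t[t2])
      V[r1, r2] <- V[r1, r2] + G0[t1, t2] * Zs[[t1]] %*% K %*% t(Zs[[t2]])
      # residual covariance only for records of the same animal
      Rblk <- R0[t1, t2] *
        (outer(ph$animal[obs[[t1]]], ph$animal[obs[[t2]]], `==`) * 1)
      if (t1 != t2 || TRUE) V[r1, r2] <- V[r1, r2] + Rblk
    }
  }
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  -0.5 * (determinant(V, logarithm = TRUE)$modulus +
            determinant(XVX, logarithm = TRUE)$modulus +
            drop(t(y) %*% P %*% y))
}

make_reml_data <- function(n_fam = 30, kids = 4, h2 = c(0.4, 0.1),
                           rg = 0.5, re = 0.3, seed = 1, drop2 = 0) {
  cfg <- sim_config(n_founders = 2 * n_fam, n_generations = 1,
                    offspring_per_mating = kids, unknown_parent_rate = 0,
                    n_snps = 40, n_qtl = 0, qtl_variance_fraction = 0,
                    h2 = h2, rg = rg, re = re,
                    trait_means = c(0, 0), trait_sds = c(1, 1),
                    n_contemporary_groups = 3, cg_sd = 0.3,
                    prop_phenotyped = 1, seed = seed)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_phenotypes(ped, simulate_genotypes(ped, cfg), cfg)
  ph <- sim$phenotypes
  if (drop2 > 0) { # make the design unbalanced: drop trait 2 for a subset
    set.seed(seed + 99)
    ph$trait2[sample(nrow(ph), round(drop2 * nrow(ph)))] <- NA
  }
  list(ped = ped, ph = ph, kinv = build_A_inverse(ped), truth = sim$truth)
}

test_that("MME-based restricted log-likelihood matches the dense-V oracle", {
  d <- make_reml_data(n_fam = 8, kids = 2, seed = 3, drop2 = 0.3)
  G0 <- matrix(c(0.5, 0.1, 0.1, 0.3), 2)
  R0 <- matrix(c(0.7, 0.15, 0.15, 0.9), 2)
  des <- stepblup:::mme_design(d$ph, c("trait1", "trait2"), d$kinv, "cg")
  expect_equal(stepblup:::reml_loglik_general(des, G0, R0),
               direct_reml_loglik(d$ph, c("trait1", "trait2"), d$kinv, G0, R0),
               tolerance = 1e-8, ignore_attr = TRUE)
  # univariate
  des1 <- stepblup:::mme_design(d$ph, "trait1", d$kinv, "cg")
  expect_equal(stepblup:::reml_loglik_general(des1, G0[1, 1, drop = FALSE],
                                              R0[1, 1, drop = FALSE]),
               direct_reml_loglik(d$ph, "trait1", d$kinv,
                                  G0[1, 1, drop = FALSE],
                                  R0[1, 1, drop = FALSE]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("canonical and general paths agree on likelihood and EM map", {
  d <- make_reml_data(n_fam = 10, kids = 2, seed = 5)
  G0 <- matrix(c(0.5, 0.1, 0.1, 0.3), 2)
  R0 <- matrix(c(0.7, 0.15, 0.15, 0.9), 2)
  des <- stepblup:::mme_design(d$ph, c("trait1", "trait2"), d$kinv, "cg")
  expect_true(des$equal_design)
  expect_equal(stepblup:::reml_loglik_canonical(des, G0, R0),
               stepblup:::reml_loglik_general(des, G0, R0),
               tolerance = 1e-8)
  st_c <- stepblup:::em_step_canonical(des, G0, R0)
  st_g <- stepblup:::em_step_general(des, G0, R0)
  expect_equal(st_c$G0, st_g$G0, tolerance = 1e-6)
  expect_equal(st_c$R0, st_g$R0, tolerance = 1e-6)
  expect_equal(st_c$loglik, st_g$loglik, tolerance = 1e-8)
})

test_that("EM-REML log-likelihood is monotone and the optimum is a fixed point", {
  d <- make_reml_data(n_fam = 20, kids = 3, seed = 7, drop2 = 0.25)
  fit <- reml_estimate(d$ph, c("trait1", "trait2"), d$kinv,
                       tol = 1e-7, se = FALSE)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik) > -1e-8))
  # restart from the converged point: one EM step barely moves h2/rg
  des <- fit$design
  st <- stepblup:::em_step_general(des, fit$G0, fit$R0)
  h2_step <- diag(st$G0) / (diag(st$G0) + diag(st$R0))
  expect_lt(max(abs(h2_step - fit$h2)), 1e-3)
  # estimates are permutation invariant in record order
  set.seed(1)
  perm <- sample(nrow(d$ph))
  fit2 <- reml_estimate(d$ph[perm, ], c("trait1", "trait2"), d$kinv,
                        tol = 1e-7, se = FALSE)
  expect_equal(fit2$G0, fit$G0, tolerance = 1e-4)
  expect_equal(fit2$R0, fit$R0, tolerance = 1e-4)
})

test_that("null and near-deterministic heritabilities are recovered", {
  null_hits <- 0
  high_hits <- 0
  reps <- 6
  for (r in seq_len(reps)) {
    d0 <- make_reml_data(n_fam = 40, kids = 4, h2 = c(0.011, 0.011),
                         rg = 0, re = 0, seed = 20 + r)
    f0 <- reml_estimate(d0$ph, "trait1", d0$kinv, tol = 1e-6, se = FALSE,
                        max_iter = 200)
    if (f0$h2[1] < 0.1) null_hits <- null_hits + 1
    d1 <- make_reml_data(n_fam = 40, kids = 4, h2 = c(0.95, 0.95),
                         rg = 0, re = 0, seed = 40 + r)
    f1 <- reml_estimate(d1$ph, "trait1", d1$kinv, tol = 1e-6, se = FALSE,
                        max_iter = 200)
    if (f1$h2[1] > 0.8) high_hits <- high_hits + 1
  }
  expect_gte(null_hits, reps - 1)
  expect_gte(high_hits, reps - 1)
})

test_that("univariate fit matches trait-1 of an uncorrelated bivariate fit", {
  d <- make_reml_data(n_fam = 40, kids = 3, h2 = c(0.4, 0.2), rg = 0,
                      re = 0, seed = 77)
  fb <- reml_estimate(d$ph, c("trait1", "trait2"), d$kinv, tol = 1e-6,
                      se = FALSE)
  fu <- reml_estimate(d$ph, "trait1", d$kinv, tol = 1e-6, se = FALSE)
  expect_equal(fu$G0[1, 1], fb$G0[1, 1], tolerance = 0.15)
  expect_equal(fu$h2[1], fb$h2[1], tolerance = 0.1)
})

test_that("standard errors are positive, shrink with n, and match a numerical Jacobian", {
  d <- make_reml_data(n_fam = 30, kids = 3, seed = 9)
  fit <- reml_estimate(d$ph, c("trait1", "trait2"), d$kinv, tol = 1e-6)
  expect_true(all(fit$se_h2 > 0))
  expect_true(fit$se_rg > 0)

  # delta-method h2 SE vs central-difference Jacobian through h2(theta)
  V <- fit$vcov_theta
  th <- c(g11 = fit$G0[1, 1], g12 = fit$G0[1, 2], g22 = fit$G0[2, 2],
          r11 = fit$R0[1, 1], r12 = fit$R0[1, 2], r22 = fit$R0[2, 2])
  h2_fun <- function(v) v["g11"] / (v["g11"] + v["r11"])
  rg_fun <- function(v) v["g12"] / sqrt(v["g11"] * v["g22"])
  num_se <- function(fun) {
    grad <- vapply(seq_along(th), function(k) {
      h <- max(1e-6, 1e-6 * abs(th[k]))
      tp <- th; tp[k] <- tp[k] + h
      tm <- th; tm[k] <- tm[k] - h
      (fun(tp) - fun(tm)) / (2 * h)
    }, 0)
    sqrt(drop(t(grad) %*% V %*% grad))
  }
  expect_equal(fit$se_h2[1], num_se(h2_fun), tolerance = 0.05)
  expect_equal(fit$se_rg, num_se(rg_fun), tolerance = 0.05)

  # larger n gives smaller SE on the same generator
  d_big <- make_reml_data(n_fam = 90, kids = 3, seed = 9)
  fit_big <- reml_estimate(d_big$ph, c("trait1", "trait2"), d_big$kinv,
                           tol = 1e-6)
  expect_lt(fit_big$se_h2[1], fit$se_h2[1])
})

test_that("tidy() and glance() expose the usual summaries", {
  d <- make_reml_data(n_fam = 20, kids = 3, seed = 13)
  fit <- reml_estimate(d$ph, c("trait1", "trait2"), d$kinv, tol = 1e-6)
  td <- tidy(fit)
  expect_setequal(unique(td$term),
                  c("sigma2_a", "sigma2_e", "h2", "sigma_a12", "sigma_e12",
                    "rg", "rp"))
  expect_true(all(td$estimate[td$term == "h2"] > 0 &
                    td$estimate[td$term == "h2"] < 1))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
})
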