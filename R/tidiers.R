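#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a REML fit
#'
#' One row per estimated quantity: additive and residual (co)variances,
#' heritabilities, genetic and phenotypic correlations, with approximate
#' standard errors where available.
#'
#' @param x a [reml_estimate()] fit.
#' @param ... unused.
#' @return A tibble `(term, trait, estimate, std_error)`.
#' @export
tidy.reml_fit <- function(x, ...) {
  nt <- length(x$traits)
  rows <- list()
  add <- function(term, trait, est, se = NA_real_) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      term = term, trait = trait, estimate = est, std_error = se)
  }
  V <- x$vcov_theta
  se_of <- function(nm) {
    if (is.null(V) || anyNA(V) || !nm %in% colnames(V)) NA_real_
    else sqrt(V[nm, nm])
  }
  for (t in seq_len(nt)) {
    gname <- if (nt == 2) paste0("g", t, t) else "g11"
    rname <- if (nt == 2) paste0("r", t, t) else "r11"
    add("sigma2_a", x$traits[t], x$G0[t, t], se_of(gname))
    add("sigma2_e", x$traits[t], x$R0[t, t], se_of(rname))
    add("h2", x$traits[t], x$h2[t],
        if (!is.null(x$se_h2)) x$se_h2[t] else NA_real_)
  }
  if (nt == 2) {
    add("sigma_a12", NA_character_, x$G0[1, 2], se_of("g12"))
    add("sigma_e12", NA_character_, x$R0[1, 2], se_of("r12"))
    add("rg", NA_character_, x$rg,
        if (!is.null(x$se_rg)) x$se_rg else NA_real_)
    add("rp", NA_character_, x$rp)
  }
  dplyr::bind_rows(rows)
}

#' Glance at a REML fit
#'
#' @param x a [reml_estimate()] fit.
#' @param ... unused.
#' @return A one-row tibble with the log-likelihood, iteration count,
#'   convergence flag, and headline genetic parameters.
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik[length(x$loglik)],
    n_iter = x$n_iter,
    converged = x$converged,
    n_records = x$n_records,
    n_animals = x$n_animals,
    h2_1 = x$h2[1],
    h2_2 = if (length(x$h2) == 2) x$h2[2] else NA_real_,
    rg = x$rg,
    rp = x$rp
  )
}

#' Tidy a breeding-value evaluation
#'
#' @param x a [solve_mme()] fit.
#' @param ... unused.
#' @return The per-animal x trait tibble of predictions, PEV and accuracy.
#' @export
tidy.blup_fit <- function(x, ...) x$predictions

#' Glance at a breeding-value evaluation
#'
#' @param x a [solve_mme()] fit.
#' @param ... unused.
#' @return A one-row tibble of solver metadata and accuracy summaries.
#' @export
glance.blup_fit <- function(x, ...) {
  pr <- x$predictions
  tibble::tibble(
    method = x$method,
    n_animals = dplyr::n_distinct(pr$animal),
    n_traits = dplyr::n_distinct(pr$trait),
    mean_accuracy = mean(pr$accuracy, na.rm = TRUE),
    residual_norm = x$residual_norm
  )
}
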