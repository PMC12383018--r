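#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Manhattan-style plot of window variance percentages
#'
#' @param object a [window_variance()] result.
#' @param threshold_pct optional horizontal significance line.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.window_result <- function(object, threshold_pct = NULL, ...) {
  df <- tibble::as_tibble(object)
  chr_order <- unique(df$chr)
  df$chr <- factor(df$chr, levels = chr_order)
  # cumulative genome coordinate
  offs <- c(0, cumsum(tapply(df$end_bp, df$chr, max)))
  df$x <- (df$start_bp + df$end_bp) / 2 + offs[as.integer(df$chr)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x,
                                        y = .data$variance_pct,
                                        colour = .data$chr)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::labs(x = "genome position",
                  y = "% of additive genetic variance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (!is.null(threshold_pct)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold_pct,
                                 linetype = "dashed")
  }
  p
}

#' Convergence trace of a REML fit
#'
#' @param object a [reml_estimate()] fit.
#' @param ... unused.
#' @return A ggplot of the restricted log-likelihood per iteration.
#' @export
autoplot.reml_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$loglik),
                       loglik = object$loglik)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "EM iteration", y = "restricted log-likelihood") +
    ggplot2::theme_minimal()
}

#' Scatter of two evaluations' breeding values
#'
#' @param ebv,gebv [solve_mme()] fits.
#' @param trait trait to plot.
#' @param animals optional subset of animal ids.
#' @return A ggplot with the identity line.
#' @export
plot_evaluation_comparison <- function(ebv, gebv, trait, animals = NULL) {
  p1 <- ebv$predictions[ebv$predictions$trait == trait, ]
  p2 <- gebv$predictions[gebv$predictions$trait == trait, ]
  d <- dplyr::inner_join(dplyr::select(p1, "animal", ebv = "bv"),
                         dplyr::select(p2, "animal", gebv = "bv"),
                         by = "animal")
  if (!is.null(animals)) d <- d[d$animal %in% animals, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ebv, y = .data$gebv)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "EBV (pedigree)", y = "GEBV (single-step)",
                  title = trait) +
    ggplot2::theme_minimal()
}

#' Per-SNP effect plot
#'
#' @param effects tibble from [backsolve_snp_effects()] (optionally with a
#'   `trait` column for facetting).
#' @param map SNP map aligned with the effects.
#' @return A ggplot of effects along the genome.
#' @export
plot_snp_effects <- function(effects, map) {
  d <- dplyr::inner_join(effects, map, by = "snp")
  chr_order <- unique(map$chr)
  d$chr <- factor(d$chr, levels = chr_order)
  offs <- c(0, cumsum(tapply(map$pos, factor(map$chr, chr_order), max)))
  d$x <- d$pos + offs[as.integer(d$chr)]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$effect,
                                       colour = .data$chr)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "genome position", y = "SNP effect") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if ("trait" %in% names(d)) {
    p <- p + ggplot2::facet_wrap(~trait, ncol = 1, scales = "free_y")
  }
  p
}
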