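#' Map significant SNPs to nearby genes
#'
#' For each significant SNP, finds every gene on the same chromosome
#' whose span lies within `max_dist` bp (inclusive).  The distance is 0
#' ("on target") when the SNP falls inside the gene's 1-based inclusive
#' span; otherwise it is signed — negative when the gene lies at lower
#' coordinates (5' of the SNP), positive when at higher coordinates.
#' Genes are aggregated per trait and a gene hit by significant SNPs of
#' both traits is flagged pleiotropic.
#'
#' A purely tabular operation: deterministic and invariant to the order
#' of SNPs and genes.  SNPs on chromosomes absent from the gene table
#' simply yield no hits (a message reports how many).
#'
#' @param snps tibble `(snp, chr, pos, trait)` of significant SNPs (one
#'   row per SNP x trait; e.g. [window_snps()] output with a `trait`
#'   column added).
#' @param genes gene table `(gene, chr, start, end)` (see
#'   [read_gene_table()]).
#' @param max_dist maximum SNP-gene gap in bp, inclusive.
#' @return A tibble `(snp, chr, pos, trait, gene, gene_start, gene_end,
#'   distance_bp, pleiotropic)`, sorted by chromosome, SNP position and
#'   |distance|.
#' @export
annotate_candidates <- function(snps, genes, max_dist = 50000) {
  snps <- tibble::as_tibble(snps)
  genes <- tibble::as_tibble(genes)
  stopifnot(all(c("snp", "chr", "pos", "trait") %in% names(snps)),
            all(c("gene", "chr", "start", "end") %in% names(genes)))
  orphan <- setdiff(unique(snps$chr), unique(genes$chr))
  if (length(orphan)) {
    message("annotate_candidates: no genes on chromosome(s) ",
            paste(orphan, collapse = ", "), "; ",
            sum(snps$chr %in% orphan), " SNP(s) get no hits")
  }
  hits <- dplyr::inner_join(snps, genes, by = "chr",
                            relationship = "many-to-many")
  hits$distance_bp <- dplyr::case_when(
    hits$pos >= hits$start & hits$pos <= hits$end ~ 0,
    hits$end < hits$pos ~ -(hits$pos - hits$end),
    TRUE ~ hits$start - hits$pos
  )
  hits <- hits[abs(hits$distance_bp) <= max_dist, ]
  if (!nrow(hits)) {
    return(tibble::tibble(snp = character(), chr = character(),
                          pos = numeric(), trait = character(),
                          gene = character(), gene_start = numeric(),
                          gene_end = numeric(), distance_bp = numeric(),
                          pleiotropic = logical()))
  }
  gene_traits <- dplyr::summarise(
    dplyr::group_by(hits, .data$gene),
    n_traits = dplyr::n_distinct(.data$trait), .groups = "drop")
  out <- dplyr::left_join(hits, gene_traits, by = "gene")
  out$pleiotropic <- out$n_traits >= 2
  out <- dplyr::select(out, snp = "snp", chr = "chr", pos = "pos",
                       trait = "trait", gene = "gene",
                       gene_start = "start", gene_end = "end",
                       distance_bp = "distance_bp",
                       pleiotropic = "pleiotropic")
  dplyr::arrange(out, .data$chr, .data$pos, abs(.data$distance_bp),
                 .data$gene, .data$trait)
}

#' Pleiotropy summary
#'
#' One row per candidate gene, with per-trait hit flags and the closest
#' significant SNP (smallest |distance|, ties broken by SNP name) per
#' trait.
#'
#' @param hits output of [annotate_candidates()].
#' @return A tibble `(gene, chr, pleiotropic, traits, <trait>_best_snp,
#'   <trait>_best_distance_bp, ...)`, one row per gene.
#' @export
pleiotropy_summary <- function(hits) {
  if (!nrow(hits)) {
    return(tibble::tibble(gene = character(), chr = character(),
                          pleiotropic = logical(), traits = character()))
  }
  best <- dplyr::ungroup(dplyr::slice(
    dplyr::arrange(dplyr::group_by(hits, .data$gene, .data$trait),
                   abs(.data$distance_bp), .data$snp), 1))
  wide <- tidyr::pivot_wider(
    dplyr::select(best, "gene", "chr", "trait", "snp", "distance_bp"),
    names_from = "trait",
    values_from = c("snp", "distance_bp"),
    names_glue = "{trait}_{.value}")
  info <- dplyr::summarise(
    dplyr::group_by(hits, .data$gene),
    chr = dplyr::first(.data$chr),
    pleiotropic = dplyr::first(.data$pleiotropic),
    traits = paste(sort(unique(.data$trait)), collapse = "+"),
    .groups = "drop")
  out <- dplyr::left_join(info, dplyr::select(wide, -"chr"), by = "gene")
  dplyr::arrange(out, .data$chr, .data$gene)
}
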