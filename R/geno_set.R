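#' Genotype set container
#'
#' A light container for an animals x SNPs matrix of allele counts
#' (0/1/2, `NA` = missing call) together with its SNP map.  Rows are
#' named by animal id; the map is a tibble `(snp, chr, pos)` with
#' 1-based bp positions, non-decreasing within chromosome.
#'
#' @param calls integer/numeric matrix, rownames = animal ids.
#' @param map tibble with columns `snp`, `chr`, `pos`.
#' @return An object of class `geno_set`.
#' @export
geno_set <- function(calls, map) {
  calls <- as.matrix(calls)
  stopifnot(!is.null(rownames(calls)))
  map <- tibble::as_tibble(map)
  stopifnot(all(c("snp", "chr", "pos") %in% names(map)),
            nrow(map) == ncol(calls))
  if (anyDuplicated(map$snp)) stop("duplicated SNP names in map")
  bad <- calls[!is.na(calls) & !(calls %in% c(0, 1, 2))]
  if (length(bad)) {
    stop("genotype calls outside {0, 1, 2, NA}: e.g. ", bad[1])
  }
  ok <- unlist(lapply(split(map$pos, map$chr), function(p) all(diff(p) >= 0)))
  if (!all(ok)) {
    stop("SNP positions decrease within chromosome(s): ",
         paste(names(ok)[!ok], collapse = ", "))
  }
  colnames(calls) <- map$snp
  structure(list(calls = calls, map = map), class = "geno_set")
}

#' @export
print.geno_set <- function(x, ...) {
  cat("<geno_set> ", nrow(x$calls), " animals x ", ncol(x$calls), " SNPs, ",
      dplyr::n_distinct(x$map$chr), " chromosome(s), ",
      sprintf("%.2f%%", 100 * mean(is.na(x$calls))), " missing\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_set <- function(x) dim(x$calls)

#' Animal ids of a genotype set
#' @param geno a [geno_set()].
#' @return Character vector of animal ids (row order).
#' @export
geno_animals <- function(geno) rownames(geno$calls)

#' Subset a genotype set
#'
#' @param geno a [geno_set()].
#' @param animals character vector of animal ids (default: keep all).
#' @param snps character vector of SNP names (default: keep all).
#' @return A `geno_set` restricted to the requested rows/columns,
#'   preserving the order given.
#' @export
geno_subset <- function(geno, animals = NULL, snps = NULL) {
  calls <- geno$calls
  map <- geno$map
  if (!is.null(animals)) {
    missing <- setdiff(animals, rownames(calls))
    if (length(missing)) {
      stop("animals absent from genotype set: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    calls <- calls[animals, , drop = FALSE]
  }
  if (!is.null(snps)) {
    keep <- match(snps, map$snp)
    if (anyNA(keep)) stop("SNPs absent from genotype set")
    calls <- calls[, keep, drop = FALSE]
    map <- map[keep, ]
  }
  geno_set(calls, map)
}

#' Observed allele frequencies
#'
#' Per-SNP frequency of the counted allele, `p = mean(calls) / 2` over
#' non-missing calls.
#'
#' @param geno a [geno_set()].
#' @return Numeric vector of frequencies, one per SNP.
#' @export
allele_freq <- function(geno) {
  colMeans(geno$calls, na.rm = TRUE) / 2
}
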