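#' Read a pedigree file
#'
#' Three whitespace/tab-separated columns (animal, sire, dam); a header row
#' is auto-detected.  Unknown parents are coded `0` or empty.  The result
#' is validated and topologically ordered by [as_pedigree()]: cycles are a
#' hard error, parents never declared as animals are added as founders
#' with a warning.
#'
#' @param path file path.
#' @return A `pedigree` tibble (see [as_pedigree()]).
#' @export
read_pedigree <- function(path) {
  lines <- read_nonempty_lines(path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    stop("pedigree file ", path, ": expected 3 columns at line ", bad[1])
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:3))
  if (tolower(m[1, 1]) %in% c("animal", "id", "animal_id")) m <- m[-1, , drop = FALSE]
  ped <- as_pedigree(tibble::tibble(animal = m[, 1], sire = m[, 2], dam = m[, 3]))
  unk <- mean(is.na(ped$sire) | is.na(ped$dam))
  message(sprintf("read_pedigree: %d animals, %.1f%% with at least one unknown parent",
                  nrow(ped), 100 * unk))
  ped
}

#' Write a pedigree file
#'
#' @param ped a `pedigree` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(animal = ped$animal,
                    sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam = ifelse(is.na(ped$dam), "0", ped$dam))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes
#'
#' Two dialects:
#' * `simple`: one line per animal, `id` then whitespace, then a contiguous
#'   string of calls over `{0,1,2,5}` with `5` = missing.
#' * `plink_raw`: PLINK `--recode A` output (header `FID IID PAT MAT SEX
#'   PHENOTYPE <snp>...`, calls 0/1/2, `NA` = missing).
#'
#' If no SNP map is supplied a placeholder map is created (chromosome
#' `"U"`, positions 1..m); supply the true map for window-based analyses.
#'
#' @param path file path.
#' @param dialect `"simple"` or `"plink_raw"`.
#' @param map optional SNP map tibble `(snp, chr, pos)`.
#' @return A [geno_set()].
#' @export
read_genotypes <- function(path, dialect = c("simple", "plink_raw"),
                           map = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "simple") {
    lines <- read_nonempty_lines(path)
    parts <- regmatches(lines, regexpr("[ \t]+", lines), invert = TRUE)
    bad <- which(lengths(parts) != 2)
    if (length(bad)) {
      stop("genotype file ", path, ": expected 'id calls' at line ", bad[1])
    }
    ids <- vapply(parts, `[`, "", 1)
    strs <- vapply(parts, `[`, "", 2)
    widths <- nchar(strs)
    if (length(unique(widths)) != 1) {
      stop("genotype file ", path, ": ragged call strings at line ",
           which(widths != widths[1])[1])
    }
    chars <- strsplit(strs, "")
    bad_call <- vapply(chars, function(x) {
      w <- which(!x %in% c("0", "1", "2", "5"))
      if (length(w)) w[1] else 0L
    }, 0L)
    if (any(bad_call > 0)) {
      l <- which(bad_call > 0)[1]
      stop("genotype file ", path, ": invalid call '",
           chars[[l]][bad_call[l]], "' at line ", l)
    }
    calls <- do.call(rbind, lapply(chars, as.integer))
    calls[calls == 5L] <- NA_integer_
    rownames(calls) <- ids
  } else {
    tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(need %in% names(tab)[1:6])) {
      stop("genotype file ", path, ": not a PLINK .raw header")
    }
    calls <- as.matrix(tab[, -(1:6), drop = FALSE])
    storage.mode(calls) <- "integer"
    rownames(calls) <- as.character(tab$IID)
    # strip the _<allele> suffix PLINK appends to SNP names
    colnames(calls) <- sub("_[ACGT0-9]+$", "", colnames(calls))
    ok <- is.na(calls) | calls %in% 0:2
    if (!all(ok)) {
      stop("genotype file ", path, ": call outside {0,1,2,NA} for SNP ",
           colnames(calls)[which(!ok, arr.ind = TRUE)[1, 2]])
    }
  }
  if (is.null(map)) {
    nm <- colnames(calls)
    if (is.null(nm)) nm <- sprintf("SNP%05d", seq_len(ncol(calls)))
    map <- tibble::tibble(snp = nm, chr = "U", pos = seq_len(ncol(calls)))
  } else {
    map <- tibble::as_tibble(map)
    if (!is.null(colnames(calls)) && all(colnames(calls) %in% map$snp)) {
      map <- map[match(colnames(calls), map$snp), ]
    }
    if (nrow(map) != ncol(calls)) {
      stop("SNP map has ", nrow(map), " rows but genotypes have ",
           ncol(calls), " SNPs")
    }
  }
  geno_set(calls, map)
}

#' Write genotypes
#'
#' @param geno a [geno_set()].
#' @param path output path.
#' @param dialect `"simple"` or `"plink_raw"` (see [read_genotypes()]).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, dialect = c("simple", "plink_raw")) {
  dialect <- match.arg(dialect)
  calls <- geno$calls
  if (dialect == "simple") {
    x <- calls
    x[is.na(x)] <- 5L
    lines <- paste(rownames(calls),
                   apply(x, 1, paste, collapse = ""))
    writeLines(lines, path)
  } else {
    tab <- data.frame(FID = rownames(calls), IID = rownames(calls),
                      PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9,
                      check.names = FALSE)
    tab <- cbind(tab, as.data.frame(calls, check.names = FALSE))
    utils::write.table(tab, path, sep = " ", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Read / write a SNP map
#'
#' Tab-separated `snp`, `chr`, `pos` (1-based bp), header required.
#' @param path file path.
#' @return A tibble `(snp, chr, pos)`.
#' @export
read_snp_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("snp", "chr", "pos")
  if (!all(need %in% names(tab))) {
    stop("SNP map ", path, ": needs columns snp, chr, pos")
  }
  tibble::as_tibble(tab[need])
}

#' @rdname read_snp_map
#' @param map SNP map tibble.
#' @export
write_snp_map <- function(map, path) {
  utils::write.table(map[c("snp", "chr", "pos")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Tab-separated with header: `animal`, a contemporary-group label column
#' `cg`, then one column per trait.  Missing trait values are `NA`;
#' records missing every trait are dropped with a message.
#'
#' @param path file path.
#' @return A tibble `(animal, cg, <traits...>)`.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  if (!all(c("animal", "cg") %in% names(tab))) {
    stop("phenotype file ", path, ": needs columns animal, cg")
  }
  traits <- setdiff(names(tab), c("animal", "cg"))
  if (!length(traits)) stop("phenotype file ", path, ": no trait columns")
  tab$animal <- as.character(tab$animal)
  tab$cg <- as.character(tab$cg)
  if (any(!nzchar(tab$cg) | is.na(tab$cg))) {
    stop("phenotype file ", path, ": empty contemporary-group label")
  }
  all_na <- rowSums(!is.na(tab[traits])) == 0
  if (any(all_na)) {
    message("read_phenotypes: dropping ", sum(all_na),
            " record(s) with no trait observed")
    tab <- tab[!all_na, , drop = FALSE]
  }
  tibble::as_tibble(tab)
}

#' @rdname read_phenotypes
#' @param phenotypes phenotype tibble.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a gene table
#'
#' Either tab-separated `gene`, `chr`, `start`, `end` (1-based inclusive)
#' or a minimal GFF3 (only `gene` features are kept; the gene name is
#' taken from the `Name=` or `ID=` attribute).
#'
#' @param path file path.
#' @param format `"tsv"` or `"gff3"`.
#' @return A tibble `(gene, chr, start, end)`.
#' @export
read_gene_table <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("gene", "chr", "start", "end")
    if (!all(need %in% names(tab))) {
      stop("gene table ", path, ": needs columns gene, chr, start, end")
    }
    out <- tibble::as_tibble(tab[need])
  } else {
    lines <- read_nonempty_lines(path)
    lines <- lines[!startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 9)
    if (length(bad)) stop("gene table ", path, ": malformed GFF3 at line ", bad[1])
    keep <- vapply(fields, `[`, "", 3) == "gene"
    fields <- fields[keep]
    attr_name <- function(a) {
      m <- regmatches(a, regexec("(?:^|;)Name=([^;]+)", a))[[1]]
      if (length(m) < 2) {
        m <- regmatches(a, regexec("(?:^|;)ID=([^;]+)", a))[[1]]
      }
      if (length(m) == 2) sub("^gene:", "", m[2]) else NA_character_
    }
    out <- tibble::tibble(
      gene = vapply(fields, function(f) attr_name(f[9]), ""),
      chr = vapply(fields, `[`, "", 1),
      start = as.integer(vapply(fields, `[`, "", 4)),
      end = as.integer(vapply(fields, `[`, "", 5))
    )
  }
  if (any(out$start > out$end)) {
    stop("gene table ", path, ": start > end for ",
         out$gene[which(out$start > out$end)[1]])
  }
  dup <- duplicated(out[c("gene", "chr")])
  if (any(dup)) {
    stop("gene table ", path, ": duplicated gene on one chromosome: ",
         out$gene[dup][1])
  }
  out
}

#' @rdname read_gene_table
#' @param genes gene tibble.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes[c("gene", "chr", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table
#'
#' Tab-separated with header, deterministic column order, numeric columns
#' at 6 significant digits.  The matching reader is [read_report()].
#'
#' @param df a data frame (EBV/GEBV table, variance-component summary,
#'   window-variance table, candidate-gene table, ...).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(df, path) {
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- signif(out[[j]], 6)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

read_nonempty_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(trimws(lines))]
}
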