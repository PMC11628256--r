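#' Load a haplotype-vs-reference SNP table
#'
#' Reads a tab-separated SNP table (the shape produced by whole-chromosome
#' alignment of one haplotype against the reference, as in MUMmer
#' `show-snps`), with columns `ref_chrom`, `ref_pos` (1-based), `ref_allele`,
#' `qry_allele`, `qry_chrom`, `qry_pos` (1-based). Rows from ambiguous
#' alignments — any reference position occurring more than once within the
#' table — are removed entirely, and indel rows (a `.` allele on either side)
#' are discarded: only biallelic substitutions can serve as haplotype markers.
#'
#' @param path TSV file path (with a header line).
#' @return A data.frame of SNP rows sorted by (`ref_chrom`, `ref_pos`).
#' @export
load_snp_table <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", blank.lines.skip = FALSE)
  required <- c("ref_chrom", "ref_pos", "ref_allele", "qry_allele",
                "qry_chrom", "qry_pos")
  assert_that(all(required %in% names(tab)),
              paste("SNP table must have columns:",
                    paste(required, collapse = ", ")))
  tab <- tab[, required]
  if (nrow(tab) == 0) {
    tab$ref_pos <- integer(0)
    tab$qry_pos <- integer(0)
    return(tab)
  }

  # line numbers in the file (header is line 1)
  lineno <- seq_len(nrow(tab)) + 1L

  # indel rows (show-snps encodes them with '.') are dropped silently
  is_indel <- tab$ref_allele == "." | tab$qry_allele == "."
  tab <- tab[!is_indel, , drop = FALSE]
  lineno <- lineno[!is_indel]

  bad_allele <- !(toupper(tab$ref_allele) %in% BASES) |
    !(toupper(tab$qry_allele) %in% BASES)
  if (any(bad_allele)) {
    stop(sprintf("malformed allele at line %d of %s",
                 lineno[which(bad_allele)[1]], path), call. = FALSE)
  }
  ref_pos <- suppressWarnings(as.integer(tab$ref_pos))
  qry_pos <- suppressWarnings(as.integer(tab$qry_pos))
  bad_pos <- is.na(ref_pos) | is.na(qry_pos) | ref_pos < 1L | qry_pos < 1L
  if (any(bad_pos)) {
    stop(sprintf("non-numeric or non-positive position at line %d of %s",
                 lineno[which(bad_pos)[1]], path), call. = FALSE)
  }
  tab$ref_allele <- toupper(tab$ref_allele)
  tab$qry_allele <- toupper(tab$qry_allele)
  tab$ref_pos <- ref_pos
  tab$qry_pos <- qry_pos

  # ambiguity rule: all rows sharing a duplicated ref position are removed
  key <- paste(tab$ref_chrom, tab$ref_pos)
  dup <- key %in% key[duplicated(key)]
  tab <- tab[!dup, , drop = FALSE]

  tab <- tab[order(tab$ref_chrom, tab$ref_pos), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Derive the haplotype-specific marker set
#'
#' Intersects two de-ambiguated haplotype-vs-reference SNP tables to the
#' positions called in **both** haplotypes and keeps those where the two
#' haplotypes carry different alternate alleles. Positions present in only
#' one table ("missing values") cannot distinguish the inherited haplotype
#' from an absent variant in an F1 alt-allele comparison and are excluded, as
#' are positions where the haplotypes carry the identical alternate allele.
#'
#' @param tableA,tableB SNP tables from [load_snp_table()] (or equivalent
#'   data.frames), one per haplotype.
#' @return A data.frame of markers with columns `ref_chrom`, `ref_pos`,
#'   `ref_allele`, `hapA_allele`, `hapB_allele`, `hapA_qry_pos`,
#'   `hapB_qry_pos`, strictly ordered by (`ref_chrom`, `ref_pos`).
#' @export
derive_marker_set <- function(tableA, tableB) {
  required <- c("ref_chrom", "ref_pos", "ref_allele", "qry_allele", "qry_pos")
  assert_that(all(required %in% names(tableA)) &&
                all(required %in% names(tableB)),
              "inputs must be loaded SNP tables")
  if (nrow(tableA) > 0 && nrow(tableB) > 0 &&
      length(intersect(unique(tableA$ref_chrom),
                       unique(tableB$ref_chrom))) == 0) {
    warning("SNP tables share no chromosome names; marker set is empty")
  }
  m <- merge(tableA, tableB, by = c("ref_chrom", "ref_pos", "ref_allele"),
             suffixes = c("_A", "_B"))
  m <- m[m$qry_allele_A != m$qry_allele_B, , drop = FALSE]
  out <- data.frame(
    ref_chrom = m$ref_chrom, ref_pos = m$ref_pos, ref_allele = m$ref_allele,
    hapA_allele = m$qry_allele_A, hapB_allele = m$qry_allele_B,
    hapA_qry_pos = m$qry_pos_A, hapB_qry_pos = m$qry_pos_B,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$ref_chrom, out$ref_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
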