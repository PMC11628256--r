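#' Annotate variants by genic context
#'
#' Assigns each variant exactly one context label with precedence
#' `utr5 > utr3 > exon > intron > intergenic`: a variant overlapping a
#' 5' UTR is `utr5` regardless of other overlaps, and a variant inside a
#' gene but outside its exons/UTRs is `intron`. A variant overlapping two
#' genes takes the first by coordinate order.
#'
#' @param variants a variant table.
#' @param features a GFF3 path or a [GenomicRanges::GRanges] with a `type`
#'   column using the GFF3 vocabulary (`gene`, `exon`, `five_prime_UTR`,
#'   `three_prime_UTR`).
#' @return `variants` with an added `context` column.
#' @export
annotate_context <- function(variants, features) {
  if (is.character(features)) {
    features <- tryCatch(rtracklayer::import(features, format = "gff3"),
                         error = function(e) {
                           stop("malformed GFF3: ", conditionMessage(e),
                                call. = FALSE)
                         })
  }
  type <- as.character(features$type)
  vg <- GenomicRanges::GRanges(
    variants$chrom,
    IRanges::IRanges(variants$pos, variant_span_end(variants))
  )
  hits_any <- function(subset) {
    if (length(subset) == 0) return(rep(FALSE, length(vg)))
    GenomicRanges::countOverlaps(vg, subset) > 0
  }
  in_utr5 <- hits_any(features[type == "five_prime_UTR"])
  in_utr3 <- hits_any(features[type == "three_prime_UTR"])
  in_exon <- hits_any(features[type == "exon"])
  in_gene <- hits_any(features[type == "gene"])
  context <- rep("intergenic", length(vg))
  context[in_gene] <- "intron"
  context[in_exon] <- "exon"
  context[in_utr3] <- "utr3"
  context[in_utr5] <- "utr5"
  variants$context <- context
  variants
}

#' Per-event context percentage table
#'
#' @param annotated output of [annotate_context()].
#' @return A data.frame with `sample_id`, `context`, `count`, `percent`.
#' @export
context_percentages <- function(annotated) {
  levels <- c("utr5", "utr3", "exon", "intron", "intergenic")
  out <- do.call(rbind, lapply(split(annotated, annotated$sample_id),
                               function(g) {
    counts <- table(factor(g$context, levels = levels))
    data.frame(sample_id = g$sample_id[1], context = levels,
               count = as.integer(counts),
               percent = round(100 * as.integer(counts) / nrow(g), 2),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Indel size spectrum and SNP count
#'
#' Tabulates signed indel lengths (`nchar(alt) - nchar(ref)` per alternate
#' allele) and counts SNPs, reporting the SNP:indel ratio — the headline
#' contrast between SNP-rich and indel-rich background variant landscapes.
#'
#' @param variants a variant table (multi-allelic records contribute one
#'   entry per alternate allele).
#' @return A list with `snp_count`, `indel_count`, `histogram` (data.frame
#'   `size`, `count` over non-zero signed lengths), `snp_indel_ratio` and
#'   `other_count` (equal-length multi-base substitutions).
#' @export
indel_size_spectrum <- function(variants) {
  if (nrow(variants) == 0) {
    return(list(snp_count = 0L, indel_count = 0L,
                histogram = data.frame(size = integer(0), count = integer(0)),
                snp_indel_ratio = NA_real_, other_count = 0L))
  }
  alts <- split_alts(variants$alt)
  ref_len <- nchar(variants$ref)
  sizes <- unlist(mapply(function(a, rl) nchar(a) - rl, alts, ref_len,
                         SIMPLIFY = FALSE))
  is_size0 <- sizes == 0L
  is_snp <- is_size0 & rep(ref_len, lengths(alts)) == 1L
  indels <- sizes[!is_size0]
  hist <- as.data.frame(table(indels), stringsAsFactors = FALSE)
  names(hist) <- c("size", "count")
  hist$size <- as.integer(hist$size)
  hist <- hist[order(hist$size), , drop = FALSE]
  rownames(hist) <- NULL
  list(
    snp_count = sum(is_snp),
    indel_count = length(indels),
    histogram = hist,
    snp_indel_ratio = if (length(indels)) sum(is_snp) / length(indels)
                      else NA_real_,
    other_count = sum(is_size0 & !is_snp)
  )
}
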