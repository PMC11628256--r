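#' Write a variant table as VCF 4.2
#'
#' Emits QD and MQ in INFO and DP/AD in the per-sample FORMAT field (AD as
#' `ref_depth,alt_depth`). One sample per file.
#'
#' @param variants a variant table.
#' @param path output path; written uncompressed unless it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path) {
  sample_name <- if (nrow(variants) && "sample_id" %in% names(variants)) {
    variants$sample_id[1]
  } else "SAMPLE"
  meta <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">"
  )
  fix <- cbind(
    CHROM = as.character(variants$chrom), POS = as.character(variants$pos),
    ID = ".", REF = variants$ref, ALT = variants$alt, QUAL = ".",
    FILTER = ".",
    INFO = sprintf("QD=%.2f;MQ=%.2f", variants$qd, variants$mq)
  )
  gt <- cbind(
    FORMAT = rep("DP:AD", nrow(variants)),
    sprintf("%d:%d,%d", variants$dp,
            pmax(variants$dp - variants$ad_alt, 0L), variants$ad_alt)
  )
  colnames(gt)[2] <- sample_name
  v <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                    meta = meta, fix = fix, gt = gt)
  tmp <- tempfile(fileext = ".vcf.gz")
  vcfR::write.vcf(v, file = tmp)
  if (grepl("\\.gz$", path)) {
    file.copy(tmp, path, overwrite = TRUE)
  } else {
    writeLines(readLines(gzfile(tmp)), path)
  }
  unlink(tmp)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Extracts QD/MQ from INFO and DP/AD from the first sample's FORMAT fields;
#' `ad_alt` is the maximum alternate-allele depth of the record. Records
#' lacking an annotation carry `NA` there (the hard filters remove them with
#' reason `"missing"`).
#'
#' @param path VCF path (plain or gzipped).
#' @return A variant table.
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) return(variant_table())
  qd <- suppressWarnings(as.numeric(vcfR::extract.info(v, "QD")))
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))
  has_gt <- ncol(v@gt) >= 2
  if (has_gt) {
    dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, "DP")[, 1]))
    ad <- vcfR::extract.gt(v, "AD")[, 1]
    ad_alt <- vapply(ad, function(x) {
      if (is.na(x)) return(NA_integer_)
      parts <- suppressWarnings(as.integer(strsplit(x, ",")[[1]]))
      if (length(parts) < 2) return(NA_integer_)
      max(parts[-1])
    }, integer(1), USE.NAMES = FALSE)
    sample_id <- colnames(v@gt)[2]
  } else {
    dp <- rep(NA_integer_, n)
    ad_alt <- rep(NA_integer_, n)
    sample_id <- "SAMPLE"
  }
  out <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    qd = qd, mq = mq, dp = dp, ad_alt = ad_alt,
    sample_id = sample_id, stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
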