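BASES <- c("A", "C", "G", "T")

# IUPAC expansion used for PAM patterns
IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# a base different from each element of `from`
other_base <- function(from) {
  vapply(from, function(b) sample(setdiff(BASES, b), 1L), character(1),
         USE.NAMES = FALSE)
}

# split a comma-joined ALT field into a character vector
split_alts <- function(alt) strsplit(alt, ",", fixed = TRUE)

#' Empty variant table
#'
#' The data.frame shape used throughout the package for VCF-style calls:
#' one row per record with `chrom`, `pos` (1-based), `ref`, `alt`
#' (comma-joined for multi-allelic records), the annotations `qd`, `mq`,
#' `dp`, `ad_alt` (maximum alt-supporting depth) and a `sample_id`.
#'
#' @return A zero-row data.frame with the canonical columns.
#' @export
variant_table <- function() {
  data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), qd = numeric(0), mq = numeric(0),
    dp = integer(0), ad_alt = integer(0), sample_id = character(0),
    stringsAsFactors = FALSE
  )
}

# end of the reference span of a record: [pos, pos + nchar(ref) - 1]
variant_span_end <- function(variants) {
  variants$pos + nchar(variants$ref) - 1L
}

# deterministic RNG scope: all stochastic operations funnel through here
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
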