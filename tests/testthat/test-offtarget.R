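SG2 <- "AACACTAATGTACCGTCAAATGG"   # spacer + PAM, auto-split on input

test_that("a genome equal to spacer+PAM yields one perfect plus-strand site", {
  g <- Biostrings::DNAStringSet(c(chrT = SG2))
  s <- enumerate_sites(g, SG2, max_mm = 5)
  expect_equal(nrow(s), 1)
  expect_equal(s$strand, "+")
  expect_equal(s$mismatch_count, 0L)
  expect_equal(s$pam_class, "NGG")
  expect_equal(s$spacer_start, 1L)
  expect_equal(s$spacer_end, 20L)
  expect_equal(s$pam_start, 21L)
})

test_that("a reverse-complement embedding is found on the minus strand", {
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(SG2)))
  g <- Biostrings::DNAStringSet(c(chrT = paste0("CCCCC", rc, "CCCCC")))
  s <- enumerate_sites(g, SG2, max_mm = 0)
  expect_equal(nrow(s), 1)
  expect_equal(s$strand, "-")
  expect_equal(s$mismatch_count, 0L)
  expect_equal(s$pam_start, 6L)      # PAM 5'-adjacent on the plus strand
  expect_equal(s$spacer_start, 9L)
  expect_equal(s$spacer_end, 28L)
})

test_that("spacer length and ambiguous bases are policed", {
  g <- Biostrings::DNAStringSet(c(chrT = strrep("ACGT", 20)))
  expect_error(enumerate_sites(g, "ACGT"), "20 nt")
  # N in the PAM disqualifies the site even under the N of NGG
  g2 <- Biostrings::DNAStringSet(c(chrT = paste0(substr(SG2, 1, 20), "NGG")))
  expect_equal(nrow(enumerate_sites(g2, SG2, max_mm = 0)), 0)
})

test_that("site enumeration equals the brute-force oracle on random genomes", {
  for (i in 1:3) {
    g <- random_genome(1, 20000, seed = 50L + i)
    sp <- withr::with_seed(60L + i, paste(
      sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""))
    mine <- enumerate_sites(g, sp, max_mm = 5)
    oracle <- oracle_enumerate_sites(g, sp, max_mm = 5)
    expect_identical(site_keys(mine), site_keys(oracle))
  }
})

test_that("site counts are non-decreasing in max_mm and PAM classes", {
  g <- random_genome(1, 50000, seed = 71L)
  counts_mm <- vapply(0:5, function(mm) {
    nrow(enumerate_sites(g, SG2, max_mm = mm))
  }, numeric(1))
  expect_true(all(diff(counts_mm) >= 0))
  n_one <- nrow(enumerate_sites(g, SG2, max_mm = 5, pam_classes = "NGG"))
  n_all <- nrow(enumerate_sites(g, SG2, max_mm = 5))
  expect_gte(n_all, n_one)
})

test_that("variants overlap sites by the 23-bp span rule", {
  sites <- data.frame(
    chrom = "chr1", strand = "+", spacer_start = 101L, spacer_end = 120L,
    pam_start = 121L, pam_end = 123L, mismatch_count = 2L,
    mismatch_positions = "1,5", pam_class = "NGG", stringsAsFactors = FALSE
  )
  mk <- function(pos) data.frame(chrom = "chr1", pos = pos, ref = "A",
                                 alt = "T", qd = 20, mq = 58, dp = 30,
                                 ad_alt = 10, sample_id = "E1",
                                 stringsAsFactors = FALSE)
  expect_equal(nrow(overlap_variants(sites, mk(122L))), 1)  # middle PAM base
  expect_equal(nrow(overlap_variants(sites, mk(124L))), 0)  # 1 bp outside
  expect_equal(nrow(overlap_variants(sites, mk(100L))), 0)
  hit <- overlap_variants(sites, mk(101L))
  expect_equal(hit$mismatch_count, 2L)
  expect_equal(hit$pam_class, "NGG")
})

test_that("planted in-site variants are all recovered as candidates", {
  # embed five degenerate spacer copies (2 mismatches each) in the genome
  base <- as.character(random_genome(1, 50000, seed = 81L)[[1]])
  embedded <- substr(SG2, 1, 20)
  substr(embedded, 3, 3) <- "G"; substr(embedded, 11, 11) <- "C"
  chars <- strsplit(base, "")[[1]]
  at <- c(1000L, 9000L, 20000L, 33000L, 45000L)
  for (p in at) {
    chars[p:(p + 22L)] <- strsplit(paste0(embedded, "AGG"), "")[[1]]
  }
  g <- Biostrings::DNAStringSet(c(c01 = paste(chars, collapse = "")))
  sites <- enumerate_sites(g, SG2, max_mm = 5)
  expect_gte(nrow(sites), 5)
  take <- sites[match(at, sites$spacer_start), ]
  planted <- do.call(rbind, lapply(seq_len(nrow(take)), function(i) {
    data.frame(chrom = take$chrom[i],
               pos = take$spacer_start[i] + 3L, ref = "A", alt = "T",
               qd = 20, mq = 58, dp = 30, ad_alt = 10, sample_id = "E1",
               stringsAsFactors = FALSE)
  }))
  cand <- overlap_variants(sites, planted)
  expect_true(all(seq_len(nrow(take)) %in%
                    match(cand$pos, take$spacer_start + 3L)))
  tally <- per_mismatch_tally(sites, cand)
  expect_true(all(tally$n_with_variant <= tally$n_sites))
  expect_equal(sum(tally$n_sites), nrow(sites))
})

test_that("triage applies the shared, allele-fraction and default rules", {
  cand <- data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L),
    ref = c("A", "A", "AT"), alt = c("T", "G", "A"),
    qd = 20, mq = 58, dp = 30, ad_alt = 10, sample_id = "E1",
    site_index = 1:3, mismatch_count = 5L, pam_class = "NGG",
    site_strand = "+", stringsAsFactors = FALSE
  )
  # the chr1:100 SNP is called identically in a second event
  e2 <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                   qd = 20, mq = 58, dp = 30, ad_alt = 10, sample_id = "E2",
                   stringsAsFactors = FALSE)
  # the chr1:200 SNP has 3 supporting reads in a control below the threshold
  support <- data.frame(
    chrom = "chr1", pos = c(200L, 300L),
    sample_id = c("WT", "WT"), supporting_reads = c(3L, 0L),
    called = FALSE, stringsAsFactors = FALSE
  )
  res <- triage_variants(cand, event_sets = list(E1 = cand, E2 = e2),
                         control_sets = list(), raw_support = support)
  expect_equal(res$label,
               c("shared_background", "allele_fraction_background",
                 "putative_cas9"))
  # indel unique to one event with zero support elsewhere stays putative
  expect_match(res$evidence[3], "indel")

  # a locus absent from the support table keeps its call but says so
  res2 <- triage_variants(cand[3, ], event_sets = list(E1 = cand),
                          raw_support = support[0, ])
  expect_equal(res2$label, "putative_cas9")
  expect_match(res2$evidence, "no cross-sample support")

  # SNV unique and unsupported: putative but flagged background-leaning
  res3 <- triage_variants(cand[2, ], event_sets = list(E1 = cand),
                          raw_support = data.frame(
                            chrom = "chr1", pos = 200L, sample_id = "WT",
                            supporting_reads = 0L, called = FALSE,
                            stringsAsFactors = FALSE))
  expect_equal(res3$label, "putative_cas9")
  expect_match(res3$evidence, "not a common Cas9")
})
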