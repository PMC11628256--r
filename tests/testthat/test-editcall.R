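test_that("target sites derive PAM, cut and seed intervals from the spacer", {
  s <- target_site("amp", 101L, 120L, "+")
  expect_equal(s$pam_start, 121L)
  expect_equal(s$cut_pos, 117L)       # blunt cut 3 bp 5' of the PAM
  expect_equal(c(s$seed_start, s$seed_end), c(111L, 120L))
  m <- target_site("amp", 101L, 120L, "-")
  expect_equal(m$pam_end, 100L)
  expect_equal(m$cut_pos, 104L)
  expect_equal(c(m$seed_start, m$seed_end), c(101L, 110L))
  expect_error(target_site("amp", 101L, 121L), "20 nt")
})

test_that("a pure wild-type read set yields one outcome with fraction 1", {
  amp <- simulate_edited_reads(
    data.frame(size = 0L, fraction = 1, pathway = "none"), 100L, seed = 3L)
  out <- call_amplicon_outcomes(amp$reads, amp$reference, amp$site)
  expect_equal(nrow(out), 1)
  expect_equal(out$net_indel, 0L)
  expect_equal(out$fraction, 1)
  expect_equal(attr(out, "n_classified"), 100L)
  expect_equal(attr(out, "n_discarded"), 0L)
})

test_that("outcomes under the minimum read count are suppressed", {
  spec <- data.frame(size = c(0L, 1L), fraction = c(0.9, 0.1),
                     pathway = c("none", "cNHEJ"))
  amp <- simulate_edited_reads(spec, 400L, seed = 5L)
  # force exactly 24 +1 reads by subsetting
  ins_reads <- amp$reads[grepl("_o2$", names(amp$reads))][1:24]
  wt_reads <- amp$reads[grepl("_o1$", names(amp$reads))][1:100]
  out <- call_amplicon_outcomes(c(wt_reads, ins_reads), amp$reference,
                                amp$site, min_frequency = 25)
  expect_equal(out$net_indel, 0L)
  expect_equal(attr(out, "n_suppressed"), 24L)
  # at 25 reads the outcome is reported
  out2 <- call_amplicon_outcomes(
    c(wt_reads, amp$reads[grepl("_o2$", names(amp$reads))][1:25]),
    amp$reference, amp$site, min_frequency = 25)
  expect_setequal(out2$net_indel, c(0L, 1L))
})

test_that("empty read sets and too-short references are rejected", {
  amp <- simulate_edited_reads(
    data.frame(size = 0L, fraction = 1, pathway = "none"), 10L, seed = 7L)
  expect_error(call_amplicon_outcomes(character(0), amp$reference, amp$site),
               "empty read set")
  expect_error(call_amplicon_outcomes(amp$reads, substr(amp$reference, 1, 15),
                                      target_site("amp", 1L, 20L)),
               "wt_marker")
})

test_that("simulated mosaic spectra are recovered within 2 percentage points", {
  spec <- data.frame(size = c(0L, 1L, -5L), fraction = c(0.6, 0.3, 0.1),
                     pathway = c("none", "cNHEJ", "MMEJ"))
  amp <- simulate_edited_reads(spec, 2000L, seed = 11L)
  out <- call_amplicon_outcomes(amp$reads, amp$reference, amp$site)
  expect_equal(nrow(out), 3)
  expect_equal(sum(out$fraction), 1)
  realized <- amp$truth$count / sum(amp$truth$count)
  for (i in seq_len(nrow(spec))) {
    got <- out$fraction[out$net_indel == spec$size[i]]
    # the caller recovers the realized draw essentially exactly, and the
    # draw itself sits within multinomial noise of the target spectrum
    expect_lt(abs(got - realized[i]), 0.005)
    expect_lt(abs(got - spec$fraction[i]), 0.04)
  }
})

test_that("fractions always sum to one over classified reads", {
  spec <- data.frame(size = c(0L, 1L, -2L, -7L),
                     fraction = c(0.4, 0.3, 0.2, 0.1),
                     pathway = c("none", "cNHEJ", "cNHEJ", "MMEJ"))
  amp <- simulate_edited_reads(spec, 800L, seed = 13L)
  out <- call_amplicon_outcomes(amp$reads, amp$reference, amp$site,
                                min_frequency = 1)
  expect_equal(sum(out$fraction), 1)
  expect_equal(sum(out$read_count) + attr(out, "n_discarded"), 800L)
})

test_that("FASTQ round trip preserves the simulated reads", {
  amp <- simulate_edited_reads(
    data.frame(size = 0L, fraction = 1, pathway = "none"), 20L, seed = 17L)
  fq <- tempfile(fileext = ".fastq")
  write_amplicon_fastq(amp, fq)
  back <- read_amplicon_reads(fq)
  expect_equal(sort(as.character(back)), sort(as.character(amp$reads)))
})

test_that("microhomology scanning matches its definition on crafted cases", {
  # deleting TAG at 3..5 of CCTAGTAGGG leaves ...TAG repeated: k = 3
  expect_equal(scan_microhomology("CCTAGTAGGG", 3L, 5L), 3L)
  # wholly distinct flanks: k = 0
  expect_equal(scan_microhomology("AAACCCGGGTTT", 4L, 6L), 0L)
  expect_error(scan_microhomology("ACGT", 2L, 9L), "out of bounds")
})

test_that("microhomology equals the character-wise oracle on random cases", {
  withr::with_seed(19L, {
    for (i in 1:1000) {
      len <- sample(20:60, 1)
      ref <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      ds <- sample(seq_len(len - 10L), 1)
      de <- min(len - 1L, ds + sample(0:8, 1))
      expect_identical(scan_microhomology(ref, ds, de),
                       oracle_microhomology(ref, ds, de))
    }
    # a full repeat: homology runs to the end of the sequence
    expect_equal(scan_microhomology(strrep("AT", 10), 1L, 2L), 18L)
  })
})

test_that("repair pathways follow the microhomology and size rules", {
  spec <- data.frame(size = c(0L, 1L, -5L), fraction = c(0.5, 0.3, 0.2),
                     pathway = c("none", "cNHEJ", "MMEJ"))
  amp <- simulate_edited_reads(spec, 600L, seed = 23L)
  out <- call_amplicon_outcomes(amp$reads, amp$reference, amp$site)
  paths <- vapply(seq_len(nrow(out)), function(i) {
    classify_repair(out[i, ], amp$site, amp$reference)$pathway
  }, character(1))
  expect_equal(paths[out$net_indel == 1L], "cNHEJ")
  rp <- classify_repair(out[out$net_indel == -5L, ], amp$site, amp$reference)
  expect_equal(rp$pathway, "MMEJ")
  expect_gte(rp$microhomology_length, 2L)
  expect_equal(paths[out$net_indel == 0L], "unclassified")
})

test_that("a large replacement with a novel insert is SDSA-like", {
  # the archetypal complex variant: 195 bases replaced by a 166-bp insert
  spec <- data.frame(size = c(0L, -29L), fraction = c(0.5, 0.5),
                     pathway = c("none", "SDSA_like"))
  amp <- simulate_edited_reads(spec, 200L, seed = 29L, amplicon_length = 600L,
                               replaced_span = 195L)
  out <- call_amplicon_outcomes(amp$reads, amp$reference, amp$site)
  rp <- classify_repair(out[out$net_indel == -29L, ], amp$site, amp$reference)
  expect_equal(rp$pathway, "SDSA_like")
  expect_equal(rp$replaced_span, 195L)
  expect_equal(rp$inserted_length, 166L)
})

test_that("every outcome receives exactly one pathway label", {
  spec <- data.frame(size = c(0L, 1L, -2L, -6L, -11L),
                     fraction = c(0.3, 0.2, 0.2, 0.15, 0.15),
                     pathway = c("none", "cNHEJ", "cNHEJ", "MMEJ", "MMEJ"))
  amp <- simulate_edited_reads(spec, 1000L, seed = 31L)
  out <- call_amplicon_outcomes(amp$reads, amp$reference, amp$site,
                                min_frequency = 10)
  for (i in seq_len(nrow(out))) {
    rp <- classify_repair(out[i, ], amp$site, amp$reference)
    expect_true(rp$pathway %in% c("MMEJ", "cNHEJ", "SDSA_like",
                                  "unclassified"))
  }
})

test_that("zygosity calls follow the diploid rules", {
  # one edited and one wild-type allele
  het <- data.frame(net_indel = c(0L, -17L), fraction = c(0.5, 0.5),
                    read_count = c(500L, 500L))
  expect_equal(classify_site(het)$zygosity, "heterozygous")

  # a mosaic haplotype: multiple coexisting non-reference outcomes
  mos <- data.frame(
    net_indel = c(0L, 1L, 0L, -5L, -7L, -12L),
    fraction = c(0.6, 0.4, 0.25, 0.25, 0.25, 0.25),
    read_count = 100L,
    haplotype_tag = c("A", "A", "B", "B", "B", "B")
  )
  expect_equal(classify_site(mos)$zygosity, "mosaic")

  # fixed homozygous edit
  hom <- data.frame(net_indel = 1L, fraction = 1, read_count = 1000L)
  expect_equal(classify_site(hom)$zygosity, "homozygous")

  # two distinct fixed edits, no wild type
  bi <- data.frame(net_indel = c(1L, -3L), fraction = c(0.5, 0.5),
                   read_count = 500L)
  expect_equal(classify_site(bi)$zygosity, "biallelic")

  # unedited
  wt <- data.frame(net_indel = 0L, fraction = 1, read_count = 100L)
  expect_equal(classify_site(wt)$zygosity, "unedited")

  expect_error(classify_site(data.frame(net_indel = 0L, fraction = 0.7,
                                        read_count = 10L)), "sum to 1")
})

test_that("low-fraction outcomes at fixed sites raise the TGE flag", {
  tge <- data.frame(net_indel = c(1L, 0L), fraction = c(0.97, 0.03),
                    read_count = c(970L, 30L))
  call <- classify_site(tge)
  expect_true(call$tge_flag)
  expect_equal(call$zygosity, "homozygous")
  # too few supporting reads: no flag
  few <- data.frame(net_indel = c(1L, 0L), fraction = c(0.97, 0.03),
                    read_count = c(97L, 3L))
  expect_false(classify_site(few)$tge_flag)
  # a balanced heterozygote is not TGE
  expect_false(classify_site(data.frame(net_indel = c(0L, -17L),
                                        fraction = c(0.5, 0.5),
                                        read_count = 500L))$tge_flag)
})

test_that("seed overlap covers the 10 PAM-proximal nucleotides only", {
  s <- target_site("amp", 101L, 120L, "+")   # seed 111..120, cut 117
  expect_true(seed_overlap(s, 118L))         # 2 bp 5' of the PAM
  expect_false(seed_overlap(s, 106L))        # spacer position 15 from PAM
  expect_true(seed_overlap(s, s$cut_pos))    # +1 insertion at the cut
  expect_true(seed_overlap(s, 109L, 112L))   # span straddling the seed edge
  expect_false(seed_overlap(s, 121L, 123L))  # PAM itself is not seed
})

test_that("recovered fractions converge to the truth as read depth grows", {
  spec <- data.frame(size = c(0L, 1L, -5L), fraction = c(0.6, 0.3, 0.1),
                     pathway = c("none", "cNHEJ", "MMEJ"))
  err <- vapply(c(200L, 2000L, 20000L), function(n) {
    errs <- vapply(1:5, function(s) {
      amp <- simulate_edited_reads(spec, n, seed = 100L + s)
      out <- call_amplicon_outcomes(amp$reads, amp$reference, amp$site,
                                    min_frequency = 1)
      max(abs(out$fraction[match(spec$size, out$net_indel)] - spec$fraction))
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(err) <= 0))
})
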