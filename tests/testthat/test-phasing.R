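mk_markers <- function(n, chrom = "chr1", start = 100L, step = 100L) {
  data.frame(
    ref_chrom = chrom, ref_pos = start + step * (seq_len(n) - 1L),
    ref_allele = "A", hapA_allele = "T", hapB_allele = "C",
    hapA_qry_pos = start + step * (seq_len(n) - 1L) + 10L,
    hapB_qry_pos = start + step * (seq_len(n) - 1L) + 20L,
    stringsAsFactors = FALSE
  )
}

mk_obs <- function(labels, chrom = "chr1", start = 100L, step = 100L) {
  m <- mk_markers(length(labels), chrom, start, step)
  m$f1_alt <- ifelse(labels == "A", "T", "C")
  m$label <- labels
  m
}

calls_at <- function(markers, alt) {
  data.frame(chrom = markers$ref_chrom, pos = markers$ref_pos, ref = "A",
             alt = alt, qd = 20, mq = 58, dp = 30, ad_alt = 15,
             sample_id = "F1", stringsAsFactors = FALSE)
}

test_that("F1 alleles are matched to haplotypes, mismatches and ties dropped", {
  m <- mk_markers(3)
  v <- calls_at(m, c("T", "G", "T,C"))
  obs <- match_f1_alleles(m, v)
  expect_equal(obs$label, c("A", "drop", "drop"))  # match / neither / tie

  # no call at a marker -> drop
  obs2 <- match_f1_alleles(m, v[1, , drop = FALSE])
  expect_equal(obs2$label, c("A", "drop", "drop"))

  # B-allele match
  obs3 <- match_f1_alleles(m, calls_at(m, c("C", "C", "C")))
  expect_equal(obs3$label, rep("B", 3))
})

test_that("chromosome name mismatch raises an error listing the names", {
  m <- mk_markers(2)
  v <- calls_at(m, "T")
  v$chrom <- "scaffold_7"
  expect_error(match_f1_alleles(m, v), "scaffold_7")
})

test_that("the 80% congruence rule is a sharp boundary at 16/20", {
  obs16 <- mk_obs(c(rep("A", 16), rep("B", 4)))
  bins <- assign_bins(obs16, window_size = 20, congruence_threshold = 0.80)
  expect_equal(nrow(bins), 1)
  expect_equal(bins$haplotype, "A")
  expect_equal(bins$start_index, 1L)
  expect_equal(bins$end_index, 20L)
  expect_equal(bins$congruence, 0.8)

  obs15 <- mk_obs(c(rep("A", 15), rep("B", 5)))
  expect_equal(nrow(assign_bins(obs15, 20, 0.80)), 0)
})

test_that("a uniform chromosome gives one full-span bin with congruence 1", {
  obs <- mk_obs(rep("A", 4000))
  bins <- assign_bins(obs)
  expect_equal(nrow(bins), 1)
  expect_equal(bins$start_index, 1L)
  expect_equal(bins$end_index, 4000L)
  expect_equal(bins$congruence, 1)
})

test_that("chromosomes with fewer labelled markers than the window warn", {
  obs <- mk_obs(rep("A", 10))
  expect_warning(bins <- assign_bins(obs), "left unassigned")
  expect_equal(nrow(bins), 0)
})

test_that("drop-labelled markers are excluded before windowing", {
  labels <- c(rep("A", 10), rep("drop", 50), rep("A", 10))
  obs <- mk_obs(labels)
  bins <- assign_bins(obs)
  expect_equal(nrow(bins), 1)
  expect_equal(bins$haplotype, "A")
  expect_equal(bins$congruence, 1)
})

test_that("breakpoints sit at the floor midpoint between flanking markers", {
  bins <- data.frame(
    ref_chrom = "chr1", start_index = c(1L, 21L), end_index = c(20L, 40L),
    start_ref_pos = c(1L, 200L), end_ref_pos = c(100L, 400L),
    haplotype = c("A", "B"), congruence = c(1, 1), stringsAsFactors = FALSE
  )
  bp <- detect_breakpoints(bins)
  expect_equal(bp$ref_pos, 150L)
  expect_equal(bp$from_hap, "A")
  expect_equal(bp$to_hap, "B")

  # single bin -> none; same-haplotype neighbours merge silently
  expect_equal(nrow(detect_breakpoints(bins[1, ])), 0)
  bins$haplotype <- c("A", "A")
  expect_equal(nrow(detect_breakpoints(bins)), 0)
})

test_that("a planted crossover is recovered near its true position", {
  cfg <- sim_config(seed = 17L, n_chromosomes = 1L,
                    chromosome_length = 200000L, marker_density = 0.01,
                    crossovers_per_chromosome = 1L, marker_noise_rate = 0.01)
  p <- generate_parent_genomes(cfg)
  sim <- simulate_f1_inheritance(cfg, p)
  markers <- derive_marker_set(p$snpA, p$snpB)
  obs <- match_f1_alleles(markers, sim$variants)
  bins <- assign_bins(obs)
  bp <- detect_breakpoints(bins)
  expect_equal(nrow(bp), 1)
  truth_pos <- sim$truth$crossovers$ref_pos
  lab <- obs[obs$label %in% c("A", "B"), ]
  idx_bp <- findInterval(bp$ref_pos, lab$ref_pos)
  idx_truth <- findInterval(truth_pos, lab$ref_pos)
  expect_lte(abs(idx_bp - idx_truth), 20)
})

test_that("recovery accuracy does not improve as marker noise rises", {
  acc <- vapply(c(0, 0.01, 0.05), function(noise) {
    cfg <- sim_config(seed = 23L, n_chromosomes = 1L,
                      chromosome_length = 100000L, marker_density = 0.01,
                      crossovers_per_chromosome = 1L,
                      marker_noise_rate = noise)
    p <- generate_parent_genomes(cfg)
    sim <- simulate_f1_inheritance(cfg, p)
    obs <- match_f1_alleles(derive_marker_set(p$snpA, p$snpB), sim$variants)
    bins <- assign_bins(obs)
    truth <- sim$truth$marker_labels
    key <- paste(truth$chrom, truth$ref_pos)
    assigned <- rep(NA_character_, nrow(obs))
    for (i in seq_len(nrow(bins))) {
      lab <- which(obs$label %in% c("A", "B"))
      span <- lab[bins$start_index[i]:bins$end_index[i]]
      assigned[span] <- bins$haplotype[i]
    }
    idx <- match(key, paste(obs$ref_chrom, obs$ref_pos))
    mean(assigned[idx] == truth$true_hap, na.rm = TRUE)
  }, numeric(1))
  expect_equal(acc[1], 1)                # noise-free recovery is perfect
  expect_true(all(diff(acc) <= 1e-6))    # non-increasing in noise
})

test_that("bins mirror when the marker order is reversed", {
  labels <- c(rep("A", 60), rep("B", 40))
  obs <- mk_obs(labels)
  fwd <- assign_bins(obs)
  rev_obs <- mk_obs(rev(labels))
  rev_bins <- assign_bins(rev_obs)
  expect_equal(nrow(fwd), nrow(rev_bins))
  n <- 100L
  expect_equal(sort(n - fwd$end_index + 1L), sort(rev_bins$start_index))
  expect_equal(fwd$haplotype[order(fwd$start_index)],
               rev(rev_bins$haplotype[order(rev_bins$start_index)]))
})
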