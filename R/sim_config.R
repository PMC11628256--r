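#' Simulation configuration
#'
#' Parameters of the truth-tracked simulator that emulates the study design:
#' a homozygous parent identical to the reference, a heterozygous parent with
#' two divergent haplotypes, and an F1 that inherited the full homozygous
#' genome plus one recombinant haplotype.
#'
#' @param seed integer seed; identical configurations (including the seed)
#'   produce byte-identical outputs.
#' @param n_chromosomes number of chromosomes to simulate.
#' @param chromosome_length length of each chromosome in bases.
#' @param marker_density expected density (markers per base) of positions at
#'   which the two heterozygous-parent haplotypes carry distinct non-reference
#'   alleles (the phasing currency).
#' @param hap_divergence total substitution density (per base) between the two
#'   heterozygous-parent haplotypes; must be at least `marker_density`. The
#'   excess over `marker_density` is planted as one-haplotype-only SNPs.
#' @param crossovers_per_chromosome integer count, either a scalar applied to
#'   every chromosome or a vector of length `n_chromosomes`. The default
#'   mirrors the study's F1: crossovers on chromosomes 1, 2, 5, 7, 8 and 9 of
#'   twelve, with the remaining chromosomes inheriting one haplotype entire.
#' @param marker_noise_rate fraction of F1 marker calls corrupted; half of the
#'   corrupted calls are flipped to the other haplotype's allele and half are
#'   dropped.
#' @param background_snv_rate,background_indel_rate number of background
#'   (tissue-culture-like) SNVs / short indels planted per genome.
#' @param artifact_1bp_indel_excess multiplier controlling how many extra
#'   artifactual 1-bp indels are planted relative to `background_indel_rate`
#'   (0 disables them). Emulates the 1-bp indel enrichment seen in
#'   short-read call sets.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_chromosomes = 2, chromosome_length = 20000)
sim_config <- function(seed = 1L,
                       n_chromosomes = 12L,
                       chromosome_length = 200000L,
                       marker_density = 0.01,
                       hap_divergence = 0.015,
                       crossovers_per_chromosome = c(1L, 1L, 0L, 0L, 1L, 0L,
                                                     1L, 1L, 1L, 0L, 0L, 0L),
                       marker_noise_rate = 0.01,
                       background_snv_rate = 60,
                       background_indel_rate = 20,
                       artifact_1bp_indel_excess = 5) {
  n_chromosomes <- as.integer(n_chromosomes)
  chromosome_length <- as.integer(chromosome_length)
  assert_that(length(seed) == 1 && is.finite(seed), "seed must be a single integer")
  assert_that(n_chromosomes >= 1L, "n_chromosomes must be positive")
  assert_that(chromosome_length >= 1L,
              "chromosome_length must be positive (zero-length chromosomes rejected)")
  for (r in c(marker_density, hap_divergence, marker_noise_rate)) {
    assert_that(r >= 0 && r <= 1, "rates must lie in [0, 1]")
  }
  assert_that(hap_divergence >= marker_density,
              "hap_divergence must be >= marker_density")
  assert_that(background_snv_rate >= 0 && background_indel_rate >= 0,
              "background rates must be non-negative")
  assert_that(artifact_1bp_indel_excess >= 0,
              "artifact_1bp_indel_excess must be non-negative")
  if (length(crossovers_per_chromosome) == 1L) {
    crossovers_per_chromosome <- rep(as.integer(crossovers_per_chromosome),
                                     n_chromosomes)
  }
  if (length(crossovers_per_chromosome) > n_chromosomes) {
    crossovers_per_chromosome <- crossovers_per_chromosome[seq_len(n_chromosomes)]
  }
  assert_that(length(crossovers_per_chromosome) == n_chromosomes,
              "crossovers_per_chromosome must be scalar or one per chromosome")
  assert_that(all(crossovers_per_chromosome >= 0L),
              "crossover counts must be non-negative")
  structure(
    list(
      seed = as.integer(seed),
      n_chromosomes = n_chromosomes,
      chromosome_length = chromosome_length,
      marker_density = marker_density,
      hap_divergence = hap_divergence,
      crossovers_per_chromosome = as.integer(crossovers_per_chromosome),
      marker_noise_rate = marker_noise_rate,
      background_snv_rate = background_snv_rate,
      background_indel_rate = background_indel_rate,
      artifact_1bp_indel_excess = artifact_1bp_indel_excess
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chromosomes, "chromosome(s) x",
      x$chromosome_length, "bp, seed", x$seed, "\n")
  cat("  marker density", x$marker_density,
      "| haplotype divergence", x$hap_divergence, "\n")
  cat("  crossovers:", paste(x$crossovers_per_chromosome, collapse = ","),
      "| marker noise", x$marker_noise_rate, "\n")
  invisible(x)
}

chrom_names <- function(config) {
  sprintf("chr%02d", seq_len(config$n_chromosomes))
}
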