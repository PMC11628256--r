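#' Generate parent genomes and haplotype-vs-reference SNP tables
#'
#' Builds a reference genome (the homozygous parent), two divergent haplotypes
#' of the heterozygous parent, and the two SNP tables that independent
#' whole-chromosome alignment of each haplotype against the reference would
#' yield. Planted sites fall into four categories, recorded in the truth
#' ledger: `marker` (both haplotypes carry distinct non-reference alleles),
#' `hapA_only` / `hapB_only` (one haplotype differs), and `shared` (both carry
#' the same non-reference allele). Each haplotype chromosome additionally
#' starts with a short unaligned pad so that haplotype coordinates differ from
#' reference coordinates, exercising coordinate translation downstream.
#'
#' @param config a [sim_config()].
#' @return A list of class `parent_genomes` with elements
#'   `reference`, `hapA`, `hapB` ([Biostrings::DNAStringSet]s),
#'   `snpA`, `snpB` (SNP tables: `ref_chrom`, `ref_pos`, `ref_allele`,
#'   `qry_allele`, `qry_chrom`, `qry_pos`), `ledger` (per-site truth) and
#'   `pads` (per-chromosome haplotype pad lengths).
#' @export
generate_parent_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  chroms <- chrom_names(config)
  L <- config$chromosome_length

  with_seed(config$seed, {
    ref <- character(length(chroms))
    hapA <- character(length(chroms))
    hapB <- character(length(chroms))
    pads <- data.frame(chrom = chroms, padA = 0L, padB = 0L,
                       stringsAsFactors = FALSE)
    ledger <- vector("list", length(chroms))

    for (i in seq_along(chroms)) {
      seq_chars <- sample(BASES, L, replace = TRUE)
      n_marker <- round(config$marker_density * L)
      n_div <- max(round(config$hap_divergence * L), n_marker)
      n_single <- n_div - n_marker
      n_shared <- round(0.2 * n_marker)
      n_sites <- n_marker + n_single + n_shared
      assert_that(n_sites <= max(L - 2L, 0L),
                  "chromosome too short for the requested site density")
      pos <- sort(sample(2:(L - 1L), n_sites))
      category <- sample(rep(c("marker", "single", "shared"),
                             c(n_marker, n_single, n_shared)))
      category[category == "single"] <-
        sample(c("hapA_only", "hapB_only"),
               sum(category == "single"), replace = TRUE)

      ref_allele <- seq_chars[pos]
      hapA_allele <- ref_allele
      hapB_allele <- ref_allele
      is_m <- category == "marker"
      hapA_allele[is_m] <- other_base(ref_allele[is_m])
      hapB_allele[is_m] <- vapply(which(is_m), function(j) {
        sample(setdiff(BASES, c(ref_allele[j], hapA_allele[j])), 1L)
      }, character(1))
      is_a <- category == "hapA_only"
      hapA_allele[is_a] <- other_base(ref_allele[is_a])
      is_b <- category == "hapB_only"
      hapB_allele[is_b] <- other_base(ref_allele[is_b])
      is_s <- category == "shared"
      shared_allele <- other_base(ref_allele[is_s])
      hapA_allele[is_s] <- shared_allele
      hapB_allele[is_s] <- shared_allele

      a_chars <- seq_chars; a_chars[pos] <- hapA_allele
      b_chars <- seq_chars; b_chars[pos] <- hapB_allele
      padA <- sample(0:200, 1L)
      padB <- sample(0:200, 1L)
      pads$padA[i] <- padA
      pads$padB[i] <- padB

      ref[i] <- paste(seq_chars, collapse = "")
      hapA[i] <- paste(c(sample(BASES, padA, replace = TRUE), a_chars),
                       collapse = "")
      hapB[i] <- paste(c(sample(BASES, padB, replace = TRUE), b_chars),
                       collapse = "")
      ledger[[i]] <- data.frame(
        chrom = rep(chroms[i], length(pos)), ref_pos = pos, category = category,
        ref_allele = ref_allele, hapA_allele = hapA_allele,
        hapB_allele = hapB_allele,
        hapA_qry_pos = pos + padA, hapB_qry_pos = pos + padB,
        stringsAsFactors = FALSE
      )
    }

    ledger <- do.call(rbind, ledger)
    snpA <- ledger[ledger$hapA_allele != ledger$ref_allele,
                   c("chrom", "ref_pos", "ref_allele", "hapA_allele",
                     "chrom", "hapA_qry_pos")]
    names(snpA) <- c("ref_chrom", "ref_pos", "ref_allele", "qry_allele",
                     "qry_chrom", "qry_pos")
    snpB <- ledger[ledger$hapB_allele != ledger$ref_allele,
                   c("chrom", "ref_pos", "ref_allele", "hapB_allele",
                     "chrom", "hapB_qry_pos")]
    names(snpB) <- c("ref_chrom", "ref_pos", "ref_allele", "qry_allele",
                     "qry_chrom", "qry_pos")
    rownames(snpA) <- rownames(snpB) <- rownames(ledger) <- NULL

    structure(
      list(
        reference = Biostrings::DNAStringSet(setNames(ref, chroms)),
        hapA = Biostrings::DNAStringSet(setNames(hapA, chroms)),
        hapB = Biostrings::DNAStringSet(setNames(hapB, chroms)),
        snpA = snpA, snpB = snpB, ledger = ledger, pads = pads,
        config = config
      ),
      class = "parent_genomes"
    )
  })
}

good_annotations <- function(n) {
  data.frame(
    qd = round(runif(n, 5, 30), 2),
    mq = round(runif(n, 55, 60), 2),
    dp = sample(10:45, n, replace = TRUE)
  )
}

#' Simulate F1 inheritance and the F1 variant call set
#'
#' Plants crossovers on each chromosome, records the true segment map of the
#' recombinant haplotype (the homozygous parent's chromosomes pass through
#' whole), and emits the F1 variant calls against the reference that a
#' short-read pipeline would produce: heterozygous calls at inherited
#' haplotype-specific positions (with `marker_noise_rate` of marker calls
#' flipped or dropped), background SNVs and short indels, artifactual 1-bp
#' indels, and a small set of filter-fodder records that each violate exactly
#' one hard-filter criterion.
#'
#' @param config a [sim_config()].
#' @param parents output of [generate_parent_genomes()].
#' @param crossover_positions optional list (one integer vector per
#'   chromosome) of crossover base positions overriding the random draw;
#'   positions must lie strictly inside the chromosome.
#' @return A list of class `f1_simulation` with `truth` (elements
#'   `segment_map`, `marker_labels`, `crossovers`, `background`) and
#'   `variants` (a variant table with an extra `category` column tracing each
#'   record to exactly one truth category: `marker`, `noise_flip`,
#'   `inherited_snv`, `inherited_shared`, `background_snv`,
#'   `background_indel`, `artifact_indel` or `fodder_*`).
#' @export
simulate_f1_inheritance <- function(config, parents,
                                    crossover_positions = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(parents, "parent_genomes"))
  chroms <- chrom_names(config)
  L <- config$chromosome_length
  ledger <- parents$ledger
  pads <- parents$pads

  with_seed(config$seed + 1L, {
    seg_rows <- list()
    xo_rows <- list()
    marker_rows <- list()
    call_rows <- list()

    for (i in seq_along(chroms)) {
      chrom <- chroms[i]
      k <- config$crossovers_per_chromosome[i]
      if (!is.null(crossover_positions)) {
        xo <- sort(as.integer(crossover_positions[[i]]))
        assert_that(all(xo >= 1L & xo < L),
                    sprintf("crossover position outside chromosome %s", chrom))
      } else {
        xo <- if (k > 0) sort(sample(seq(round(L * 0.1), round(L * 0.9)), k))
              else integer(0)
      }
      start_hap <- sample(c("A", "B"), 1L)
      n_seg <- length(xo) + 1L
      haps <- rep(c(start_hap, setdiff(c("A", "B"), start_hap)),
                  length.out = n_seg)
      ref_start <- c(1L, xo + 1L)
      ref_end <- c(xo, L)

      # DM chromosome inherited whole
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        f1_chrom = paste0(chrom, "_DM"), f1_start = 1L, f1_end = L,
        source_assembly = "reference", source_chrom = chrom,
        source_start = 1L, source_end = L, orientation = "+",
        stringsAsFactors = FALSE
      )
      # recombinant haplotype: source coordinates carry the haplotype pad;
      # terminal segments extend to source position 1 and source end
      pad <- c(A = pads$padA[i], B = pads$padB[i])
      src_start <- ref_start + pad[haps]
      src_end <- ref_end + pad[haps]
      src_start[1L] <- 1L
      seg_len <- src_end - src_start + 1L
      f1_end <- cumsum(seg_len)
      f1_start <- f1_end - seg_len + 1L
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        f1_chrom = paste0(chrom, "_RH"), f1_start = f1_start, f1_end = f1_end,
        source_assembly = paste0("hap", haps), source_chrom = chrom,
        source_start = src_start, source_end = src_end, orientation = "+",
        stringsAsFactors = FALSE
      )
      if (length(xo)) {
        xo_rows[[length(xo_rows) + 1L]] <- data.frame(
          chrom = chrom, ref_pos = xo,
          from_hap = haps[seq_along(xo)], to_hap = haps[seq_along(xo) + 1L],
          stringsAsFactors = FALSE
        )
      }

      led <- ledger[ledger$chrom == chrom, ]
      seg_of <- findInterval(led$ref_pos, ref_start)
      true_hap <- haps[seg_of]

      is_m <- led$category == "marker"
      m <- led[is_m, ]
      m_hap <- true_hap[is_m]
      m_alt <- ifelse(m_hap == "A", m$hapA_allele, m$hapB_allele)
      u <- runif(nrow(m))
      flip <- u < config$marker_noise_rate / 2
      drop <- !flip & u < config$marker_noise_rate
      obs_alt <- m_alt
      obs_alt[flip] <- ifelse(m_hap[flip] == "A",
                              m$hapB_allele[flip], m$hapA_allele[flip])
      marker_rows[[length(marker_rows) + 1L]] <- data.frame(
        chrom = chrom, ref_pos = m$ref_pos, true_hap = m_hap,
        observed = ifelse(drop, "dropped", ifelse(flip, "flipped", "clean")),
        stringsAsFactors = FALSE
      )
      keep <- !drop
      if (any(keep)) {
        ann <- good_annotations(sum(keep))
        call_rows[[length(call_rows) + 1L]] <- data.frame(
          chrom = chrom, pos = m$ref_pos[keep], ref = m$ref_allele[keep],
          alt = obs_alt[keep], ann,
          ad_alt = pmin(ann$dp, sample(5:30, sum(keep), replace = TRUE)),
          sample_id = "F1",
          category = ifelse(flip[keep], "noise_flip", "marker"),
          stringsAsFactors = FALSE
        )
      }

      # inherited one-haplotype-only and shared heterozygous-parent SNVs
      inh_a <- led$category == "hapA_only" & true_hap == "A"
      inh_b <- led$category == "hapB_only" & true_hap == "B"
      inh_s <- led$category == "shared"
      inh <- inh_a | inh_b | inh_s
      if (any(inh)) {
        alt <- ifelse(true_hap[inh] == "A",
                      led$hapA_allele[inh], led$hapB_allele[inh])
        ann <- good_annotations(sum(inh))
        call_rows[[length(call_rows) + 1L]] <- data.frame(
          chrom = chrom, pos = led$ref_pos[inh], ref = led$ref_allele[inh],
          alt = alt, ann,
          ad_alt = pmin(ann$dp, sample(5:30, sum(inh), replace = TRUE)),
          sample_id = "F1",
          category = ifelse(inh_s[inh], "inherited_shared", "inherited_snv"),
          stringsAsFactors = FALSE
        )
      }
    }

    # background, artifact and filter-fodder records on random chromosomes,
    # avoiding planted parental sites
    used <- paste(ledger$chrom, ledger$ref_pos)
    draw_loci <- function(n) {
      out <- data.frame(chrom = character(0), pos = integer(0))
      while (nrow(out) < n) {
        cand <- data.frame(
          chrom = sample(chroms, n, replace = TRUE),
          pos = sample(5:(L - 5L), n, replace = TRUE),
          stringsAsFactors = FALSE
        )
        cand <- cand[!(paste(cand$chrom, cand$pos) %in% used) &
                       !duplicated(paste(cand$chrom, cand$pos)), ]
        out <- rbind(out, cand)
        used <<- c(used, paste(cand$chrom, cand$pos))
      }
      out[seq_len(n), , drop = FALSE]
    }
    ref_base_at <- function(chrom, pos, width = 1L) {
      as.character(Biostrings::subseq(parents$reference[[chrom]],
                                      pos, pos + width - 1L))
    }
    n_snv <- round(config$background_snv_rate)
    n_indel <- round(config$background_indel_rate)
    n_artifact <- round(config$background_indel_rate *
                          config$artifact_1bp_indel_excess)
    n_fodder <- max(5L, round(0.1 * config$background_snv_rate))

    bg <- list()
    if (n_snv > 0) {
      loci <- draw_loci(n_snv)
      refs <- mapply(ref_base_at, loci$chrom, loci$pos)
      ann <- good_annotations(n_snv)
      bg$snv <- data.frame(
        chrom = loci$chrom, pos = loci$pos, ref = refs,
        alt = other_base(refs), ann,
        ad_alt = pmin(ann$dp, sample(5:30, n_snv, replace = TRUE)),
        sample_id = "F1", category = "background_snv",
        stringsAsFactors = FALSE
      )
    }
    make_indels <- function(n, sizes, category) {
      loci <- draw_loci(n)
      size <- sample(sizes, n, replace = TRUE)
      ref <- character(n); alt <- character(n)
      for (j in seq_len(n)) {
        anchor <- ref_base_at(loci$chrom[j], loci$pos[j])
        if (size[j] > 0) {
          ref[j] <- anchor
          alt[j] <- paste0(anchor, random_dna(size[j]))
        } else {
          ref[j] <- ref_base_at(loci$chrom[j], loci$pos[j], 1L - size[j])
          alt[j] <- anchor
        }
      }
      ann <- good_annotations(n)
      data.frame(
        chrom = loci$chrom, pos = loci$pos, ref = ref, alt = alt, ann,
        ad_alt = pmin(ann$dp, sample(5:30, n, replace = TRUE)),
        sample_id = "F1", category = category, stringsAsFactors = FALSE
      )
    }
    if (n_indel > 0) {
      bg$indel <- make_indels(n_indel, c(-3L, -2L, 2L, 3L), "background_indel")
    }
    if (n_artifact > 0) {
      bg$artifact <- make_indels(n_artifact, c(-1L, 1L), "artifact_indel")
    }
    if (n_fodder > 0) {
      loci <- draw_loci(n_fodder)
      refs <- mapply(ref_base_at, loci$chrom, loci$pos)
      ann <- good_annotations(n_fodder)
      ad <- pmin(ann$dp, sample(5:30, n_fodder, replace = TRUE))
      viol <- rep(c("qd", "mq", "dp_low", "dp_high", "ad"),
                  length.out = n_fodder)
      ann$qd[viol == "qd"] <- round(runif(sum(viol == "qd"), 0, 1.99), 2)
      ann$mq[viol == "mq"] <- round(runif(sum(viol == "mq"), 20, 49.99), 2)
      ann$dp[viol == "dp_low"] <- sample(0:3, sum(viol == "dp_low"), TRUE)
      ad[viol == "dp_low"] <- pmin(ad[viol == "dp_low"],
                                   ann$dp[viol == "dp_low"])
      ann$dp[viol == "dp_high"] <- sample(51:120, sum(viol == "dp_high"), TRUE)
      ad[viol == "ad"] <- sample(0:3, sum(viol == "ad"), TRUE)
      bg$fodder <- data.frame(
        chrom = loci$chrom, pos = loci$pos, ref = refs,
        alt = other_base(refs), ann, ad_alt = ad, sample_id = "F1",
        category = paste0("fodder_", viol), stringsAsFactors = FALSE
      )
    }

    variants <- do.call(rbind, c(call_rows, unname(bg)))
    variants <- variants[order(variants$chrom, variants$pos), ]
    rownames(variants) <- NULL

    structure(
      list(
        truth = list(
          segment_map = do.call(rbind, seg_rows),
          marker_labels = do.call(rbind, marker_rows),
          crossovers = if (length(xo_rows)) do.call(rbind, xo_rows)
                       else data.frame(chrom = character(0),
                                       ref_pos = integer(0),
                                       from_hap = character(0),
                                       to_hap = character(0)),
          background = do.call(rbind, unname(bg))
        ),
        variants = variants,
        config = config
      ),
      class = "f1_simulation"
    )
  })
}

#' Simulate edited amplicon reads with a known outcome spectrum
#'
#' Constructs a random amplicon carrying a 20-nt spacer + NGG PAM, then draws
#' reads from a mixture of editing outcomes at the predicted blunt cut site
#' (3 bp 5' of the PAM). Outcome alleles are built according to their repair
#' pathway label: `MMEJ` deletions get a junction engineered to carry at least
#' 2 bases of microhomology, `cNHEJ` outcomes are 1-bp insertions (or small
#' deletions without junction homology), and `SDSA_like` outcomes replace a
#' span of the reference with a novel insert. Read counts per outcome are a
#' multinomial draw at the given fractions; base qualities are constant Q40.
#'
#' @param spectrum data.frame with columns `size` (signed net indel, 0 = wild
#'   type), `fraction` (must sum to 1) and `pathway`
#'   (`"none"`, `"cNHEJ"`, `"MMEJ"`, `"SDSA_like"`).
#' @param n_reads number of reads to draw.
#' @param seed integer seed for the amplicon and the multinomial draw.
#' @param amplicon_length amplicon length in bases.
#' @param spacer 20-nt protospacer planted in the amplicon (default: the
#'   polyphenol-oxidase-targeting guide used throughout the examples).
#' @param replaced_span span of reference bases removed in `SDSA_like`
#'   replacement outcomes (the insert length is `replaced_span + size`).
#' @return A list of class `amplicon_simulation`: `reads` (named
#'   [Biostrings::DNAStringSet]), `qualities` (constant per read),
#'   `reference` (amplicon string), `site` (a [target_site()] in amplicon
#'   coordinates) and `truth` (spectrum with realized counts and allele
#'   sequences).
#' @export
simulate_edited_reads <- function(spectrum, n_reads, seed = 1L,
                                  amplicon_length = 400L,
                                  spacer = "AACACTAATGTACCGTCAAA",
                                  replaced_span = 30L) {
  stopifnot(is.data.frame(spectrum),
            all(c("size", "fraction", "pathway") %in% names(spectrum)))
  assert_that(abs(sum(spectrum$fraction) - 1) < 1e-9,
              "outcome fractions must sum to 1")
  assert_that(nchar(spacer) == 20L, "spacer must be 20 nt")
  assert_that(n_reads >= 1, "n_reads must be positive")

  with_seed(seed, {
    # amplicon with the spacer+PAM planted at its centre, + strand
    spacer_start <- as.integer(amplicon_length / 2) - 10L
    pam <- paste0(sample(BASES, 1L), "GG")
    chars <- strsplit(random_dna(amplicon_length), "")[[1]]
    chars[spacer_start:(spacer_start + 19L)] <- strsplit(spacer, "")[[1]]
    chars[(spacer_start + 20L):(spacer_start + 22L)] <- strsplit(pam, "")[[1]]
    site <- target_site("amplicon", spacer_start, spacer_start + 19L, "+")
    cut <- site$cut_pos

    # engineer junction (non-)homology for deletion outcomes; deletions end
    # at the cut position
    for (j in seq_len(nrow(spectrum))) {
      s <- spectrum$size[j]
      if (s >= 0) next
      del_start <- cut + s + 1L
      if (identical(spectrum$pathway[j], "MMEJ")) {
        chars[del_start + 0:1] <- chars[cut + 1:2]
      } else if (chars[del_start] == chars[cut + 1L]) {
        chars[del_start] <- other_base(chars[cut + 1L])
      }
    }
    reference <- paste(chars, collapse = "")

    alleles <- character(nrow(spectrum))
    for (j in seq_len(nrow(spectrum))) {
      s <- spectrum$size[j]
      pw <- spectrum$pathway[j]
      if (identical(pw, "SDSA_like")) {
        a <- cut - replaced_span %/% 2L + 1L       # replaced interval [a, b]
        b <- a + replaced_span - 1L
        ins <- strsplit(random_dna(replaced_span + s), "")[[1]]
        # junction-distinct insert ends keep the replaced span unambiguous
        ins[1L] <- other_base(substr(reference, a, a))
        ins[length(ins)] <- other_base(substr(reference, b, b))
        alleles[j] <- paste0(substr(reference, 1L, a - 1L),
                             paste(ins, collapse = ""),
                             substr(reference, b + 1L, nchar(reference)))
      } else if (s == 0) {
        alleles[j] <- reference
      } else if (s > 0) {
        alleles[j] <- paste0(substr(reference, 1L, cut), random_dna(s),
                             substr(reference, cut + 1L, nchar(reference)))
      } else {
        del_start <- cut + s + 1L
        alleles[j] <- paste0(substr(reference, 1L, del_start - 1L),
                             substr(reference, cut + 1L, nchar(reference)))
        if (identical(pw, "MMEJ")) {
          mh <- scan_microhomology(reference, del_start, cut)
          assert_that(mh >= 2L,
                      "could not engineer >=2 bp of junction microhomology; choose MMEJ deletion sizes at least 2 apart")
        }
      }
    }

    counts <- as.integer(stats::rmultinom(1L, n_reads, spectrum$fraction))
    reads <- rep(alleles, counts)
    ord <- sample(length(reads))
    reads <- setNames(reads[ord],
                      sprintf("read_%05d_o%d",
                              seq_along(reads),
                              rep(seq_len(nrow(spectrum)), counts)[ord]))
    truth <- spectrum
    truth$count <- counts
    truth$allele <- alleles

    structure(
      list(
        reads = Biostrings::DNAStringSet(reads),
        qualities = "I",
        reference = reference,
        site = site,
        truth = truth
      ),
      class = "amplicon_simulation"
    )
  })
}

#' Write a simulated amplicon read set as FASTQ
#'
#' @param sim output of [simulate_edited_reads()].
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_amplicon_fastq <- function(sim, path) {
  quals <- Biostrings::BStringSet(
    vapply(Biostrings::width(sim$reads),
           function(w) strrep(sim$qualities, w), character(1))
  )
  names(quals) <- names(sim$reads)
  reads <- Biostrings::QualityScaledDNAStringSet(
    sim$reads, Biostrings::PhredQuality(quals)
  )
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

#' Write the SNP tables and FASTA files of a simulated parent set
#'
#' @param parents output of [generate_parent_genomes()].
#' @param outdir output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_parent_genomes <- function(parents, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(parents$reference,
                              file.path(outdir, "reference.fa"))
  Biostrings::writeXStringSet(parents$hapA, file.path(outdir, "hapA.fa"))
  Biostrings::writeXStringSet(parents$hapB, file.path(outdir, "hapB.fa"))
  write.table(parents$snpA, file.path(outdir, "hapA_vs_ref.snps.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(parents$snpB, file.path(outdir, "hapB_vs_ref.snps.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(parents$ledger, file.path(outdir, "truth_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
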