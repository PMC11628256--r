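#' Run the end-to-end demonstration pipeline on simulated data
#'
#' Chains every stage on truth-tracked simulated data: parent-genome
#' simulation, marker derivation, F1 phasing, synthetic-assembly
#' construction, hard filtering with wild-type control subtraction,
#' off-target enumeration on the stitched assembly, amplicon outcome calling
#' with repair-pathway and zygosity classification, and genic-context
#' annotation. Writes a machine-readable `report.tsv` and a plain-text
#' `summary.txt` including truth-vs-inferred comparisons; with a fixed
#' configuration the outputs are byte-identical across runs.
#'
#' @param config a [sim_config()]; the default is a down-scaled demonstration
#'   genome (4 chromosomes of 50 kb, crossovers on two of them).
#' @param outdir output directory.
#' @param window_size,congruence_threshold phasing parameters.
#' @param max_mm off-target mismatch allowance used in the demo scan.
#' @param spacer spacer scanned against the stitched assembly (default: the
#'   polyphenol-oxidase-targeting guide, supplied with its PAM).
#' @return Invisibly, a list with the stage results (`parents`, `sim`,
#'   `markers`, `bins`, `breakpoints`, `segment_map`, `assembly`,
#'   `filtered`, `retained`, `sites`, `outcomes`, `site_call`, `report`).
#' @export
run_demo <- function(config = sim_config(n_chromosomes = 4L,
                                         chromosome_length = 50000L,
                                         crossovers_per_chromosome =
                                           c(1L, 1L, 0L, 0L)),
                     outdir = tempfile("editscape_demo_"),
                     window_size = 20L, congruence_threshold = 0.80,
                     max_mm = 3L,
                     spacer = "AACACTAATGTACCGTCAAATGG") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  note <- function(metric, value) {
    report[[length(report) + 1L]] <<- data.frame(
      metric = metric, value = as.character(value), stringsAsFactors = FALSE)
  }

  # 1. simulate parents and F1
  parents <- generate_parent_genomes(config)
  write_parent_genomes(parents, file.path(outdir, "sim"))
  sim <- simulate_f1_inheritance(config, parents)
  write_variant_vcf(sim$variants[, setdiff(names(sim$variants), "category")],
                    file.path(outdir, "f1_calls.vcf"))
  note("chromosomes", config$n_chromosomes)
  note("chromosome_length", config$chromosome_length)
  note("seed", config$seed)
  note("f1_vcf_records", nrow(sim$variants))

  # 2. markers
  tabA <- load_snp_table(file.path(outdir, "sim", "hapA_vs_ref.snps.tsv"))
  tabB <- load_snp_table(file.path(outdir, "sim", "hapB_vs_ref.snps.tsv"))
  markers <- derive_marker_set(tabA, tabB)
  write.table(markers, file.path(outdir, "markers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("markers_derived", nrow(markers))
  note("markers_planted", sum(parents$ledger$category == "marker"))

  # 3. phase (assembly-mode filters first, as when selecting calls for binning)
  assembly_pass <- apply_hard_filters(
    sim$variants, filter_config(mode = "assembly"))$retained
  obs <- match_f1_alleles(markers, assembly_pass)
  bins <- assign_bins(obs, window_size, congruence_threshold)
  breakpoints <- detect_breakpoints(bins)
  write.table(bins, file.path(outdir, "bins.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(breakpoints, file.path(outdir, "breakpoints.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth_lab <- sim$truth$marker_labels
  lab_key <- paste(obs$ref_chrom, obs$ref_pos)
  truth_key <- paste(truth_lab$chrom, truth_lab$ref_pos)
  labelled <- obs$label %in% c("A", "B")
  agree <- obs$label[labelled] ==
    truth_lab$true_hap[match(lab_key[labelled], truth_key)]
  note("marker_label_accuracy_pct", sprintf("%.3f", 100 * mean(agree)))
  note("breakpoints_planted", nrow(sim$truth$crossovers))
  note("breakpoints_detected", nrow(breakpoints))

  # 4. build the synthetic assembly
  source_lengths <- list(
    reference = setNames(Biostrings::width(parents$reference),
                         names(parents$reference)),
    hapA = setNames(Biostrings::width(parents$hapA), names(parents$hapA)),
    hapB = setNames(Biostrings::width(parents$hapB), names(parents$hapB))
  )
  segment_map <- build_segment_map(bins, breakpoints, obs, source_lengths)
  sources <- list(reference = parents$reference, hapA = parents$hapA,
                  hapB = parents$hapB)
  assembly <- stitch_assembly(segment_map, sources)
  Biostrings::writeXStringSet(assembly, file.path(outdir, "f1_assembly.fa"))
  write_agp(segment_map, file.path(outdir, "f1_assembly.agp"))
  truth_assembly <- stitch_assembly(sim$truth$segment_map, sources)
  shared <- intersect(names(assembly), names(truth_assembly))
  ident <- vapply(shared, function(ch) {
    as.character(assembly[[ch]]) == as.character(truth_assembly[[ch]])
  }, logical(1))
  note("assembly_chromosomes", length(assembly))
  note("assembly_chromosomes_matching_truth",
       sprintf("%d/%d", sum(ident), length(shared)))

  # 5. hard filters + control subtraction (the wild-type control of a clonal
  # F1 carries the inherited parental variants)
  filtered <- apply_hard_filters(sim$variants, filter_config(mode = "event"))
  wt_control <- sim$variants[
    sim$variants$category %in% c("marker", "noise_flip", "inherited_snv",
                                 "inherited_shared"), , drop = FALSE]
  retained <- subtract_controls(filtered$retained, list(wt_control))
  note("records_failing_hard_filters", nrow(filtered$removed))
  note("records_after_control_subtraction", nrow(retained))
  spectrum <- indel_size_spectrum(retained)
  note("retained_snps", spectrum$snp_count)
  note("retained_indels", spectrum$indel_count)
  if (nrow(spectrum$histogram)) {
    mode_size <- spectrum$histogram$size[which.max(spectrum$histogram$count)]
    note("retained_indel_modal_size", mode_size)
  }

  # 6. off-target scan of the stitched assembly
  sites <- enumerate_sites(assembly, spacer, max_mm = max_mm)
  write.table(sites, file.path(outdir, "offtarget_sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("offtarget_sites_found", nrow(sites))
  note("offtarget_max_mm", max_mm)

  # 7. amplicon outcome calling on a simulated mosaic spectrum
  spec <- data.frame(size = c(0L, 1L, -5L), fraction = c(0.6, 0.3, 0.1),
                     pathway = c("none", "cNHEJ", "MMEJ"))
  amp <- simulate_edited_reads(spec, n_reads = 2000L,
                               seed = config$seed + 2L)
  outcomes <- call_amplicon_outcomes(amp$reads, amp$reference, amp$site)
  for (i in seq_len(nrow(outcomes))) {
    rp <- classify_repair(outcomes[i, ], amp$site, amp$reference)
    note(sprintf("amplicon_outcome_%+d_fraction", outcomes$net_indel[i]),
         sprintf("%.4f", outcomes$fraction[i]))
    note(sprintf("amplicon_outcome_%+d_pathway", outcomes$net_indel[i]),
         rp$pathway)
  }
  sc <- classify_site(outcomes)
  note("site_zygosity", sc$zygosity)
  note("site_tge_flag", sc$tge_flag)

  # 8. genic-context annotation against a toy gene model
  gff <- toy_gene_models(source_lengths$reference)
  ann <- annotate_context(retained, gff)
  pct <- context_percentages(ann)
  write.table(pct, file.path(outdir, "context_percentages.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("variants_annotated", nrow(ann))

  report <- do.call(rbind, report)
  write.table(report, file.path(outdir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(c(
    "editscape demonstration pipeline",
    "================================",
    sprintf("%-40s %s", report$metric, report$value)
  ), file.path(outdir, "summary.txt"))

  invisible(list(parents = parents, sim = sim, markers = markers,
                 observations = obs, bins = bins, breakpoints = breakpoints,
                 segment_map = segment_map, assembly = assembly,
                 filtered = filtered, retained = retained, sites = sites,
                 outcomes = outcomes, site_call = sc, report = report,
                 outdir = outdir))
}

# deterministic toy gene models covering a fixed fraction of each chromosome
toy_gene_models <- function(ref_lengths) {
  rows <- list()
  for (chrom in names(ref_lengths)) {
    L <- ref_lengths[[chrom]]
    starts <- seq(round(L * 0.1), round(L * 0.8), length.out = 3)
    for (g in seq_along(starts)) {
      gs <- round(starts[g]); ge <- gs + round(L * 0.05)
      u5 <- c(gs, gs + 99L)
      e1 <- c(gs + 100L, gs + 499L)
      e2 <- c(ge - 499L, ge - 100L)
      u3 <- c(ge - 99L, ge)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom,
        start = c(gs, u5[1], e1[1], e2[1], u3[1]),
        end = c(ge, u5[2], e1[2], e2[2], u3[2]),
        type = c("gene", "five_prime_UTR", "exon", "exon", "three_prime_UTR"),
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$start, tab$end))
  gr$type <- tab$type
  gr
}
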