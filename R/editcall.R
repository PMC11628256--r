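#' Define an on-target site
#'
#' Records the spacer interval, PAM interval, predicted blunt-cut position
#' (between the 3rd and 4th base 5' of the PAM; `cut_pos` is the last base on
#' the PAM-distal side of the cut) and the 10-nt PAM-proximal seed interval.
#'
#' @param chrom chromosome or amplicon name.
#' @param spacer_start,spacer_end 1-based inclusive interval of the 20-nt
#'   protospacer on the + strand.
#' @param strand `"+"` if the PAM lies 3' of `spacer_end`, `"-"` if 3' of
#'   `spacer_start` on the reverse strand.
#' @return A list of class `target_site` with `chrom`, `strand`,
#'   `spacer_start`, `spacer_end`, `pam_start`, `pam_end`, `cut_pos`,
#'   `seed_start`, `seed_end`.
#' @export
target_site <- function(chrom, spacer_start, spacer_end, strand = "+") {
  assert_that(spacer_end - spacer_start + 1L == 20L,
              "protospacer interval must span exactly 20 nt")
  assert_that(strand %in% c("+", "-"), "strand must be '+' or '-'")
  if (strand == "+") {
    pam_start <- spacer_end + 1L; pam_end <- spacer_end + 3L
    cut_pos <- spacer_end - 3L
    seed_start <- spacer_end - 9L; seed_end <- spacer_end
  } else {
    pam_start <- spacer_start - 3L; pam_end <- spacer_start - 1L
    cut_pos <- spacer_start + 3L
    seed_start <- spacer_start; seed_end <- spacer_start + 9L
  }
  structure(
    list(chrom = chrom, strand = strand,
         spacer_start = as.integer(spacer_start),
         spacer_end = as.integer(spacer_end),
         pam_start = as.integer(pam_start), pam_end = as.integer(pam_end),
         cut_pos = as.integer(cut_pos),
         seed_start = as.integer(seed_start), seed_end = as.integer(seed_end)),
    class = "target_site"
  )
}

# all start positions of `pattern` as an exact substring of `x`
exact_matches <- function(pattern, x) {
  hits <- gregexpr(pattern, x, fixed = TRUE)[[1]]
  hits[hits > 0L]
}

#' Call amplicon editing outcomes
#'
#' Classifies merged amplicon reads against the reference amplicon within a
#' comparison window of `comparison_range` bases either side of the predicted
#' cut site. A read is anchored by the two `wt_marker`-length reference
#' sequences immediately outside the window: reads that do not contain both
#' flanks as exact matches are discarded as unalignable (the wild-type-marker
#' rule). The read segment enclosed by the anchors is the window allele; its
#' net indel is its length change relative to the reference window, so
#' compound events collapse to one signed number. Reads are grouped by their
#' window allele sequence, and outcomes supported by at least `min_frequency`
#' reads are reported, sorted by read count.
#'
#' @param reads a [Biostrings::DNAStringSet], character vector, or FASTQ/FASTA
#'   path.
#' @param reference_amplicon reference amplicon sequence (string).
#' @param site a [target_site()] in amplicon coordinates.
#' @param comparison_range half-width of the comparison window in bases.
#' @param min_frequency minimum supporting reads for a reported outcome
#'   (a read count, following the deep-sequencing caller convention).
#' @param wt_marker length of the exact-match flank required outside the
#'   window.
#' @return A data.frame of outcomes: `net_indel`, `allele` (window
#'   sequence), `read_count`, `fraction` (of classified reads),
#'   `window_start`, `window_end`; attributes `n_classified`, `n_discarded`
#'   and `n_suppressed` (reads in outcomes under `min_frequency`).
#' @export
call_amplicon_outcomes <- function(reads, reference_amplicon, site,
                                   comparison_range = 100L,
                                   min_frequency = 25L, wt_marker = 10L) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- read_amplicon_reads(reads)
  }
  reads <- as.character(reads)
  assert_that(length(reads) > 0, "empty read set")
  stopifnot(inherits(site, "target_site"))
  len <- nchar(reference_amplicon)
  assert_that(len >= 2L * wt_marker + 1L,
              "reference shorter than window + 2 x wt_marker")
  ws <- max(site$cut_pos - comparison_range, wt_marker + 1L)
  we <- min(site$cut_pos + comparison_range, len - wt_marker)
  assert_that(ws <= we, "reference shorter than window + 2 x wt_marker")

  lf_seq <- substr(reference_amplicon, ws - wt_marker, ws - 1L)
  rf_seq <- substr(reference_amplicon, we + 1L, we + wt_marker)
  window_len <- we - ws + 1L

  counts <- table(reads)
  uniq <- names(counts)
  out_rows <- list()
  n_discarded <- 0L
  for (u in seq_along(uniq)) {
    lf_at <- exact_matches(lf_seq, uniq[u])
    rf_at <- exact_matches(rf_seq, uniq[u])
    if (length(lf_at) == 0 || length(rf_at) == 0) {
      n_discarded <- n_discarded + as.integer(counts[u])
      next
    }
    # choose the anchor pair whose enclosed segment is closest in length to
    # the reference window (flank sequences can recur by chance)
    pairs <- expand.grid(i = lf_at, j = rf_at)
    pairs <- pairs[pairs$j >= pairs$i + wt_marker, , drop = FALSE]
    if (nrow(pairs) == 0) {
      n_discarded <- n_discarded + as.integer(counts[u])
      next
    }
    seg_len <- pairs$j - (pairs$i + wt_marker)
    best <- pairs[which.min(abs(seg_len - window_len)), ]
    allele <- substr(uniq[u], best$i + wt_marker, best$j - 1L)
    out_rows[[length(out_rows) + 1L]] <- data.frame(
      net_indel = as.integer(nchar(allele) - window_len), allele = allele,
      read_count = as.integer(counts[u]), stringsAsFactors = FALSE
    )
  }
  n_classified <- length(reads) - n_discarded
  if (length(out_rows) == 0) {
    res <- data.frame(net_indel = integer(0), allele = character(0),
                      read_count = integer(0), fraction = numeric(0),
                      window_start = integer(0), window_end = integer(0))
  } else {
    res <- do.call(rbind, out_rows)
    # identical window alleles from different full reads collapse together
    res <- do.call(rbind, lapply(
      split(res, res$allele),
      function(g) data.frame(net_indel = g$net_indel[1], allele = g$allele[1],
                             read_count = sum(g$read_count),
                             stringsAsFactors = FALSE)
    ))
    res$fraction <- res$read_count / n_classified
    n_suppressed <- sum(res$read_count[res$read_count < min_frequency])
    res <- res[res$read_count >= min_frequency, , drop = FALSE]
    res <- res[order(-res$read_count), , drop = FALSE]
    res$window_start <- ws
    res$window_end <- we
    attr(res, "n_suppressed") <- n_suppressed
  }
  rownames(res) <- NULL
  attr(res, "n_classified") <- n_classified
  attr(res, "n_discarded") <- n_discarded
  res
}

#' Read amplicon reads from FASTQ or FASTA
#'
#' @param path file path; format chosen by extension (`.fq`/`.fastq` vs
#'   `.fa`/`.fasta`).
#' @return A [Biostrings::DNAStringSet].
#' @export
read_amplicon_reads <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", path)) "fastq" else "fasta"
  Biostrings::readDNAStringSet(path, format = fmt)
}

#' Junction microhomology of a deletion
#'
#' Returns the longest `k >= 0` such that the `k` bases starting at
#' `deletion_start` equal the `k` bases starting at `deletion_end + 1`
#' (left-aligned junction homology).
#'
#' @param reference reference sequence (string).
#' @param deletion_start,deletion_end 1-based inclusive deletion interval.
#' @return Integer microhomology length.
#' @export
scan_microhomology <- function(reference, deletion_start, deletion_end) {
  len <- nchar(reference)
  assert_that(deletion_start >= 1L && deletion_end <= len &&
                deletion_start <= deletion_end,
              "deletion interval out of bounds")
  chars <- strsplit(reference, "")[[1]]
  k <- 0L
  while (deletion_start + k <= len && deletion_end + 1L + k <= len &&
         chars[deletion_start + k] == chars[deletion_end + 1L + k]) {
    k <- k + 1L
  }
  k
}

#' Classify the repair pathway of an editing outcome
#'
#' Rules, applied to the indel structure of the outcome allele aligned to the
#' reference: a pure deletion with junction microhomology >= 2 is `MMEJ`;
#' an insertion of 1-3 bp at the cut, or a deletion of <= 3 bp without
#' junction microhomology, is `cNHEJ`; a replacement (deletion plus
#' insertion) whose insert has no exact match of 20 bp or more in the local
#' reference is `SDSA_like`; everything else (including wild type) is
#' `unclassified`.
#'
#' @param outcome one row of [call_amplicon_outcomes()] output (needs
#'   `allele`, `window_start`, `window_end`), or a list with those fields.
#' @param site the [target_site()].
#' @param reference the reference amplicon sequence.
#' @return A list of class `repair_call`: `pathway`, `microhomology_length`,
#'   `replaced_span`, `inserted_length`.
#' @export
classify_repair <- function(outcome, site, reference) {
  ws <- outcome$window_start[1]
  we <- outcome$window_end[1]
  ref_window <- substr(reference, ws, we)
  allele <- outcome$allele[1]

  # anchor the event by the longest exact prefix and suffix shared with the
  # reference window; the unanchored middles are the replaced reference span
  # and the inserted read sequence
  a <- strsplit(allele, "")[[1]]
  r <- strsplit(ref_window, "")[[1]]
  nmin <- min(length(a), length(r))
  pre_mismatch <- which(a[seq_len(nmin)] != r[seq_len(nmin)])
  p <- if (length(pre_mismatch)) pre_mismatch[1] - 1L else nmin
  suf_mismatch <- which(rev(a)[seq_len(nmin)] != rev(r)[seq_len(nmin)])
  s <- if (length(suf_mismatch)) suf_mismatch[1] - 1L else nmin
  s <- min(s, nmin - p)                 # prefix and suffix must not overlap
  mid_read <- length(a) - p - s
  mid_ref <- length(r) - p - s

  res <- list(pathway = "unclassified", microhomology_length = 0L,
              replaced_span = 0L, inserted_length = 0L)

  if (mid_read == 0L && mid_ref > 0L) {
    # pure deletion; left-align before the microhomology scan (maximal
    # prefix anchoring right-shifts deletions with junction homology)
    del_start <- ws + p
    del_end <- del_start + mid_ref - 1L
    chars <- strsplit(reference, "")[[1]]
    while (del_start > 1L && chars[del_start - 1L] == chars[del_end]) {
      del_start <- del_start - 1L
      del_end <- del_end - 1L
    }
    mh <- scan_microhomology(reference, del_start, del_end)
    res$microhomology_length <- mh
    res$pathway <- if (mh >= 2L) "MMEJ"
                   else if (mid_ref <= 3L) "cNHEJ"
                   else "unclassified"
  } else if (mid_ref == 0L && mid_read > 0L) {
    res$inserted_length <- mid_read
    at_cut <- abs((ws + p) - site$cut_pos) <= 5L
    res$pathway <- if (mid_read <= 3L && at_cut) "cNHEJ" else "unclassified"
  } else if (mid_read > 0L && mid_ref > 0L) {
    if (mid_read == mid_ref && mid_read <= 5L) {
      # a short substitution run, not a replacement event
      return(structure(res, class = "repair_call"))
    }
    res$replaced_span <- mid_ref
    res$inserted_length <- mid_read
    insert <- substr(allele, p + 1L, p + mid_read)
    templated <- FALSE
    if (nchar(insert) >= 20L) {
      # any 20-mer of the insert matching the local reference marks the
      # insert as templated
      for (i in seq_len(nchar(insert) - 19L)) {
        if (Biostrings::countPattern(
          Biostrings::DNAString(substr(insert, i, i + 19L)),
          Biostrings::DNAString(reference)
        ) > 0) { templated <- TRUE; break }
      }
    }
    res$pathway <- if (!templated) "SDSA_like" else "unclassified"
  }
  structure(res, class = "repair_call")
}

#' Classify zygosity, mosaicism and transgenerational editing at a site
#'
#' Outcomes with fraction above `error_floor` are considered present. A site
#' is `mosaic` when any single haplotype carries two or more distinct
#' non-reference outcomes, or when more than two outcomes in total are
#' present at a diploid locus. Otherwise zygosity is determined from the
#' outcomes at or above `fixed_threshold`: wild type only is `unedited`; one
#' edited and one wild-type allele is `heterozygous`; the same single edit
#' fixed on both haplotypes (or a single dominant edit with no wild type
#' above threshold) is `homozygous`; two distinct fixed edits are
#' `biallelic`. The `tge_flag` marks continued editing: at a site whose
#' majority outcome is fixed or wild type (fraction at least
#' `1 - tge_band[2]`), at least one additional outcome lies inside
#' `tge_band` with at least `min_tge_reads` supporting reads.
#'
#' @param outcomes data.frame with `net_indel`, `fraction`, `read_count` and
#'   optionally `haplotype_tag` (`"A"`/`"B"`/`"unphased"`); fractions must
#'   sum to 1 overall (or per tagged haplotype).
#' @param error_floor fractions at or below this are treated as noise.
#' @param fixed_threshold minimum fraction for an allele to count as fixed on
#'   a haplotype (default passes a 50% diploid allele).
#' @param tge_band fraction band (inclusive) flagging low-level continued
#'   editing.
#' @param min_tge_reads minimum supporting reads for a TGE outcome.
#' @return A list of class `site_call`: `zygosity` (one of `unedited`,
#'   `heterozygous`, `homozygous`, `biallelic`, `mosaic`), `tge_flag`,
#'   `n_outcomes_present`, `per_haplotype` (summary by tag, when tagged).
#' @export
classify_site <- function(outcomes, error_floor = 0.01,
                          fixed_threshold = 0.35,
                          tge_band = c(0.01, 0.35), min_tge_reads = 4L) {
  tagged <- "haplotype_tag" %in% names(outcomes) &&
    any(outcomes$haplotype_tag %in% c("A", "B"))
  check_sum <- function(fr, what) {
    assert_that(abs(sum(fr) - 1) <= 1e-6,
                sprintf("outcome fractions%s must sum to 1", what))
  }
  if (tagged) {
    for (h in intersect(c("A", "B"), unique(outcomes$haplotype_tag))) {
      check_sum(outcomes$fraction[outcomes$haplotype_tag == h],
                sprintf(" on haplotype %s", h))
    }
  } else {
    check_sum(outcomes$fraction, "")
  }

  present <- outcomes[outcomes$fraction > error_floor, , drop = FALSE]
  edits <- present[present$net_indel != 0L, , drop = FALSE]
  wt_present <- any(present$net_indel == 0L)

  mosaic <- FALSE
  per_hap <- NULL
  if (tagged) {
    per_hap <- do.call(rbind, lapply(c("A", "B"), function(h) {
      ph <- present[present$haplotype_tag == h, , drop = FALSE]
      data.frame(haplotype = h,
                 n_edits = length(unique(ph$net_indel[ph$net_indel != 0L])),
                 wt = any(ph$net_indel == 0L),
                 top_edit = if (any(ph$net_indel != 0L))
                   ph$net_indel[ph$net_indel != 0L][
                     which.max(ph$fraction[ph$net_indel != 0L])]
                 else NA_integer_,
                 stringsAsFactors = FALSE)
    }))
    mosaic <- any(per_hap$n_edits >= 2L)
  }
  if (!mosaic) mosaic <- nrow(present) > 2L

  fixed <- present[present$fraction >= fixed_threshold, , drop = FALSE]
  fixed_edits <- unique(fixed$net_indel[fixed$net_indel != 0L])
  wt_fixed <- any(fixed$net_indel == 0L)

  zygosity <- if (mosaic) {
    "mosaic"
  } else if (nrow(edits) == 0L) {
    "unedited"
  } else if (length(fixed_edits) == 0L) {
    # only sub-threshold edits: a wild-type site with trace editing
    "unedited"
  } else if (length(fixed_edits) == 1L && wt_fixed) {
    "heterozygous"
  } else if (length(fixed_edits) == 1L && !wt_present) {
    "homozygous"
  } else if (length(fixed_edits) == 1L && wt_present) {
    # wild type above floor but below threshold alongside one fixed edit
    "homozygous"
  } else if (length(fixed_edits) == 2L && !wt_fixed) {
    if (tagged && !is.null(per_hap) &&
        all(per_hap$n_edits == 1L) &&
        length(unique(per_hap$top_edit)) == 1L) "homozygous" else "biallelic"
  } else {
    "mosaic"
  }
  if (tagged && !mosaic && !is.null(per_hap)) {
    # tag-aware refinement of the diploid call
    if (all(per_hap$n_edits == 0L)) zygosity <- "unedited"
    else if (sum(per_hap$n_edits >= 1L) == 1L &&
             per_hap$wt[per_hap$n_edits == 0L]) zygosity <- "heterozygous"
    else if (all(per_hap$n_edits == 1L)) {
      zygosity <- if (length(unique(per_hap$top_edit)) == 1L) "homozygous"
                  else "biallelic"
    }
  }

  majority <- max(outcomes$fraction)
  rc <- if ("read_count" %in% names(outcomes)) outcomes$read_count else Inf
  in_band <- outcomes$fraction >= tge_band[1] &
    outcomes$fraction <= tge_band[2] &
    rc >= min_tge_reads
  tge_flag <- majority >= (1 - tge_band[2]) && any(in_band)

  structure(
    list(zygosity = zygosity, tge_flag = tge_flag,
         n_outcomes_present = nrow(present), per_haplotype = per_hap),
    class = "site_call"
  )
}

#' Does a variant overlap the seed sequence?
#'
#' The seed is the 10 PAM-proximal spacer nucleotides — the first 10 nt
#' upstream of the 3' end of the guide — where variation most strongly
#' abolishes Cas9 activity.
#'
#' @param site a [target_site()].
#' @param span_start,span_end 1-based inclusive variant span (an insertion at
#'   the cut has `span_start == span_end == cut_pos`).
#' @return `TRUE` iff the span intersects the seed interval.
#' @export
seed_overlap <- function(site, span_start, span_end = span_start) {
  span_end >= site$seed_start && span_start <= site$seed_end
}
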