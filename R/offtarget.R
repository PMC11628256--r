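pam_matches <- function(pam_bases, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  all(vapply(seq_along(pat), function(i) {
    pam_bases[i] %in% IUPAC[[pat[i]]]
  }, logical(1)))
}

#' Enumerate candidate Cas9 sites for a spacer
#'
#' Scans both strands of a genome for 20-nt protospacer matches with up to
#' `max_mm` mismatches whose 3-bp 3'-adjacent PAM matches one of the given
#' IUPAC patterns (canonical `NGG`; non-canonical `NGA`, `NAG`). Mismatches
#' are counted on the protospacer only; the PAM must match its pattern
#' exactly and PAM mismatches do not count toward `max_mm`. Ambiguous genome
#' bases (`N`) never match — they count as spacer mismatches and disqualify
#' a PAM. Spacers supplied with their PAM (23 nt) are auto-split.
#'
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @param spacer 20-nt protospacer, or 23-nt spacer+PAM.
#' @param max_mm maximum number of protospacer mismatches.
#' @param pam_classes character vector of 3-nt IUPAC PAM patterns.
#' @return A data.frame of sites: `chrom`, `strand`, `spacer_start`,
#'   `spacer_end`, `pam_start`, `pam_end` (all 1-based inclusive on the +
#'   strand), `mismatch_count`, `mismatch_positions` (comma-joined spacer
#'   indices, 1 = PAM-distal) and `pam_class`. One row per
#'   (position, strand, PAM class).
#' @export
enumerate_sites <- function(genome, spacer, max_mm = 5L,
                            pam_classes = c("NGG", "NGA", "NAG")) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  spacer <- toupper(spacer)
  if (nchar(spacer) == 23L) spacer <- substr(spacer, 1L, 20L)
  assert_that(nchar(spacer) == 20L, "spacer must be 20 nt (or 23 nt with PAM)")
  assert_that(all(strsplit(spacer, "")[[1]] %in% BASES),
              "spacer alphabet must be A/C/G/T")
  pat <- Biostrings::DNAString(spacer)
  spacer_chars <- strsplit(spacer, "")[[1]]

  rows <- list()
  for (chrom in names(genome)) {
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") genome[[chrom]]
                 else Biostrings::reverseComplement(genome[[chrom]])
      L <- length(subject)
      if (L < 23L) next
      hits <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mm,
                                       with.indels = FALSE)
      starts <- BiocGenerics::start(hits)
      starts <- starts[starts >= 1L & starts + 22L <= L]
      if (length(starts) == 0) next
      for (s in starts) {
        window <- toupper(as.character(Biostrings::subseq(subject, s, s + 22L)))
        chars <- strsplit(window, "")[[1]]
        pam_bases <- chars[21:23]
        if (any(!pam_bases %in% BASES)) next
        mm_pos <- which(chars[1:20] != spacer_chars)
        if (length(mm_pos) > max_mm) next
        for (pc in pam_classes) {
          if (!pam_matches(pam_bases, pc)) next
          if (strand == "+") {
            sp_start <- s; sp_end <- s + 19L
            pam_start <- s + 20L; pam_end <- s + 22L
          } else {
            sp_start <- L - (s + 19L) + 1L; sp_end <- L - s + 1L
            pam_start <- L - (s + 22L) + 1L; pam_end <- L - (s + 20L) + 1L
          }
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, strand = strand,
            spacer_start = sp_start, spacer_end = sp_end,
            pam_start = pam_start, pam_end = pam_end,
            mismatch_count = length(mm_pos),
            mismatch_positions = paste(mm_pos, collapse = ","),
            pam_class = pc, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(
      chrom = character(0), strand = character(0),
      spacer_start = integer(0), spacer_end = integer(0),
      pam_start = integer(0), pam_end = integer(0),
      mismatch_count = integer(0), mismatch_positions = character(0),
      pam_class = character(0), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, pmin(out$spacer_start, out$pam_start),
                   out$strand, out$pam_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

site_span <- function(sites) {
  data.frame(
    start = pmin(sites$spacer_start, sites$pam_start),
    end = pmax(sites$spacer_end, sites$pam_end)
  )
}

#' Intersect off-target sites with retained variants
#'
#' A variant is a candidate off-target edit when its reference span
#' intersects the 23-bp site span (protospacer plus PAM). Each candidate
#' carries its site's mismatch count and PAM class so per-mismatch tallies
#' can be formed.
#'
#' @param sites site table from [enumerate_sites()].
#' @param retained_variants variant table after hard filtering and control
#'   subtraction.
#' @return A data.frame of candidates: the variant columns plus `site_index`,
#'   `mismatch_count`, `pam_class`, `strand` of the matched site.
#' @export
overlap_variants <- function(sites, retained_variants) {
  empty <- cbind(
    retained_variants[0, , drop = FALSE],
    data.frame(site_index = integer(0), mismatch_count = integer(0),
               pam_class = character(0), site_strand = character(0))
  )
  if (nrow(sites) == 0 || nrow(retained_variants) == 0) return(empty)
  span <- site_span(sites)
  sg <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(span$start, span$end))
  vg <- GenomicRanges::GRanges(
    retained_variants$chrom,
    IRanges::IRanges(retained_variants$pos,
                     variant_span_end(retained_variants))
  )
  hits <- GenomicRanges::findOverlaps(vg, sg)
  if (length(hits) == 0) return(empty)
  vi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  out <- cbind(
    retained_variants[vi, , drop = FALSE],
    data.frame(site_index = si,
               mismatch_count = sites$mismatch_count[si],
               pam_class = sites$pam_class[si],
               site_strand = sites$strand[si],
               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}

#' Per-mismatch site tally
#'
#' For each (mismatch count, PAM class) stratum: total sites and sites
#' containing at least one candidate variant.
#'
#' @param sites site table from [enumerate_sites()].
#' @param candidates output of [overlap_variants()].
#' @param max_mm largest mismatch count to tabulate.
#' @return A data.frame with `pam_class`, `mismatch_count`, `n_sites`,
#'   `n_with_variant`.
#' @export
per_mismatch_tally <- function(sites, candidates, max_mm = 5L) {
  grid <- expand.grid(pam_class = unique(c(sites$pam_class, "NGG")),
                      mismatch_count = 0:max_mm,
                      stringsAsFactors = FALSE)
  grid$n_sites <- mapply(function(pc, mm) {
    sum(sites$pam_class == pc & sites$mismatch_count == mm)
  }, grid$pam_class, grid$mismatch_count)
  grid$n_with_variant <- mapply(function(pc, mm) {
    length(unique(candidates$site_index[
      candidates$pam_class == pc & candidates$mismatch_count == mm
    ]))
  }, grid$pam_class, grid$mismatch_count)
  grid[order(grid$pam_class, grid$mismatch_count), ]
}

#' Triage candidate off-target variants against cross-sample evidence
#'
#' Applies, in order: (1) `shared_background` when the identical variant key
#' occurs in two or more events or in any control call set — recurrence
#' across independent transformation events marks a tissue-culture somatic
#' variant, not a Cas9 edit; (2) `allele_fraction_background` when any other
#' sample or control shows at least `min_support_reads` supporting reads at
#' the locus at a fraction below the calling threshold; (3) the remainder is
#' `putative_cas9` — for SNV candidates the evidence notes that single-base
#' substitutions are not a common outcome of Cas9-dependent editing, so they
#' remain background-leaning.
#'
#' @param candidates output of [overlap_variants()] (must carry `sample_id`,
#'   the event each candidate was called in).
#' @param event_sets named list of per-event retained variant tables.
#' @param control_sets list of control variant tables (may be empty).
#' @param raw_support optional data.frame of per-sample read support at
#'   candidate loci: `chrom`, `pos`, `sample_id`, `supporting_reads`,
#'   `called` (logical: did this sample have a called variant here).
#' @param min_support_reads read-support threshold for rule (2).
#' @return `candidates` with added `label` and `evidence` columns.
#' @export
triage_variants <- function(candidates, event_sets, control_sets = list(),
                            raw_support = NULL, min_support_reads = 2L) {
  if (nrow(candidates) == 0) {
    candidates$label <- character(0)
    candidates$evidence <- character(0)
    return(candidates)
  }
  key_of <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  cand_key <- key_of(candidates)
  event_keys <- lapply(event_sets, key_of)
  control_keys <- unique(unlist(lapply(control_sets, key_of)))
  n_events_with <- vapply(cand_key, function(k) {
    sum(vapply(event_keys, function(ek) k %in% ek, logical(1)))
  }, integer(1))
  is_snv <- nchar(candidates$ref) == 1L &
    !grepl(",", candidates$alt, fixed = TRUE) & nchar(candidates$alt) == 1L

  label <- character(nrow(candidates))
  evidence <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    if (n_events_with[i] >= 2L || cand_key[i] %in% control_keys) {
      label[i] <- "shared_background"
      evidence[i] <- sprintf("identical variant in %d event(s)%s",
                             n_events_with[i],
                             if (cand_key[i] %in% control_keys)
                               " and in controls" else "")
      next
    }
    if (!is.null(raw_support)) {
      sup <- raw_support[raw_support$chrom == candidates$chrom[i] &
                           raw_support$pos == candidates$pos[i], ,
                         drop = FALSE]
      if (nrow(sup) == 0) {
        label[i] <- "putative_cas9"
        evidence[i] <- "no cross-sample support data"
        next
      }
      other <- sup[sup$sample_id != candidates$sample_id[i], , drop = FALSE]
      subthr <- other$supporting_reads >= min_support_reads & !other$called
      if (any(subthr)) {
        label[i] <- "allele_fraction_background"
        evidence[i] <- sprintf(
          "sub-threshold read support in %d other sample(s)", sum(subthr))
        next
      }
    }
    label[i] <- "putative_cas9"
    evidence[i] <- if (is_snv[i]) {
      "SNV: single-base substitutions are not a common Cas9 editing outcome (background-leaning)"
    } else if (is.null(raw_support)) {
      "indel unique to one event; no cross-sample support data"
    } else {
      "indel unique to one event, no support elsewhere"
    }
  }
  candidates$label <- label
  candidates$evidence <- evidence
  candidates
}
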