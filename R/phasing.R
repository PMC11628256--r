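#' Match F1 alternate alleles against the haplotype marker set
#'
#' Produces one observation per marker: label `A` if an F1 alternate allele
#' at the marker position equals the hapA allele, `B` if it equals the hapB
#' allele, and `drop` when there is no F1 call, the alternate matches neither
#' haplotype, or a multi-allelic record matches both (a tie).
#'
#' @param markers marker set from [derive_marker_set()].
#' @param f1_variants variant table of F1 calls against the reference
#'   (columns `chrom`, `pos`, `alt`; multi-allelic `alt` comma-joined).
#' @return The marker data.frame with added columns `f1_alt` (`NA` when no
#'   call) and `label` (`A`, `B` or `drop`), ordered by
#'   (`ref_chrom`, `ref_pos`).
#' @export
match_f1_alleles <- function(markers, f1_variants) {
  if (nrow(markers) > 0 && nrow(f1_variants) > 0) {
    mc <- unique(markers$ref_chrom)
    vc <- unique(f1_variants$chrom)
    if (length(intersect(mc, vc)) == 0) {
      stop("no chromosome names shared between markers and F1 calls; ",
           "marker-only: ", paste(setdiff(mc, vc), collapse = ","),
           "; call-only: ", paste(setdiff(vc, mc), collapse = ","),
           call. = FALSE)
    }
  }
  key_m <- paste(markers$ref_chrom, markers$ref_pos)
  key_v <- paste(f1_variants$chrom, f1_variants$pos)
  idx <- match(key_m, key_v)
  f1_alt <- ifelse(is.na(idx), NA_character_, f1_variants$alt[idx])

  label <- rep("drop", nrow(markers))
  has_call <- !is.na(f1_alt)
  if (any(has_call)) {
    alts <- split_alts(f1_alt[has_call])
    hitA <- mapply(function(a, h) h %in% a, alts,
                   markers$hapA_allele[has_call])
    hitB <- mapply(function(a, h) h %in% a, alts,
                   markers$hapB_allele[has_call])
    lab <- rep("drop", sum(has_call))
    lab[hitA & !hitB] <- "A"
    lab[hitB & !hitA] <- "B"
    label[has_call] <- lab
  }
  out <- markers
  out$f1_alt <- f1_alt
  out$label <- label
  out <- out[order(out$ref_chrom, out$ref_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# threshold count for a window: >= ceiling(congruence * window) same labels
window_threshold <- function(window_size, congruence_threshold) {
  as.integer(ceiling(congruence_threshold * window_size - 1e-9))
}

#' Assign haplotype bins by sliding-window congruence
#'
#' Slides a window of `window_size` consecutive labelled markers (drop-labelled
#' markers are excluded before windowing) along each chromosome in steps of
#' one marker. A window is assigned to haplotype A when at least
#' `ceiling(congruence_threshold * window_size)` of its labels are A
#' (16 of 20 at the defaults), symmetrically for B, and is otherwise
#' unassigned. Each marker takes the haplotype of the assigned windows
#' covering it (conflicting or no coverage leaves it unassigned); maximal
#' runs of same-haplotype markers become bins, and unassigned gaps between
#' two bins of the same haplotype are absorbed into a single bin. Gaps
#' between bins of different haplotypes are left unassigned — they are the
#' breakpoint intervals.
#'
#' @param observations output of [match_f1_alleles()].
#' @param window_size window size in markers.
#' @param congruence_threshold minimum fraction of congruent labels in a
#'   window.
#' @return A data.frame of bins: `ref_chrom`, `start_index` / `end_index`
#'   (1-based indices into the chromosome's labelled-marker sequence),
#'   `start_ref_pos` / `end_ref_pos`, `haplotype` and `congruence` (fraction
#'   of the bin's labels supporting its haplotype).
#' @export
assign_bins <- function(observations, window_size = 20L,
                        congruence_threshold = 0.80) {
  assert_that(window_size >= 1L, "window_size must be positive")
  assert_that(congruence_threshold > 0.5 && congruence_threshold <= 1,
              "congruence_threshold must be in (0.5, 1]")
  w <- as.integer(window_size)
  thr <- window_threshold(w, congruence_threshold)

  labelled <- observations[observations$label %in% c("A", "B"), , drop = FALSE]
  empty <- data.frame(
    ref_chrom = character(0), start_index = integer(0), end_index = integer(0),
    start_ref_pos = integer(0), end_ref_pos = integer(0),
    haplotype = character(0), congruence = numeric(0),
    stringsAsFactors = FALSE
  )
  if (nrow(labelled) == 0) return(empty)

  out <- lapply(split(labelled, labelled$ref_chrom), function(obs) {
    obs <- obs[order(obs$ref_pos), , drop = FALSE]
    n <- nrow(obs)
    if (n < w) {
      warning(sprintf("chromosome %s has %d labelled markers (< window %d); left unassigned",
                      obs$ref_chrom[1], n, w))
      return(empty)
    }
    isA <- obs$label == "A"
    n_win <- n - w + 1L
    cs <- cumsum(isA)
    countA <- cs[w:n] - c(0L, cs[seq_len(n_win - 1L)])
    winA <- countA >= thr
    winB <- (w - countA) >= thr
    tie <- winA & winB
    winA[tie] <- FALSE
    winB[tie] <- FALSE

    # marker m is covered by windows max(1, m-w+1) .. min(m, n_win)
    csA <- c(0L, cumsum(winA))
    csB <- c(0L, cumsum(winB))
    m <- seq_len(n)
    lo <- pmax(1L, m - w + 1L)
    hi <- pmin(m, n_win)
    anyA <- (csA[hi + 1L] - csA[lo]) > 0L
    anyB <- (csB[hi + 1L] - csB[lo]) > 0L
    hap <- rep(NA_character_, n)
    hap[anyA & !anyB] <- "A"
    hap[anyB & !anyA] <- "B"

    # runs of assigned markers, then absorb gaps between same-haplotype runs
    r <- rle(ifelse(is.na(hap), "gap", hap))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != "gap"
    runs <- data.frame(start = starts[keep], end = ends[keep],
                       hap = r$values[keep], stringsAsFactors = FALSE)
    if (nrow(runs) == 0) return(empty)
    merged <- runs[1, , drop = FALSE]
    for (k in seq_len(nrow(runs))[-1]) {
      last <- nrow(merged)
      if (runs$hap[k] == merged$hap[last]) {
        merged$end[last] <- runs$end[k]
      } else {
        merged <- rbind(merged, runs[k, ])
      }
    }
    data.frame(
      ref_chrom = obs$ref_chrom[1],
      start_index = merged$start, end_index = merged$end,
      start_ref_pos = obs$ref_pos[merged$start],
      end_ref_pos = obs$ref_pos[merged$end],
      haplotype = merged$hap,
      congruence = vapply(seq_len(nrow(merged)), function(k) {
        span <- merged$start[k]:merged$end[k]
        mean(obs$label[span] == merged$hap[k])
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Detect recombination breakpoints between haplotype bins
#'
#' Reports one breakpoint per adjacent bin pair with different haplotypes,
#' placed at the integer (floor) midpoint between the last marker of the left
#' bin and the first marker of the right bin. Adjacent bins with the same
#' haplotype are merged silently; single-bin chromosomes yield no breakpoints.
#'
#' @param bins output of [assign_bins()].
#' @return A data.frame with `ref_chrom`, `ref_pos` (midpoint), `from_hap`,
#'   `to_hap`, `left_marker_pos` and `right_marker_pos`.
#' @export
detect_breakpoints <- function(bins) {
  empty <- data.frame(
    ref_chrom = character(0), ref_pos = integer(0),
    from_hap = character(0), to_hap = character(0),
    left_marker_pos = integer(0), right_marker_pos = integer(0),
    stringsAsFactors = FALSE
  )
  if (nrow(bins) == 0) return(empty)
  out <- lapply(split(bins, bins$ref_chrom), function(b) {
    b <- b[order(b$start_ref_pos), , drop = FALSE]
    # merge same-haplotype neighbours
    keep <- c(TRUE, b$haplotype[-1] != b$haplotype[-nrow(b)])
    grp <- factor(cumsum(keep), levels = unique(cumsum(keep)))
    b <- do.call(rbind, lapply(split(b, grp), function(g) {
      g$end_index[1] <- max(g$end_index)
      g$end_ref_pos[1] <- max(g$end_ref_pos)
      g[1, , drop = FALSE]
    }))
    if (nrow(b) < 2) return(empty)
    i <- seq_len(nrow(b) - 1L)
    data.frame(
      ref_chrom = b$ref_chrom[1],
      ref_pos = as.integer((b$end_ref_pos[i] + b$start_ref_pos[i + 1L]) %/% 2L),
      from_hap = b$haplotype[i], to_hap = b$haplotype[i + 1L],
      left_marker_pos = b$end_ref_pos[i],
      right_marker_pos = b$start_ref_pos[i + 1L],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
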