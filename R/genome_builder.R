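#' Build the F1 segment map from bins and breakpoints
#'
#' Constructs the segment map of the synthetic F1 assembly. All chromosomes
#' of the homozygous parent (the reference) are assumed inherited whole and
#' pass through as single `<chrom>_DM` segments. The recombinant haplotype
#' of each chromosome (`<chrom>_RH`) is assembled from haplotype A/B
#' intervals: each reference-coordinate breakpoint is translated into each
#' source haplotype's coordinates via the query position of the nearest
#' flanking marker on the retained side, and terminal segments extend to
#' source position 1 and to the source chromosome end.
#'
#' @param bins haplotype bins from [assign_bins()].
#' @param breakpoints breakpoints from [detect_breakpoints()].
#' @param observations labelled markers from [match_f1_alleles()] (supplies
#'   the haplotype query coordinates used for breakpoint translation).
#' @param source_lengths named list with elements `reference`, `hapA`,
#'   `hapB`, each a named integer vector of chromosome lengths.
#' @return A data.frame of segment records (`f1_chrom`, `f1_start`, `f1_end`,
#'   `source_assembly`, `source_chrom`, `source_start`, `source_end`,
#'   `orientation`), 1-based inclusive, tiling each F1 chromosome.
#' @export
build_segment_map <- function(bins, breakpoints, observations,
                              source_lengths) {
  assert_that(all(c("reference", "hapA", "hapB") %in% names(source_lengths)),
              "source_lengths must name reference, hapA and hapB")
  chroms <- names(source_lengths$reference)
  rows <- list()

  for (chrom in chroms) {
    L <- source_lengths$reference[[chrom]]
    rows[[length(rows) + 1L]] <- data.frame(
      f1_chrom = paste0(chrom, "_DM"), f1_start = 1L, f1_end = as.integer(L),
      source_assembly = "reference", source_chrom = chrom,
      source_start = 1L, source_end = as.integer(L), orientation = "+",
      stringsAsFactors = FALSE
    )

    b <- bins[bins$ref_chrom == chrom, , drop = FALSE]
    if (nrow(b) == 0) {
      warning(sprintf("no haplotype bins on %s; recombinant haplotype omitted",
                      chrom))
      next
    }
    b <- b[order(b$start_ref_pos), , drop = FALSE]
    bp <- breakpoints[breakpoints$ref_chrom == chrom, , drop = FALSE]
    bp <- bp[order(bp$ref_pos), , drop = FALSE]
    assert_that(nrow(bp) == nrow(b) - 1L,
                sprintf("bins and breakpoints inconsistent on %s", chrom))
    obs <- observations[observations$ref_chrom == chrom, , drop = FALSE]
    obs <- obs[order(obs$ref_pos), , drop = FALSE]
    qry_of <- function(ref_pos, hap) {
      i <- match(ref_pos, obs$ref_pos)
      q <- if (hap == "A") obs$hapA_qry_pos[i] else obs$hapB_qry_pos[i]
      if (is.na(q)) {
        stop(sprintf("flanking marker at %s:%d has no %s query coordinate",
                     chrom, ref_pos, hap), call. = FALSE)
      }
      q
    }

    n_seg <- nrow(b)
    src_start <- integer(n_seg)
    src_end <- integer(n_seg)
    for (j in seq_len(n_seg)) {
      hap <- b$haplotype[j]
      hap_len <- source_lengths[[paste0("hap", hap)]][[chrom]]
      src_start[j] <- if (j == 1L) 1L else {
        q <- qry_of(b$start_ref_pos[j], hap)
        as.integer(q - (b$start_ref_pos[j] - bp$ref_pos[j - 1L]) + 1L)
      }
      src_end[j] <- if (j == n_seg) as.integer(hap_len) else {
        q <- qry_of(b$end_ref_pos[j], hap)
        as.integer(q + (bp$ref_pos[j] - b$end_ref_pos[j]))
      }
      assert_that(src_start[j] >= 1L && src_end[j] <= hap_len &&
                    src_start[j] <= src_end[j],
                  sprintf("translated segment %d on %s out of bounds", j, chrom))
    }
    seg_len <- src_end - src_start + 1L
    f1_end <- cumsum(seg_len)
    rows[[length(rows) + 1L]] <- data.frame(
      f1_chrom = paste0(chrom, "_RH"),
      f1_start = as.integer(f1_end - seg_len + 1L), f1_end = as.integer(f1_end),
      source_assembly = paste0("hap", b$haplotype),
      source_chrom = chrom,
      source_start = src_start, source_end = src_end, orientation = "+",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stitch the F1 assembly from a segment map
#'
#' Concatenates the source substrings named by the segment map, in map order,
#' into one sequence per F1 chromosome. Runs of `N` in the sources pass
#' through verbatim.
#'
#' @param segment_map segment records from [build_segment_map()] or
#'   [read_agp()].
#' @param sources named list of [Biostrings::DNAStringSet]s: `reference`,
#'   `hapA`, `hapB`.
#' @return A [Biostrings::DNAStringSet] of F1 chromosomes.
#' @export
stitch_assembly <- function(segment_map, sources) {
  chroms <- unique(segment_map$f1_chrom)
  seqs <- vapply(chroms, function(fc) {
    seg <- segment_map[segment_map$f1_chrom == fc, , drop = FALSE]
    seg <- seg[order(seg$f1_start), , drop = FALSE]
    assert_that(seg$f1_start[1] == 1L &&
                  all(seg$f1_start[-1] == head(seg$f1_end, -1) + 1L),
                sprintf("segments of %s do not tile the chromosome", fc))
    parts <- vapply(seq_len(nrow(seg)), function(j) {
      src <- sources[[seg$source_assembly[j]]]
      assert_that(!is.null(src) && seg$source_chrom[j] %in% names(src),
                  sprintf("unknown source for segment %d of %s", j, fc))
      s <- src[[seg$source_chrom[j]]]
      assert_that(seg$source_end[j] <= length(s) && seg$source_start[j] >= 1L,
                  sprintf("segment %d of %s out of source bounds", j, fc))
      as.character(Biostrings::subseq(s, seg$source_start[j],
                                      seg$source_end[j]))
    }, character(1))
    paste(parts, collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, chroms))
}

#' Write a segment map as AGP 2.1 component lines
#'
#' Component IDs encode the source as `<assembly>:<chromosome>`.
#'
#' @param segment_map segment records.
#' @param path output AGP path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(segment_map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  sm <- segment_map[order(segment_map$f1_chrom, segment_map$f1_start), ,
                    drop = FALSE]
  part <- stats::ave(seq_len(nrow(sm)), sm$f1_chrom, FUN = seq_along)
  lines <- paste(sm$f1_chrom, sm$f1_start, sm$f1_end, part, "W",
                 paste0(sm$source_assembly, ":", sm$source_chrom),
                 sm$source_start, sm$source_end, sm$orientation, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read an AGP file back into a segment map
#'
#' Only `W` (component) lines are consumed; the inverse of [write_agp()].
#'
#' @param path AGP file path.
#' @return A segment-map data.frame.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  f <- f[vapply(f, function(x) x[5] == "W", logical(1))]
  comp <- t(vapply(f, function(x) x[c(1:3, 6:9)], character(7)))
  src <- strsplit(comp[, 4], ":", fixed = TRUE)
  out <- data.frame(
    f1_chrom = comp[, 1],
    f1_start = as.integer(comp[, 2]), f1_end = as.integer(comp[, 3]),
    source_assembly = vapply(src, `[`, character(1), 1L),
    source_chrom = vapply(src, `[`, character(1), 2L),
    source_start = as.integer(comp[, 5]), source_end = as.integer(comp[, 6]),
    orientation = comp[, 7],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Lift a source-assembly position into F1 coordinates
#'
#' Affine shift within the segment containing the position. Positions in
#' source regions that were not inherited raise a `"not inherited"` error.
#'
#' @param segment_map segment records.
#' @param source_assembly one of `"reference"`, `"hapA"`, `"hapB"`.
#' @param source_chrom source chromosome name.
#' @param pos vector of 1-based source positions.
#' @return A data.frame with `f1_chrom` and `f1_pos`.
#' @export
liftover_position <- function(segment_map, source_assembly, source_chrom,
                              pos) {
  seg <- segment_map[segment_map$source_assembly == source_assembly &
                       segment_map$source_chrom == source_chrom, ,
                     drop = FALSE]
  out <- data.frame(f1_chrom = character(length(pos)),
                    f1_pos = integer(length(pos)), stringsAsFactors = FALSE)
  for (i in seq_along(pos)) {
    hit <- which(seg$source_start <= pos[i] & seg$source_end >= pos[i])
    if (length(hit) == 0) {
      stop(sprintf("position %s:%d of %s not inherited in the F1 assembly",
                   source_chrom, pos[i], source_assembly), call. = FALSE)
    }
    hit <- hit[1]
    out$f1_chrom[i] <- seg$f1_chrom[hit]
    out$f1_pos[i] <- seg$f1_start[hit] + (pos[i] - seg$source_start[hit])
  }
  out
}

#' Lift an F1 position back to its source assembly
#'
#' Inverse of [liftover_position()].
#'
#' @param segment_map segment records.
#' @param f1_chrom F1 chromosome name.
#' @param pos vector of 1-based F1 positions.
#' @return A data.frame with `source_assembly`, `source_chrom`, `source_pos`.
#' @export
liftover_inverse <- function(segment_map, f1_chrom, pos) {
  seg <- segment_map[segment_map$f1_chrom == f1_chrom, , drop = FALSE]
  out <- data.frame(source_assembly = character(length(pos)),
                    source_chrom = character(length(pos)),
                    source_pos = integer(length(pos)), stringsAsFactors = FALSE)
  for (i in seq_along(pos)) {
    hit <- which(seg$f1_start <= pos[i] & seg$f1_end >= pos[i])
    if (length(hit) == 0) {
      stop(sprintf("position %s:%d outside the F1 assembly", f1_chrom, pos[i]),
           call. = FALSE)
    }
    hit <- hit[1]
    out$source_assembly[i] <- seg$source_assembly[hit]
    out$source_chrom[i] <- seg$source_chrom[hit]
    out$source_pos[i] <- seg$source_start[hit] + (pos[i] - seg$f1_start[hit])
  }
  out
}

#' Lift a source-assembly interval into F1 coordinates
#'
#' Both ends must fall in the same segment; intervals spanning a segment
#' boundary raise a `"split feature"` error.
#'
#' @param segment_map segment records.
#' @param source_assembly,source_chrom source location.
#' @param start,end 1-based inclusive interval.
#' @return A one-row data.frame with `f1_chrom`, `f1_start`, `f1_end`.
#' @export
liftover_interval <- function(segment_map, source_assembly, source_chrom,
                              start, end) {
  a <- liftover_position(segment_map, source_assembly, source_chrom, start)
  b <- liftover_position(segment_map, source_assembly, source_chrom, end)
  if (a$f1_chrom != b$f1_chrom ||
      (b$f1_pos - a$f1_pos) != (end - start)) {
    stop(sprintf("split feature: %s:%d-%d spans a segment boundary",
                 source_chrom, start, end), call. = FALSE)
  }
  data.frame(f1_chrom = a$f1_chrom, f1_start = a$f1_pos, f1_end = b$f1_pos,
             stringsAsFactors = FALSE)
}
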