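# Independent brute-force oracles used to cross-check the implementation.

# position-by-position off-target scan, written without Biostrings matching:
# plus strand compares the spacer directly; minus strand compares the
# reverse-complemented spacer and PAM laid out on the plus strand.
oracle_enumerate_sites <- function(genome, spacer, max_mm = 5L,
                                   pam_classes = c("NGG", "NGA", "NAG")) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                N = c("A", "C", "G", "T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rows <- list()
  for (chrom in names(genome)) {
    chars <- strsplit(toupper(as.character(genome[[chrom]])), "")[[1]]
    L <- length(chars)
    if (L < 23L) next
    sp <- strsplit(toupper(spacer), "")[[1]][1:20]

    # + strand: spacer at s..s+19, PAM at s+20..s+22
    smax <- L - 22L
    mm <- integer(smax)
    for (i in 1:20) mm <- mm + (chars[(1:smax) + i - 1L] != sp[i])
    for (pc in pam_classes) {
      pat <- strsplit(pc, "")[[1]]
      ok <- rep(TRUE, smax)
      for (j in 1:3) ok <- ok & chars[(1:smax) + 19L + j] %in% iupac[[pat[j]]]
      for (s in which(ok & mm <= max_mm)) {
        mmp <- which(chars[s + 0:19] != sp)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, strand = "+", spacer_start = s, spacer_end = s + 19L,
          pam_start = s + 20L, pam_end = s + 22L, mismatch_count = length(mmp),
          mismatch_positions = paste(mmp, collapse = ","), pam_class = pc,
          stringsAsFactors = FALSE)
      }
    }

    # - strand: plus layout is revcomp(PAM) then revcomp(spacer);
    # q = PAM start on the plus strand
    rc_sp <- rev(unname(comp[sp]))
    qmax <- L - 22L
    mm2 <- integer(qmax)
    for (i in 1:20) mm2 <- mm2 + (chars[(1:qmax) + 2L + i] != rc_sp[i])
    for (pc in pam_classes) {
      pat <- strsplit(pc, "")[[1]]
      rc_pat <- rev(unname(comp[pat]))       # e.g. NGG -> CCN
      ok <- rep(TRUE, qmax)
      for (j in 1:3) {
        ok <- ok & chars[(1:qmax) + j - 1L] %in% iupac[[rc_pat[j]]]
      }
      for (q in which(ok & mm2 <= max_mm)) {
        off <- which(chars[q + 3:22] != rc_sp)          # 1-based plus offset
        mmp <- sort(21L - off)                          # spacer index, PAM-distal = 1
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, strand = "-", spacer_start = q + 3L,
          spacer_end = q + 22L, pam_start = q, pam_end = q + 2L,
          mismatch_count = length(mmp),
          mismatch_positions = paste(mmp, collapse = ","), pam_class = pc,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(0), strand = character(0),
                      spacer_start = integer(0), spacer_end = integer(0),
                      pam_start = integer(0), pam_end = integer(0),
                      mismatch_count = integer(0),
                      mismatch_positions = character(0),
                      pam_class = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

site_keys <- function(sites) {
  sort(paste(sites$chrom, sites$strand, sites$spacer_start, sites$spacer_end,
             sites$pam_start, sites$pam_end, sites$mismatch_count,
             sites$mismatch_positions, sites$pam_class, sep = "|"))
}

# character-by-character microhomology oracle
oracle_microhomology <- function(reference, del_start, del_end) {
  chars <- strsplit(reference, "")[[1]]
  k <- 0L
  repeat {
    i <- del_start + k
    j <- del_end + 1L + k
    if (i > length(chars) || j > length(chars)) break
    if (chars[i] != chars[j]) break
    k <- k + 1L
  }
  k
}

# quadratic interval-intersection oracle for control subtraction
oracle_subtract <- function(events, controls) {
  keep <- rep(TRUE, nrow(events))
  ev_end <- events$pos + nchar(events$ref) - 1L
  ct_end <- controls$pos + nchar(controls$ref) - 1L
  for (i in seq_len(nrow(events))) {
    for (j in seq_len(nrow(controls))) {
      if (events$chrom[i] == controls$chrom[j] &&
          events$pos[i] <= ct_end[j] && ev_end[i] >= controls$pos[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  events[keep, , drop = FALSE]
}

random_genome <- function(n_chrom, len, seed) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n_chrom), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(stats::setNames(seqs,
                                             sprintf("c%02d", seq_len(n_chrom))))
  })
}

random_variant_rows <- function(n, chroms, max_pos, seed) {
  withr::with_seed(seed, {
    v <- data.frame(
      chrom = sample(chroms, n, replace = TRUE),
      pos = sample(seq_len(max_pos), n, replace = TRUE),
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      qd = round(runif(n, 5, 30), 2), mq = round(runif(n, 55, 60), 2),
      dp = sample(10:45, n, replace = TRUE),
      ad_alt = sample(5:30, n, replace = TRUE),
      sample_id = "S", stringsAsFactors = FALSE
    )
    v <- v[order(v$chrom, v$pos), ]
    rownames(v) <- NULL
    v
  })
}
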