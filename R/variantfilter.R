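#' Hard-filter configuration
#'
#' Thresholds of the variant hard filters. In `"event"` mode a record is
#' removed when **any** of the five criteria is violated
#' (`QD < 2.00`, `MQ < 50.00`, `DP < 4`, `DP > 50`, `AD < 4`); in
#' `"assembly"` mode only the conjunctive expression
#' `QD < 2.00 & MQ < 50.00` removes a record — the expression used when
#' selecting calls for haplotype binning.
#'
#' @param qd_min,mq_min,dp_min,dp_max,ad_min thresholds; all comparisons are
#'   strict, so records exactly at a threshold are retained.
#' @param mode `"event"` (disjunctive, all five criteria) or `"assembly"`
#'   (conjunctive, QD and MQ only).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(qd_min = 2.00, mq_min = 50.00, dp_min = 4L,
                          dp_max = 50L, ad_min = 4L,
                          mode = c("event", "assembly")) {
  mode <- match.arg(mode)
  assert_that(dp_min <= dp_max, "dp_min must be <= dp_max")
  structure(list(qd_min = qd_min, mq_min = mq_min, dp_min = dp_min,
                 dp_max = dp_max, ad_min = ad_min, mode = mode),
            class = "filter_config")
}

#' Apply hard filters to a variant table
#'
#' Records missing a required annotation are removed with reason
#' `"missing"`. In event mode each violated criterion is recorded
#' (comma-joined) as the removal reason; in assembly mode the reason is
#' `"qd&mq"`.
#'
#' @param records a variant table (columns `qd`, `mq`, `dp`, `ad_alt`
#'   required; `ad_alt` is the maximum alt-supporting depth of the record).
#' @param config a [filter_config()].
#' @return A list with `retained` (records passing) and `removed` (records
#'   with an added `reason` column).
#' @export
apply_hard_filters <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  need <- c("qd", "mq", "dp", "ad_alt")
  assert_that(all(need %in% names(records)),
              "records must carry qd, mq, dp and ad_alt annotations")
  n <- nrow(records)
  missing_ann <- Reduce(`|`, lapply(records[need], is.na), rep(FALSE, n))

  if (config$mode == "event") {
    fail <- cbind(
      qd = records$qd < config$qd_min,
      mq = records$mq < config$mq_min,
      dp_low = records$dp < config$dp_min,
      dp_high = records$dp > config$dp_max,
      ad = records$ad_alt < config$ad_min
    )
    fail[is.na(fail)] <- FALSE
    remove <- missing_ann | rowSums(fail) > 0
    reason <- vapply(seq_len(n), function(i) {
      if (missing_ann[i]) "missing"
      else paste(colnames(fail)[fail[i, ]], collapse = ",")
    }, character(1))
  } else {
    both <- records$qd < config$qd_min & records$mq < config$mq_min
    both[is.na(both)] <- FALSE
    remove <- missing_ann | both
    reason <- ifelse(missing_ann, "missing", "qd&mq")
  }

  removed <- records[remove, , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason[remove]
  else removed$reason <- character(0)
  list(retained = records[!remove, , drop = FALSE], removed = removed)
}

check_sorted <- function(records, what) {
  if (nrow(records) < 2) return(invisible(TRUE))
  o <- order(records$chrom, records$pos)
  assert_that(identical(o, seq_len(nrow(records))),
              sprintf("%s must be sorted by (chrom, pos)", what))
}

#' Subtract control variants by interval overlap
#'
#' Removes every event record whose reference span (`[pos, pos+len(ref)-1]`)
#' intersects the span of any control record on the same chromosome,
#' regardless of allele identity — the semantics of interval subtraction on
#' VCFs. Control sets are applied cumulatively (e.g. wild-type, then
#' empty-vector), so adding a control set can only shrink the retained set.
#'
#' @param event_records variant table, sorted by (`chrom`, `pos`).
#' @param control_record_sets list of variant tables (each sorted), applied
#'   in order.
#' @return The retained event records.
#' @export
subtract_controls <- function(event_records, control_record_sets) {
  check_sorted(event_records, "event records")
  if (is.data.frame(control_record_sets)) {
    control_record_sets <- list(control_record_sets)
  }
  retained <- event_records
  for (ctrl in control_record_sets) {
    check_sorted(ctrl, "control records")
    if (nrow(retained) == 0 || nrow(ctrl) == 0) next
    ev <- GenomicRanges::GRanges(
      retained$chrom,
      IRanges::IRanges(retained$pos, variant_span_end(retained))
    )
    ct <- GenomicRanges::GRanges(
      ctrl$chrom, IRanges::IRanges(ctrl$pos, variant_span_end(ctrl))
    )
    hit <- GenomicRanges::countOverlaps(ev, ct) > 0
    retained <- retained[!hit, , drop = FALSE]
  }
  rownames(retained) <- NULL
  retained
}

#' Exclusive intersection counts of per-event variant sets
#'
#' For every non-empty subset of events, counts the variant keys
#' (`chrom:pos:ref:alt`) present in exactly that subset — the numbers an
#' UpSet plot of per-event variant intersections displays. Counts sum to the
#' size of the union.
#'
#' @param event_sets named list, one variant table (or character vector of
#'   pre-made keys) per event.
#' @return A data.frame with `subset` (event names joined by `&`), `degree`
#'   and `count`, including zero-count subsets.
#' @export
set_intersections <- function(event_sets) {
  assert_that(length(event_sets) >= 1 && !is.null(names(event_sets)),
              "event_sets must be a named list")
  keys <- lapply(event_sets, function(x) {
    if (is.character(x)) unique(x)
    else unique(paste(x$chrom, x$pos, x$ref, x$alt, sep = ":"))
  })
  universe <- unique(unlist(keys))
  members <- vapply(keys, function(k) universe %in% k,
                    logical(length(universe)))
  if (length(universe) == 1) members <- matrix(members, nrow = 1,
                                               dimnames = list(NULL, names(keys)))
  n <- length(event_sets)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1, , drop = FALSE]
  names(subsets) <- names(event_sets)
  sig <- if (length(universe)) apply(members, 1, paste, collapse = "")
         else character(0)
  out <- data.frame(
    subset = apply(subsets, 1, function(s) {
      paste(names(event_sets)[as.logical(s)], collapse = "&")
    }),
    degree = rowSums(subsets),
    count = vapply(seq_len(nrow(subsets)), function(i) {
      sum(sig == paste(ifelse(as.logical(subsets[i, ]), "TRUE", "FALSE"),
                       collapse = ""))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
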