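## QA/QC of long-read taxonomic hit tables: size selection, identity and
## alignment-length windows, top-hit selection, and reagent-contamination
## (kitome) arithmetic.

#' QC window configuration
#'
#' The windows of the long-read rRNA operon workflow: reads size-selected to
#' 3,700--5,700 bp (the near-full-length operon amplicon) and database hits
#' kept with percent identity between 70 and 95 and an alignment covering
#' more than 1,200 bp of the 16S gene. Length and identity bounds are
#' inclusive; the alignment bound is strictly exclusive (`> aln_min`).
#'
#' @param len_min,len_max read-length window (bp), inclusive.
#' @param id_min,id_max percent-identity window on the 0--100 scale,
#'   inclusive.
#' @param aln_min alignment-length lower bound (bp), exclusive.
#' @return object of class `qc_config`.
#' @export
qc_config <- function(len_min = 3700, len_max = 5700,
                      id_min = 70, id_max = 95, aln_min = 1200) {
  if (len_min >= len_max) stopf("len_min must be < len_max")
  if (!(0 < id_min && id_min < id_max && id_max <= 100))
    stopf("need 0 < id_min < id_max <= 100")
  if (aln_min <= 0) stopf("aln_min must be > 0")
  structure(list(len_min = len_min, len_max = len_max,
                 id_min = id_min, id_max = id_max, aln_min = aln_min),
            class = "qc_config")
}

check_hits <- function(hits, cols) {
  if (!is.data.frame(hits)) stopf("hit records must be a data.frame")
  miss <- setdiff(cols, names(hits))
  if (length(miss))
    stopf("hit records lack column(s): %s", paste(miss, collapse = ", "))
  invisible(hits)
}

#' Size-selection filter on read length
#'
#' Keeps records whose `read_length` lies inside the `[len_min, len_max]`
#' window (both ends inclusive). Record order is preserved and the filter is
#' idempotent. Records with a missing `read_length` (hit tables from reads
#' already size-selected upstream carry none) are kept with a warning by
#' default; `strict = TRUE` turns them into an error.
#'
#' @param hits data.frame of hit records with a `read_length` column.
#' @param qc a [qc_config()].
#' @param strict error on missing read lengths instead of keeping them.
#' @return the surviving records, same columns, original order.
#' @export
filter_read_lengths <- function(hits, qc = qc_config(), strict = FALSE) {
  check_hits(hits, "read_length")
  if (nrow(hits) == 0L) return(hits)
  na <- is.na(hits$read_length)
  if (any(na)) {
    if (strict)
      stopf("%d record(s) lack read_length (strict mode)", sum(na))
    warning(sprintf("%d record(s) lack read_length; kept unfiltered",
                    sum(na)), call. = FALSE)
  }
  keep <- na | (hits$read_length >= qc$len_min & hits$read_length <= qc$len_max)
  hits[keep, , drop = FALSE]
}

#' Identity/alignment QA window on database hits
#'
#' Keeps records with `id_min <= pct_identity <= id_max` (inclusive) and
#' `aln_length > aln_min` (strict). Idempotent; the survivors are a
#' sub-multiset of the input in original order.
#'
#' @inheritParams filter_read_lengths
#' @return the surviving records.
#' @export
filter_hits <- function(hits, qc = qc_config()) {
  check_hits(hits, c("pct_identity", "aln_length"))
  if (nrow(hits) == 0L) return(hits)
  keep <- hits$pct_identity >= qc$id_min & hits$pct_identity <= qc$id_max &
    hits$aln_length > qc$aln_min
  keep[is.na(keep)] <- FALSE
  hits[keep, , drop = FALSE]
}

#' Select one top hit per read
#'
#' Within each `(sample_id, read_id)` group, keeps the record maximizing bit
#' score, breaking ties by higher percent identity, then longer alignment,
#' then lexicographically smallest `taxon_id` — a fully deterministic
#' ordering.
#'
#' @param hits data.frame of hit records (possibly several per read).
#' @return one record per read, in order of first appearance of each read.
#' @export
select_top_hit <- function(hits) {
  check_hits(hits, c("read_id", "taxon_id", "pct_identity", "aln_length",
                     "bit_score"))
  if (nrow(hits) == 0L) return(hits)
  key <- if ("sample_id" %in% names(hits))
    paste(hits$sample_id, hits$read_id, sep = "\r") else hits$read_id
  ord <- order(match(key, unique(key)),
               -hits$bit_score, -hits$pct_identity, -hits$aln_length,
               hits$taxon_id, method = "radix")
  sorted <- hits[ord, , drop = FALSE]
  first <- !duplicated(key[ord])
  out <- sorted[first, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reagent (kitome) contamination estimate
#'
#' Contamination implied by a paired PCR-negative / PCR-positive sequencing
#' run: `100 * neg_count / pos_count` percent, plus the fold-difference
#' `pos_count / neg_count` when any negative reads exist. The canonical
#' benchmark pair of 13 negative vs 41,135 positive QC-passing reads gives
#' 0.03% (two decimals).
#'
#' @param neg_count QC-passing reads in the PCR-negative library (>= 0).
#' @param pos_count QC-passing reads in the PCR-positive library (> 0).
#' @return list with `percent`, `fold` (`NA` when `neg_count` is 0),
#'   `neg_count`, `pos_count`.
#' @export
kitome_contamination <- function(neg_count, pos_count) {
  if (length(pos_count) != 1L || !is.finite(pos_count) || pos_count <= 0)
    stopf("pos_count must be a single positive number (rate undefined)")
  if (length(neg_count) != 1L || !is.finite(neg_count) || neg_count < 0)
    stopf("neg_count must be a single non-negative number")
  list(percent = 100 * neg_count / pos_count,
       fold = if (neg_count > 0) pos_count / neg_count else NA_real_,
       neg_count = neg_count, pos_count = pos_count)
}

#' Per-sample QC summary
#'
#' Tallies record counts per sample before and after each QC stage; the
#' shape serialized to the run's QC summary JSON.
#'
#' @param raw,after_length,after_hits,after_tophit hit data.frames at the
#'   successive stages (any may be `NULL` to skip).
#' @return data.frame with one row per sample and one column per stage.
#' @export
qc_summary <- function(raw, after_length = NULL, after_hits = NULL,
                       after_tophit = NULL) {
  stages <- list(reads_in = raw, after_length_filter = after_length,
                 after_hit_filter = after_hits, after_top_hit = after_tophit)
  stages <- Filter(Negate(is.null), stages)
  ids <- unique(unlist(lapply(stages, function(h) unique(h$sample_id))))
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (nm in names(stages)) {
    tab <- table(factor(stages[[nm]]$sample_id, levels = ids))
    out[[nm]] <- as.integer(tab)
  }
  out
}
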