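## PCR-duplicate marking by mapping endpoints. Captured gDNA libraries are
## amplified after capture, so distinct sequencing reads can descend from one
## original fragment; such copies share exact alignment endpoints. Reads
## sharing (sample, contig, start, end, strand) form a duplicate group; one
## representative per group is kept unflagged.

#' Mark PCR duplicates by alignment endpoints
#'
#' Within each (sample_id, contig, start, end, strand) group exactly one read
#' is left unflagged: the one with the highest mean base QV, ties broken by
#' lexicographically smallest read id. Input order is preserved; no reads are
#' added or removed. Endpoints are alignment (reference) endpoints, so
#' soft-clipped bases play no role. Opposite-strand reads with the same
#' endpoints are distinct molecules and are both kept.
#'
#' @param reads alignment `data.table` with columns sample_id, contig, start,
#'   end, strand, mean_qv (recomputed from `qual` when absent).
#' @return the same table with `is_duplicate` filled in.
#' @export
mark_duplicates <- function(reads) {
  if (nrow(reads) == 0L) {
    if (!"is_duplicate" %in% names(reads)) reads$is_duplicate <- logical(0)
    return(reads)
  }
  stopifnot(length(unique(reads$contig)) == 1L)
  r <- data.table::copy(reads)
  if (!"mean_qv" %in% names(r))
    r[, mean_qv := vapply(qual, mean_read_qv, numeric(1))]
  r[, .row := .I]
  r[, is_duplicate := {
    best <- order(-mean_qv, read_id)[1]
    seq_len(.N) != best
  }, by = .(sample_id, contig, start, end, strand)]
  data.table::setorder(r, .row)
  r[, .row := NULL]
  r[]
}

#' Unique-coverage summary over a target interval
#'
#' Mean depth (from alignment spans of non-duplicate reads) over every
#' position of the target, and the fraction of the target covered at
#' depth >= 1, per sample.
#'
#' @param reads deduplicated alignment table (`is_duplicate` filled; flagged
#'   reads are excluded here).
#' @param target interval `c(start, end)`.
#' @return `data.table` with sample_id, n_reads, mean_unique_coverage,
#'   covered_fraction.
#' @export
coverage_summary <- function(reads, target) {
  if (length(target) != 2L || target[2] < target[1])
    stop("target must be a non-empty interval c(start, end)")
  width <- target[2] - target[1] + 1L
  r <- reads[is.na(is_duplicate) | !is_duplicate]
  if (nrow(r) == 0L)
    return(data.table::data.table(sample_id = character(0), n_reads = integer(0),
                                  mean_unique_coverage = numeric(0),
                                  covered_fraction = numeric(0)))
  r[, {
    s <- pmax(start, target[1]); e <- pmin(end, target[2])
    ok <- s <= e
    if (!any(ok)) {
      .(n_reads = 0L, mean_unique_coverage = 0, covered_fraction = 0)
    } else {
      ir <- IRanges::IRanges(start = s[ok], end = e[ok])
      cov_bases <- sum(as.numeric(IRanges::width(ir)))
      covered <- interval_union_width(s[ok], e[ok])
      .(n_reads = sum(ok),
        mean_unique_coverage = cov_bases / width,
        covered_fraction = covered / width)
    }
  }, by = sample_id]
}
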