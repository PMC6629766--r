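## Isoform-level SNP calling from full-length cDNA pileups. Only reads
## assigned to retained isoforms contribute. Bases below QV 13 are excluded;
## positions with pooled filtered coverage >= 40 are tested with a one-sided
## Fisher exact test of the observed (alt, ref) counts against the expected
## sequencing-error counts, Bonferroni-corrected over the number of tested
## positions at a 0.01 cutoff. Substitutions only; positions in or adjacent
## to reference homopolymer runs (>= 4 identical bases) are excluded.
## Per-sample genotypes use the 5+/5+ full-length read rule.

#' Parameters for the cDNA SNP caller
#'
#' @param min_base_qv minimum base QV (default 13).
#' @param min_cov minimum pooled filtered coverage to test a position
#'   (default 40).
#' @param alpha significance cutoff before Bonferroni division (default
#'   0.01).
#' @param homopolymer_len minimum run length defining a homopolymer
#'   (default 4).
#' @param homopolymer_flank exclusion flank around homopolymer runs in bases
#'   (default 1).
#' @param min_gt_reads full-length reads per allele for genotyping
#'   (default 5).
#' @param error_rate per-base substitution error rate assumed under the null
#'   (default 0.005).
#' @return object of class `SnpCallerParams`.
#' @export
snp_caller_params <- function(min_base_qv = 13L, min_cov = 40L, alpha = 0.01,
                              homopolymer_len = 4L, homopolymer_flank = 1L,
                              min_gt_reads = 5L, error_rate = 0.005) {
  stopifnot(alpha > 0, alpha < 1, min_cov > 0, min_base_qv >= 0,
            homopolymer_len > 0, min_gt_reads > 0, error_rate >= 0,
            error_rate <= 1)
  structure(list(min_base_qv = min_base_qv, min_cov = min_cov, alpha = alpha,
                 homopolymer_len = homopolymer_len,
                 homopolymer_flank = homopolymer_flank,
                 min_gt_reads = min_gt_reads, error_rate = error_rate),
            class = "SnpCallerParams")
}

#' QV-filtered pileup of full-length reads
#'
#' Per-position A/C/G/T counts from bases with QV at or above the threshold;
#' insertions and deletions never contribute to counts. Per-sample counts
#' are kept alongside the pooled counts. When an isoform assignment and a
#' retained-isoform set are supplied, only reads assigned to retained
#' isoforms are piled up.
#'
#' @param fl_reads aligned full-length read table.
#' @param contig_len reference length.
#' @param params a `SnpCallerParams`.
#' @param assignment optional read -> isoform table (from [collapse_flnc()]).
#' @param retained_ids optional character vector of retained isoform ids.
#' @return list with `pooled` (position x base count matrix) and
#'   `per_sample` (named list of matrices).
#' @export
flnc_pileup <- function(fl_reads, contig_len, params = snp_caller_params(),
                        assignment = NULL, retained_ids = NULL) {
  r <- fl_reads
  if (!is.null(assignment) && !is.null(retained_ids)) {
    keep_ids <- assignment[isoform_id %in% retained_ids, read_id]
    r <- r[read_id %in% keep_ids]
  }
  samples <- sort(unique(r$sample_id))
  per_sample <- lapply(samples, function(s)
    .sample_pileup(r[sample_id == s], contig_len, params$min_base_qv)$counts[, 1:4])
  names(per_sample) <- samples
  pooled <- Reduce(`+`, per_sample)
  list(pooled = pooled, per_sample = per_sample)
}

#' Reference positions excluded by the homopolymer rule
#'
#' Positions inside, or within `flank` bases of, a run of at least
#' `run_len` identical reference bases.
#'
#' @param ref_seq reference sequence string.
#' @param run_len minimum homopolymer run length (default 4).
#' @param flank exclusion flank (default 1).
#' @return logical vector over reference positions.
#' @export
homopolymer_mask <- function(ref_seq, run_len = 4L, flank = 1L) {
  refc <- s2c(ref_seq)
  r <- rle(refc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mask <- logical(length(refc))
  for (k in which(r$lengths >= run_len)) {
    lo <- max(1L, starts[k] - flank)
    hi <- min(length(refc), ends[k] + flank)
    mask[lo:hi] <- TRUE
  }
  mask
}

#' One-sided Fisher exact p-value for a candidate SNP
#'
#' Tests enrichment of the alternative allele over the expected
#' sequencing-error count: the 2x2 table is `[[alt, ref], [e, cov - e]]`
#' with `e = round(error_rate x cov)`, tested one-sided (greater).
#'
#' @param alt_count,ref_count observed allele counts.
#' @param cov total filtered coverage at the position.
#' @param error_rate assumed per-base substitution error rate.
#' @return the p-value.
#' @export
fisher_snp_p <- function(alt_count, ref_count, cov, error_rate = 0.005) {
  e <- as.integer(floor(error_rate * cov + 0.5))   # round half up
  stats::fisher.test(matrix(c(alt_count, e, ref_count, cov - e), nrow = 2L),
                     alternative = "greater")$p.value
}

#' Call substitution SNPs from a pooled cDNA pileup
#'
#' Positions with pooled filtered coverage at or above `min_cov` are tested
#' (their number is the Bonferroni divisor m). At each, the most frequent
#' non-reference base is the candidate allele and a one-sided Fisher exact
#' test compares `[[alt, ref], [e, cov - e]]` with `e = round(error_rate x
#' cov)`. A SNP is called when the raw p-value is at most `alpha / m` and
#' the position is not homopolymer-adjacent.
#'
#' @param pileup output of [flnc_pileup()].
#' @param locus a `LocusModel`.
#' @param params a `SnpCallerParams`.
#' @return `data.table` of tested significant positions: contig, pos,
#'   ref_base, alt_base, alt_count, ref_count, cov, raw_p, m, called and the
#'   suppression reason for significant-but-excluded positions.
#' @export
call_snps <- function(pileup, locus, params = snp_caller_params()) {
  pooled <- pileup$pooled
  cov <- rowSums(pooled)
  tested <- which(cov >= params$min_cov)
  refc <- s2c(locus$ref_seq)
  tested <- tested[refc[tested] %in% DNA_BASES]   # skip N reference bases
  m <- length(tested)
  if (m == 0L)
    return(data.table::data.table(contig = character(0), pos = integer(0),
                                  ref_base = character(0),
                                  alt_base = character(0),
                                  alt_count = integer(0), ref_count = integer(0),
                                  cov = integer(0), raw_p = numeric(0),
                                  m = integer(0), called = logical(0),
                                  reason = character(0)))
  hp <- homopolymer_mask(locus$ref_seq, params$homopolymer_len,
                         params$homopolymer_flank)
  out <- vector("list", length(tested))
  for (k in seq_along(tested)) {
    p <- tested[k]
    counts <- pooled[p, ]
    ref_b <- refc[p]
    alt_counts <- counts
    alt_counts[ref_b] <- 0L
    alt_b <- names(alt_counts)[which.max(alt_counts)]
    alt_n <- alt_counts[[alt_b]]
    ref_n <- counts[[ref_b]]
    if (alt_n == 0L) next
    covp <- as.integer(cov[p])
    pv <- fisher_snp_p(alt_n, ref_n, covp, params$error_rate)
    if (pv > params$alpha / m) next
    reason <- if (hp[p]) "homopolymer" else "pass"
    out[[k]] <- data.table::data.table(
      contig = locus$contig_name, pos = p, ref_base = ref_b,
      alt_base = alt_b, alt_count = alt_n, ref_count = ref_n, cov = covp,
      raw_p = pv, m = m, called = !hp[p], reason = reason)
  }
  res <- data.table::rbindlist(out)
  if (nrow(res)) data.table::setorder(res, pos)
  res[]
}

#' Genotype samples at a SNP by full-length read counts
#'
#' The evidence rule: 5+ reads for both alleles is heterozygous; 5+ for one
#' allele and fewer than 5 for the other is homozygous for that allele;
#' anything else is inconclusive. A total function over count pairs.
#'
#' @param ref_count,alt_count integer vectors of per-sample supporting
#'   full-length reads.
#' @param min_gt_reads threshold (default 5).
#' @return character vector in {homo_ref, homo_alt, het, inconclusive}.
#' @export
genotype_samples <- function(ref_count, alt_count, min_gt_reads = 5L) {
  ifelse(ref_count >= min_gt_reads & alt_count >= min_gt_reads, "het",
  ifelse(ref_count >= min_gt_reads & alt_count < min_gt_reads, "homo_ref",
  ifelse(alt_count >= min_gt_reads & ref_count < min_gt_reads, "homo_alt",
         "inconclusive")))
}

#' Per-sample genotypes for every called SNP
#'
#' @param snps output of [call_snps()] (rows with `called == TRUE` are
#'   genotyped).
#' @param pileup output of [flnc_pileup()].
#' @param params a `SnpCallerParams`.
#' @return long `data.table`: pos, ref_base, alt_base, sample_id, ref_fl,
#'   alt_fl, genotype.
#' @export
genotype_cdna_snps <- function(snps, pileup, params = snp_caller_params()) {
  called <- snps[called == TRUE]
  out <- list()
  for (s in names(pileup$per_sample)) {
    cnt <- pileup$per_sample[[s]]
    if (nrow(called) == 0L) next
    ref_fl <- cnt[cbind(called$pos, match(called$ref_base, colnames(cnt)))]
    alt_fl <- cnt[cbind(called$pos, match(called$alt_base, colnames(cnt)))]
    out[[s]] <- data.table::data.table(
      pos = called$pos, ref_base = called$ref_base,
      alt_base = called$alt_base, sample_id = s,
      ref_fl = ref_fl, alt_fl = alt_fl,
      genotype = genotype_samples(ref_fl, alt_fl, params$min_gt_reads))
  }
  data.table::rbindlist(out)
}

#' Link called SNPs to the isoforms that cover them
#'
#' An isoform covers a SNP when the SNP position falls in one of its exons.
#' SNP pairs whose covering-isoform sets are disjoint cannot be phased
#' through any single isoform and are reported as unlinkable.
#'
#' @param snps output of [call_snps()].
#' @param isoforms retained isoform list.
#' @return list with `covering` (pos -> isoform ids) and `unlinkable_pairs`
#'   (`data.table` pos1, pos2).
#' @export
link_snps_to_isoforms <- function(snps, isoforms) {
  called <- snps[called == TRUE]
  covering <- lapply(seq_len(nrow(called)), function(i) {
    p <- called$pos[i]
    ids <- vapply(isoforms, function(iso)
      any(p >= iso$chain[, "start"] & p <= iso$chain[, "end"]), logical(1))
    names(isoforms)[ids]
  })
  names(covering) <- as.character(called$pos)
  pairs <- list()
  if (nrow(called) >= 2L) {
    cmb <- utils::combn(nrow(called), 2L)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      if (length(intersect(covering[[i]], covering[[j]])) == 0L)
        pairs[[length(pairs) + 1L]] <-
          data.table::data.table(pos1 = called$pos[i], pos2 = called$pos[j])
    }
  }
  list(covering = covering,
       unlinkable_pairs = if (length(pairs)) data.table::rbindlist(pairs)
                          else data.table::data.table(pos1 = integer(0),
                                                      pos2 = integer(0)))
}
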