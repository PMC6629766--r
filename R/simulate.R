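## Read simulation. Reads are emitted pre-aligned: the simulator knows the
## true coordinates of every base, so alignments are exact up to the planted
## variants and sequencing errors, and junctions of cDNA reads are never
## shifted. Quality values separate correct bases (QV 30-93) from erroneous
## ones (QV 3-20) so that QV thresholds in downstream filters bite.

#' Read-simulation configuration
#'
#' @param seed integer; fully determines simulator output.
#' @param gdna_mean_fragment mean sheared gDNA fragment size in bases
#'   (default 6000, emulating 6 kb shearing).
#' @param gdna_fragment_sd fragment size standard deviation (default 600).
#' @param gdna_mean_coverage per-sample fold coverage used when
#'   `gdna_coverage_range` is `NULL` (default 40).
#' @param gdna_coverage_range if non-`NULL`, per-sample coverage is drawn
#'   uniformly from this integer range; default `c(16, 71)`, the unique
#'   coverage range of the emulated study.
#' @param duplicate_rate fraction of gDNA reads that are PCR duplicates
#'   (default 0.3).
#' @param substitution_error_rate per-base substitution error (default 0.004).
#' @param indel_error_rate per-base indel error (default 0.007); together
#'   with substitutions this yields roughly 98.9% read accuracy.
#' @param flnc_reads_per_sample full-length cDNA reads per sample
#'   (default 2000).
#' @param qv_correct,qv_error integer QV ranges for correct and erroneous
#'   bases.
#' @param flnc_end_jitter5,flnc_end_jitter3 sd (bases) of transcript end
#'   jitter; clipped to fit inside the collapse end-clustering tolerances.
#' @param dropout_region optional interval with zero capture coverage
#'   (probe dropout).
#' @param region optional interval restricting gDNA fragment sampling
#'   (targeted capture of a subinterval).
#' @return object of class `ReadSimConfig`.
#' @export
read_sim_config <- function(seed = 1L,
                            gdna_mean_fragment = 6000L,
                            gdna_fragment_sd = 600L,
                            gdna_mean_coverage = 40,
                            gdna_coverage_range = c(16L, 71L),
                            duplicate_rate = 0.3,
                            substitution_error_rate = 0.004,
                            indel_error_rate = 0.007,
                            flnc_reads_per_sample = 2000L,
                            qv_correct = c(30L, 93L),
                            qv_error = c(3L, 20L),
                            flnc_end_jitter5 = 8,
                            flnc_end_jitter3 = 15,
                            dropout_region = NULL,
                            region = NULL) {
  cfg <- list(seed = as.integer(seed),
              gdna_mean_fragment = gdna_mean_fragment,
              gdna_fragment_sd = gdna_fragment_sd,
              gdna_mean_coverage = gdna_mean_coverage,
              gdna_coverage_range = gdna_coverage_range,
              duplicate_rate = duplicate_rate,
              substitution_error_rate = substitution_error_rate,
              indel_error_rate = indel_error_rate,
              flnc_reads_per_sample = as.integer(flnc_reads_per_sample),
              qv_correct = qv_correct, qv_error = qv_error,
              flnc_end_jitter5 = flnc_end_jitter5,
              flnc_end_jitter3 = flnc_end_jitter3,
              dropout_region = dropout_region,
              region = region)
  for (r in c("duplicate_rate", "substitution_error_rate", "indel_error_rate"))
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop(r, " must be in [0, 1]")
  structure(cfg, class = "ReadSimConfig")
}

## ---- haplotype alignment ---------------------------------------------------

# A haplotype represented as an alignment to the reference: one entry per
# reference position (possibly substituted or deleted) plus insertion entries
# anchored after a reference position. Repeat-region alleles are applied as
# block replacements (matched prefix, then insertion or deletion).
build_haplotype_alignment <- function(locus, hap) {
  n <- locus$length
  base <- s2c(locus$ref_seq)
  del <- logical(n)
  if (nrow(hap$snps)) base[hap$snps$pos] <- hap$snps$alt

  ins_anchor <- integer(0)
  ins_base <- list()
  if (nrow(hap$indels)) {
    for (i in seq_len(nrow(hap$indels))) {
      v <- hap$indels[i]
      if (v$type == "del") {
        del[v$pos:(v$pos + v$len - 1L)] <- TRUE
      } else {
        ins_anchor <- c(ins_anchor, v$pos)
        ins_base[[length(ins_base) + 1L]] <- s2c(v$seq)
      }
    }
  }

  apply_block <- function(region, alt_seq) {
    s <- region[1]; e <- region[2]
    n_r <- e - s + 1L
    alt <- s2c(alt_seq)
    n_a <- length(alt)
    k <- min(n_r, n_a)
    base[s:(s + k - 1L)] <<- alt[seq_len(k)]
    del[s:e][seq_len(n_r) <= k] <<- FALSE
    if (n_a > n_r) {
      ins_anchor <<- c(ins_anchor, s + k - 1L)
      ins_base[[length(ins_base) + 1L]] <<- alt[(k + 1L):n_a]
    } else if (n_r > n_a) {
      del[(s + k):e] <<- TRUE
    }
  }
  apply_block(locus$str_region, strrep(locus$str_unit, hap$str_units))
  apply_block(locus$ct_rich_region, locus$ct_catalog[[hap$ct_hap]])

  # assemble ordered entry vectors: (anchor, sub) sorted
  anchor <- seq_len(n)
  sub <- integer(n)
  ref_pos <- seq_len(n)
  if (length(ins_anchor)) {
    ilens <- lengths(ins_base)
    anchor <- c(anchor, rep(ins_anchor, ilens))
    sub <- c(sub, unlist(lapply(ilens, seq_len)))
    ref_pos <- c(ref_pos, rep(NA_integer_, sum(ilens)))
    base <- c(base, unlist(ins_base))
    del <- c(del, rep(FALSE, sum(ilens)))
    ord <- order(anchor, sub)
    anchor <- anchor[ord]; ref_pos <- ref_pos[ord]
    base <- base[ord]; del <- del[ord]
  }
  list(anchor = anchor, ref_pos = ref_pos, base = base, del = del)
}

# indices of haplotype entries with anchor in [s, e]
.hap_slice_idx <- function(hal, s, e) {
  i <- findInterval(c(s - 0.5, e + 0.5), hal$anchor)
  if (i[2] <= i[1]) return(integer(0))
  (i[1] + 1L):i[2]
}

## ---- per-read assembly -----------------------------------------------------

# Apply sequencing errors to a read's entry rows. The first and last aligned
# entries are left untouched so that error processes never change mapping
# endpoints (duplicate marking relies on this guarantee).
.apply_errors <- function(rows, cfg) {
  n <- length(rows$base)
  rows$err <- logical(n)
  alive <- which(!rows$del)
  if (length(alive) > 4L) {
    elig <- alive[-c(1L, length(alive))]
    ns <- rbinom(1L, length(elig), cfg$substitution_error_rate)
    if (ns > 0L) {
      idx <- if (ns == length(elig)) elig else sample(elig, ns)
      shift <- sample.int(3L, ns, replace = TRUE)
      rows$base[idx] <- DNA_BASES[((match(rows$base[idx], DNA_BASES) - 1L +
                                      shift) %% 4L) + 1L]
      rows$err[idx] <- TRUE
    }
    ni <- rbinom(1L, length(elig), cfg$indel_error_rate)
    if (ni > 0L) {
      idx <- if (ni == length(elig)) elig else sample(elig, ni)
      is_del <- runif(ni) < 0.5
      if (any(is_del)) rows$del[idx[is_del]] <- TRUE
      nins <- sum(!is_del)
      if (nins > 0L) {
        key <- c(seq_len(n), idx[!is_del] + 0.5)
        rows <- list(anchor = c(rows$anchor, rows$anchor[idx[!is_del]]),
                     ref_pos = c(rows$ref_pos, rep(NA_integer_, nins)),
                     base = c(rows$base, sample(DNA_BASES, nins, replace = TRUE)),
                     del = c(rows$del, rep(FALSE, nins)),
                     err = c(rows$err, rep(TRUE, nins)))
        ord <- order(key)
        rows <- lapply(rows, function(v) v[ord])
      }
    }
  }
  rows
}

# Turn entry rows into a read record: sequence, qualities, CIGAR (with N for
# reference jumps between exons), reference start/end.
.rows_to_read <- function(rows, cfg) {
  # a deletion error on an inserted base simply removes the insertion
  nas <- is.na(rows$ref_pos)
  gone <- rows$del & nas
  if (any(gone)) {
    rows <- lapply(rows, function(v) v[!gone])
    nas <- is.na(rows$ref_pos)
  }
  op <- rep("M", length(rows$base))
  op[nas] <- "I"
  op[rows$del] <- "D"
  # trim so the alignment starts and ends with M
  m <- which(op == "M")
  if (length(m) == 0L) return(NULL)
  keep_range <- m[1]:m[length(m)]
  rows <- lapply(rows, function(v) v[keep_range])
  op <- op[keep_range]

  keep <- !rows$del
  bases <- rows$base[keep]
  err <- rows$err[keep]
  nq <- length(bases)
  qv <- integer(nq)
  qv[!err] <- sample(cfg$qv_correct[1]:cfg$qv_correct[2], sum(!err),
                     replace = TRUE)
  if (any(err)) qv[err] <- sample(cfg$qv_error[1]:cfg$qv_error[2], sum(err),
                                  replace = TRUE)

  # CIGAR with N gaps where consecutive reference positions jump
  rp <- rows$ref_pos
  rp_fill <- rp
  nas <- is.na(rp_fill)
  if (any(nas)) {
    idx <- cummax(ifelse(nas, 0L, seq_along(rp_fill)))
    rp_fill <- rp_fill[pmax(idx, 1L)]
  }
  gap_before <- c(0L, pmax(diff(rp_fill) - 1L, 0L))
  gap_before[is.na(gap_before)] <- 0L
  brk <- c(TRUE, op[-1] != op[-length(op)]) | gap_before > 0L
  grp <- cumsum(brk)
  g_op <- op[brk]
  g_len <- tabulate(grp)
  g_gap <- gap_before[brk]
  parts <- paste0(ifelse(g_gap > 0L, paste0(g_gap, "N"), ""), g_len, g_op)
  list(seq = c2s(bases),
       qual = qv_to_char(qv),
       cigar = paste(parts, collapse = ""),
       start = rp[1],
       end = rp[length(rp)],
       mean_qv = mean(qv))
}

## ---- gDNA simulation -------------------------------------------------------

#' Simulate captured gDNA long reads with PCR duplicates
#'
#' Fragments are drawn per sample at the configured coverage from a random
#' haplotype, PCR duplicates share a fragment's exact endpoints and haplotype
#' with independently resampled errors, and every read records its source
#' (haplotype, PCR family, duplicate status).
#'
#' @param locus a `LocusModel`.
#' @param truths list of `SampleTruth` (see [make_sample_truths()]).
#' @param cfg a `ReadSimConfig`.
#' @return list with `reads` (alignment `data.table`), `dup_truth`
#'   (per-read duplicate ground truth) and `coverage` (per-sample requested
#'   fold coverage).
#' @export
simulate_gdna <- function(locus, truths, cfg = read_sim_config()) {
  stopifnot(length(truths) >= 1L)
  with_seed(derive_seed(cfg$seed, 1L), {
    all_reads <- list()
    requested <- numeric(0)
    for (tr in truths) {
      hals <- list(build_haplotype_alignment(locus, tr$hap1),
                   build_haplotype_alignment(locus, tr$hap2))
      cov <- if (!is.null(cfg$gdna_coverage_range)) {
        sample(cfg$gdna_coverage_range[1]:cfg$gdna_coverage_range[2], 1L)
      } else cfg$gdna_mean_coverage
      requested[tr$sample_id] <- cov
      target <- if (!is.null(cfg$region)) cfg$region else c(1L, locus$length)
      span <- target[2] - target[1] + 1L
      n_frag <- as.integer(round(cov * span / cfg$gdna_mean_fragment))
      if (n_frag == 0L) {
        warning("zero coverage requested for sample ", tr$sample_id)
        next
      }
      flen <- pmax(1000L, pmin(as.integer(round(
        rnorm(n_frag, cfg$gdna_mean_fragment, cfg$gdna_fragment_sd))),
        as.integer(1.5 * cfg$gdna_mean_fragment)))
      if (is.null(cfg$region)) {
        fs <- sample.int(locus$length - max(flen) + 1L, n_frag, replace = TRUE)
      } else {
        lo <- pmax(1L, target[1] - flen + 1L)
        fs <- lo + as.integer(floor(runif(n_frag) * (target[2] - lo + 1L)))
        fs <- pmin(fs, locus$length - flen + 1L)
      }
      fe <- fs + flen - 1L
      hap <- sample.int(2L, n_frag, replace = TRUE)
      strand <- sample(c("+", "-"), n_frag, replace = TRUE)

      if (!is.null(cfg$dropout_region)) {
        drop <- fs <= cfg$dropout_region[2] & fe >= cfg$dropout_region[1]
        fs <- fs[!drop]; fe <- fe[!drop]; hap <- hap[!drop]
        strand <- strand[!drop]
        n_frag <- length(fs)
      }

      n_dup <- as.integer(round(cfg$duplicate_rate / (1 - cfg$duplicate_rate) *
                                  n_frag))
      src <- if (n_dup > 0L) sample.int(n_frag, n_dup, replace = TRUE)
             else integer(0)
      fam <- c(seq_len(n_frag), src)
      copy_no <- c(rep(0L, n_frag), seq_along(src))

      nr <- length(fam)
      v_start <- integer(nr); v_end <- integer(nr)
      v_cigar <- character(nr); v_seq <- character(nr)
      v_qual <- character(nr); v_mqv <- numeric(nr)
      ok <- logical(nr)
      for (k in seq_len(nr)) {
        f <- fam[k]
        hal <- hals[[hap[f]]]
        rows_idx <- .hap_slice_idx(hal, fs[f], fe[f])
        rows <- list(anchor = hal$anchor[rows_idx],
                     ref_pos = hal$ref_pos[rows_idx],
                     base = hal$base[rows_idx],
                     del = hal$del[rows_idx])
        rows <- .apply_errors(rows, cfg)
        rec <- .rows_to_read(rows, cfg)
        if (is.null(rec)) next
        ok[k] <- TRUE
        v_start[k] <- rec$start; v_end[k] <- rec$end
        v_cigar[k] <- rec$cigar; v_seq[k] <- rec$seq
        v_qual[k] <- rec$qual; v_mqv[k] <- rec$mean_qv
      }
      all_reads[[tr$sample_id]] <- data.table::data.table(
        read_id = sprintf("%s_g%05d_c%d", tr$sample_id, fam, copy_no),
        sample_id = tr$sample_id, contig = locus$contig_name,
        start = v_start, end = v_end, strand = strand[fam],
        cigar = v_cigar, seq = v_seq, qual = v_qual,
        mean_qv = v_mqv, hap = hap[fam],
        family_id = sprintf("%s_f%05d", tr$sample_id, fam),
        read_type = "gdna")[ok]
    }
    reads <- data.table::rbindlist(all_reads)
    if (nrow(reads) == 0L) {
      return(list(reads = reads, dup_truth = data.table::data.table(),
                  coverage = requested))
    }
    data.table::setorder(reads, sample_id, start, end, read_id)
    reads[, is_duplicate := NA]

    # duplicate ground truth: within each PCR family all reads but the
    # representative (highest mean QV, ties by read id) are duplicates
    dup_truth <- reads[, {
      best <- order(-mean_qv, read_id)[1]
      .(read_id = read_id, true_duplicate = seq_len(.N) != best)
    }, by = .(sample_id, family_id)]
    list(reads = reads, dup_truth = dup_truth, coverage = requested)
  })
}

## ---- full-length cDNA simulation ------------------------------------------

#' Simulate full-length cDNA reads from a planted isoform repertoire
#'
#' Each read carries the exact exon chain of its source isoform (junctions
#' are never shifted), with transcript ends jittered within the collapse
#' clustering tolerances, haplotype-of-origin recorded, and per-base QVs.
#' Repertoire members with a `fixed_total` receive exactly that many reads,
#' distributed round-robin across samples, in addition to the per-sample
#' read budget drawn from the isoform mix.
#'
#' @param locus a `LocusModel`.
#' @param truths list of `SampleTruth`.
#' @param cfg a `ReadSimConfig`.
#' @param repertoire isoform repertoire (default `build_repertoire(locus)`).
#' @return list with `reads` (alignment `data.table`) and `iso_truth`
#'   (per-read isoform and haplotype of origin).
#' @export
simulate_flnc <- function(locus, truths, cfg = read_sim_config(),
                          repertoire = build_repertoire(locus)) {
  for (tr in truths) {
    missing <- setdiff(names(tr$isoform_mix), names(repertoire))
    if (length(missing))
      stop("isoform_mix references undefined isoform(s): ",
           paste(missing, collapse = ", "))
  }
  with_seed(derive_seed(cfg$seed, 2L), {
    minus <- locus$strand == "-"
    all_reads <- list()
    fixed <- Filter(function(x) !is.na(x$fixed_total), repertoire)

    for (si in seq_along(truths)) {
      tr <- truths[[si]]
      hals <- list(build_haplotype_alignment(locus, tr$hap1),
                   build_haplotype_alignment(locus, tr$hap2))
      mix <- tr$isoform_mix
      n <- cfg$flnc_reads_per_sample
      iso_ids <- sample(names(mix), n, replace = TRUE, prob = mix)
      # fixed-count members: round-robin share for this sample
      for (fx in fixed) {
        share <- fx$fixed_total %/% length(truths) +
          as.integer(si <= fx$fixed_total %% length(truths))
        if (share > 0L) iso_ids <- c(iso_ids, rep(fx$id, share))
      }
      hap <- sample.int(2L, length(iso_ids), replace = TRUE)

      nr <- length(iso_ids)
      v_start <- integer(nr); v_end <- integer(nr)
      v_cigar <- character(nr); v_seq <- character(nr)
      v_qual <- character(nr); v_mqv <- numeric(nr)
      ok <- logical(nr)
      for (k in seq_len(nr)) {
        iso <- repertoire[[iso_ids[k]]]
        chain <- iso$chain
        # jitter transcript ends within clustering tolerances
        j5 <- max(-20L, min(20L, as.integer(round(rnorm(1, 0, cfg$flnc_end_jitter5)))))
        j3 <- max(-40L, min(40L, as.integer(round(rnorm(1, 0, cfg$flnc_end_jitter3)))))
        ch <- chain
        nex <- nrow(ch)
        if (minus) {        # 5' end = genomic high end of last row
          ch[nex, 2] <- ch[nex, 2] + j5
          ch[1, 1] <- ch[1, 1] - j3
        } else {
          ch[1, 1] <- ch[1, 1] - j5
          ch[nex, 2] <- ch[nex, 2] + j3
        }
        hal <- hals[[hap[k]]]
        idx <- unlist(lapply(seq_len(nex), function(i)
          .hap_slice_idx(hal, ch[i, 1], ch[i, 2])))
        rows <- list(anchor = hal$anchor[idx], ref_pos = hal$ref_pos[idx],
                     base = hal$base[idx], del = hal$del[idx])
        rows <- .apply_errors(rows, cfg)
        rec <- .rows_to_read(rows, cfg)
        if (is.null(rec)) next
        ok[k] <- TRUE
        v_start[k] <- rec$start; v_end[k] <- rec$end
        v_cigar[k] <- rec$cigar; v_seq[k] <- rec$seq
        v_qual[k] <- rec$qual; v_mqv[k] <- rec$mean_qv
      }
      all_reads[[tr$sample_id]] <- data.table::data.table(
        read_id = sprintf("%s_f%05d", tr$sample_id, seq_len(nr)),
        sample_id = tr$sample_id, contig = locus$contig_name,
        start = v_start, end = v_end, strand = locus$strand,
        cigar = v_cigar, seq = v_seq, qual = v_qual,
        mean_qv = v_mqv, hap = hap,
        true_isoform = iso_ids, read_type = "flnc")[ok]
    }
    reads <- data.table::rbindlist(all_reads)
    data.table::setorder(reads, sample_id, start, end, read_id)
    iso_truth <- reads[, .(read_id, sample_id, isoform_id = true_isoform, hap)]
    list(reads = reads, iso_truth = iso_truth)
  })
}
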