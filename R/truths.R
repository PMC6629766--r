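## Ground truth for a simulated 12-subject study: per-sample diploid variant
## sets (intronic SNPs and indels, repeat-region alleles, expressed UTR SNPs)
## and per-sample isoform mixes. The default study has 4 PD, 4 control and
## 4 DLB subjects and the triplet-repeat genotypes observed in the cohort
## the simulator emulates.

.DEFAULT_STR_GENOTYPES <- list(
  "PD-1" = c(15L, 15L), "PD-2" = c(12L, 12L), "PD-3" = c(12L, 12L),
  "PD-4" = c(15L, 12L), "N-1" = c(15L, 12L), "N-2" = c(12L, 12L),
  "N-3" = c(12L, 12L), "N-4" = c(12L, 12L), "DLB-1" = c(12L, 12L),
  "DLB-2" = c(12L, 12L), "DLB-3" = c(15L, 9L), "DLB-4" = c(12L, 12L)
)

.DEFAULT_CT_HAPS <- list(
  c(1L, 2L), c(1L, 1L), c(3L, 4L), c(2L, 2L), c(1L, 4L), c(2L, 3L),
  c(1L, 1L), c(2L, 2L), c(3L, 3L), c(1L, 2L), c(4L, 4L), c(1L, 3L)
)

#' Draw per-sample diploid ground truth for a synthetic locus
#'
#' Builds a population pool of intronic SNPs and short indels, assigns each
#' to sample haplotypes by its population frequency, plants four expressed
#' (exonic, UTR) SNPs at frequency 0.5, and assigns repeat-region alleles:
#' TTG unit counts (9/12/15 against a 16-unit reference) and one of four
#' CT-rich haplotypes per chromosome. Isoform mixes default to the planted
#' repertoire mix.
#'
#' @param locus a `LocusModel`.
#' @param n_samples number of samples (default 12: 4 PD, 4 N, 4 DLB).
#' @param seed integer seed.
#' @param repertoire isoform repertoire (default `build_repertoire(locus)`).
#' @param het_snp_spacing mean spacing of pool SNPs in bases (default 600;
#'   with frequencies 0.2-0.5 this yields roughly one heterozygous site per
#'   1.5 kb per sample).
#' @param str_genotypes named list of 2 TTG unit counts per sample; defaults
#'   to the cohort table the simulator emulates (extended cyclically for
#'   other sample counts).
#' @param ct_haps list of 2 CT-rich catalog ids per sample.
#' @return list of `SampleTruth` objects.
#' @export
make_sample_truths <- function(locus, n_samples = 12L, seed = 1L,
                               repertoire = build_repertoire(locus),
                               het_snp_spacing = 600L,
                               str_genotypes = NULL, ct_haps = NULL) {
  stopifnot(n_samples >= 1L)
  conditions <- rep(c("PD", "N", "DLB"), each = 4L)
  ids <- paste0(conditions, "-", rep(1:4, times = 3))
  if (n_samples != 12L) {
    conditions <- rep_len(c("PD", "N", "DLB"), n_samples)
    ids <- paste0(conditions, "-", seq_len(n_samples))
  }
  if (is.null(str_genotypes))
    str_genotypes <- setNames(rep_len(.DEFAULT_STR_GENOTYPES, n_samples), ids)
  if (is.null(ct_haps)) ct_haps <- rep_len(.DEFAULT_CT_HAPS, n_samples)

  with_seed(seed, {
    allowed <- .allowed_variant_positions(locus)
    n_pool <- max(4L, as.integer(round(locus$length / het_snp_spacing)))
    pool_pos <- sort(sample(allowed, min(n_pool, length(allowed))))
    # enforce a minimum spacing so calls at neighbouring sites stay distinct
    pool_pos <- pool_pos[c(TRUE, diff(pool_pos) >= 10L)]
    refc <- s2c(locus$ref_seq)
    pool <- data.table::data.table(
      pos = pool_pos,
      ref = refc[pool_pos],
      freq = sample(c(0.2, 0.35, 0.5), length(pool_pos), replace = TRUE)
    )
    pool[, alt := vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                         character(1))]

    # short indels, sparser
    remaining <- setdiff(allowed, unlist(lapply(pool_pos, function(p) (p - 8L):(p + 8L))))
    n_ind <- max(2L, as.integer(round(locus$length / 5000L)))
    ind_pos <- sort(sample(remaining, min(n_ind, length(remaining))))
    ind_pos <- ind_pos[c(TRUE, diff(ind_pos) >= 20L)]
    indel_pool <- data.table::data.table(
      pos = ind_pos,
      type = sample(c("del", "ins"), length(ind_pos), replace = TRUE),
      len = sample(1:6, length(ind_pos), replace = TRUE),
      freq = sample(c(0.2, 0.35, 0.5), length(ind_pos), replace = TRUE)
    )
    indel_pool[, seq := ifelse(type == "ins",
                               vapply(len, function(l) c2s(random_dna(l)), character(1)),
                               NA_character_)]

    cdna <- .cdna_snp_sites(locus)

    truths <- vector("list", n_samples)
    for (i in seq_len(n_samples)) {
      haps <- lapply(1:2, function(h) {
        carry <- runif(nrow(pool)) < pool$freq
        snps <- pool[carry, .(pos, ref, alt)]
        carry_c <- runif(nrow(cdna)) < cdna$freq
        snps <- rbind(snps, cdna[carry_c, .(pos, ref, alt)])
        data.table::setorder(snps, pos)
        icarry <- runif(nrow(indel_pool)) < indel_pool$freq
        list(
          snps = snps,
          indels = indel_pool[icarry, .(pos, type, len, seq)],
          str_units = str_genotypes[[ids[i]]][h],
          ct_hap = ct_haps[[i]][h]
        )
      })
      truths[[i]] <- structure(list(
        sample_id = ids[i],
        condition = conditions[i],
        hap1 = haps[[1]],
        hap2 = haps[[2]],
        isoform_mix = repertoire_mix(repertoire)
      ), class = "SampleTruth")
    }
    attr(truths, "snp_pool") <- pool
    attr(truths, "indel_pool") <- indel_pool
    attr(truths, "cdna_snps") <- cdna
    truths
  })
}

# Positions where random variants may be planted: intronic/intergenic, away
# from exons, splice motifs, repeat regions and planted novel elements.
.allowed_variant_positions <- function(locus) {
  forbidden <- logical(locus$length)
  block <- function(s, e, pad = 0L) {
    s <- max(1L, s - pad); e <- min(locus$length, e + pad)
    forbidden[s:e] <<- TRUE
  }
  ex <- locus$gene$exons
  for (i in 1:6) block(ex[i, 1], ex[i, 2], pad = 12L)
  for (fe in locus$gene$alt_first_exons) block(fe[1], fe[2], pad = 12L)
  block(locus$novel_start_exon[1], locus$novel_start_exon[2], pad = 12L)
  block(locus$novel_last_exon[1], locus$novel_last_exon[2], pad = 12L)
  block(locus$str_region[1], locus$str_region[2], pad = 60L)
  block(locus$ct_rich_region[1], locus$ct_rich_region[2], pad = 60L)
  block(locus$decoy_exon4[1], locus$decoy_exon4[2], pad = 12L)
  margin <- max(1000L, as.integer(round(0.06 * locus$length)))
  block(1L, margin)                       # keep variants inside covered span
  block(locus$length - margin, locus$length)
  which(!forbidden)
}

# Four expressed SNP sites at population frequency 0.5: one in each first
# exon option (mutually exclusive usage) and two in the 3' UTR at short and
# long offsets from the stop, so one is covered only by long-UTR isoforms.
# Sites are kept clear of reference homopolymer runs (>= 4) so the cDNA
# caller's homopolymer exclusion never suppresses a planted site.
.cdna_snp_sites <- function(locus) {
  g <- locus$gene
  minus <- locus$strand == "-"
  refc <- s2c(locus$ref_seq)
  pick <- function(center) {
    for (off in c(0L, 1L, -1L, 2L, -2L, 3L, -3L, 4L, -4L, 5L, -5L,
                  6L, -6L, 8L, -8L, 10L, -10L)) {
      p <- center + off
      if (!.near_homopolymer(refc, p, run_len = 4L, flank = 2L)) return(p)
    }
    center
  }
  e1 <- g$alt_first_exons$exon1
  e1b <- g$alt_first_exons$exon1b
  stopb <- g$cds_stop
  sites <- c(
    exon1 = pick(as.integer(mean(e1))),
    exon1b = pick(as.integer(mean(e1b))),
    utr3_near = pick(if (minus) stopb - 120L else stopb + 120L),
    utr3_far = pick(if (minus) stopb - 1400L else stopb + 1400L)
  )
  dt <- data.table::data.table(
    site = names(sites), pos = unname(sites), ref = refc[sites], freq = 0.5
  )
  dt[, alt := vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                     character(1))]
  dt
}

.near_homopolymer <- function(refc, pos, run_len = 4L, flank = 1L) {
  lo <- max(1L, pos - (run_len + flank))
  hi <- min(length(refc), pos + run_len + flank)
  window <- refc[lo:hi]
  r <- rle(window)
  if (!any(r$lengths >= run_len)) return(FALSE)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= run_len
  any(pos >= (lo + starts[keep] - 1L - flank) &
      pos <= (lo + ends[keep] - 1L + flank))
}

#' Expected diploid genotype table from planted truth
#'
#' Flattens a truth list into one row per (variant, sample) with the genotype
#' implied by haplotype carriage, for use as the oracle in genotyping tests.
#'
#' @param truths list of `SampleTruth`.
#' @return `data.table` with columns pos, ref, alt, type, sample_id, gt.
#' @export
variant_truth_table <- function(truths) {
  all_snps <- unique(data.table::rbindlist(lapply(truths, function(tr)
    rbind(tr$hap1$snps, tr$hap2$snps))))
  all_ind <- unique(data.table::rbindlist(lapply(truths, function(tr)
    rbind(tr$hap1$indels, tr$hap2$indels))))
  out <- list()
  for (tr in truths) {
    if (nrow(all_snps)) {
      k <- all_snps[, paste(pos, alt)]
      n_carry <- (k %in% tr$hap1$snps[, paste(pos, alt)]) +
                 (k %in% tr$hap2$snps[, paste(pos, alt)])
      out[[length(out) + 1L]] <- data.table::data.table(
        pos = all_snps$pos, ref = all_snps$ref, alt = all_snps$alt,
        type = "snp", sample_id = tr$sample_id,
        hap1 = as.integer(k %in% tr$hap1$snps[, paste(pos, alt)]),
        hap2 = as.integer(k %in% tr$hap2$snps[, paste(pos, alt)]),
        gt = c("0/0", "0/1", "1/1")[n_carry + 1L]
      )
    }
    if (nrow(all_ind)) {
      k <- all_ind[, paste(pos, type, len)]
      in1 <- k %in% tr$hap1$indels[, paste(pos, type, len)]
      in2 <- k %in% tr$hap2$indels[, paste(pos, type, len)]
      out[[length(out) + 1L]] <- data.table::data.table(
        pos = all_ind$pos, ref = NA_character_,
        alt = ifelse(all_ind$type == "ins", all_ind$seq, NA_character_),
        type = all_ind$type, sample_id = tr$sample_id,
        hap1 = as.integer(in1), hap2 = as.integer(in2),
        gt = c("0/0", "0/1", "1/1")[in1 + in2 + 1L]
      )
    }
  }
  data.table::rbindlist(out)
}
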