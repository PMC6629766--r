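## Diploid short-variant genotyping from deduplicated long-read pileups.
## A deliberately simple allele-fraction genotyper: at each site the fraction
## f of QV-filtered bases supporting the top non-reference allele decides the
## genotype (f < 0.2 hom-ref, 0.2 <= f <= 0.8 het, f > 0.8 hom-alt) —
## fraction thresholds appropriate for high-accuracy long reads. Indels are
## genotyped from alignment gaps by the same fractions. Repeat regions that
## pileup genotyping handles poorly are masked and left to the dedicated
## repeat haplotyper.

.BASE5 <- c("A", "C", "G", "T", "-")

# Per-sample pileup: QV-filtered base counts per position plus insertion
# events (anchored at the position before the inserted bases). Deletions are
# counted in the fifth column regardless of QV (they carry none).
.sample_pileup <- function(reads, contig_len, min_base_qv = 13L) {
  idx_all <- vector("list", nrow(reads))
  ins_pos <- integer(0); ins_seq <- character(0)
  code_map <- integer(128)
  code_map[utf8ToInt("A")] <- 1L; code_map[utf8ToInt("C")] <- 2L
  code_map[utf8ToInt("G")] <- 3L; code_map[utf8ToInt("T")] <- 4L
  for (i in seq_len(nrow(reads))) {
    cg <- parse_cigar(reads$cigar[i])
    rcur <- reads$start[i]; qcur <- 1L
    sc <- utf8ToInt(reads$seq[i])
    qv <- char_to_qv(reads$qual[i])
    acc <- vector("list", length(cg$op))
    for (j in seq_along(cg$op)) {
      l <- cg$len[j]; o <- cg$op[j]
      if (o == "M") {
        p <- rcur:(rcur + l - 1L)
        q <- qcur:(qcur + l - 1L)
        code <- code_map[sc[q]]
        ok <- qv[q] >= min_base_qv & code > 0L
        if (any(ok))
          acc[[j]] <- (p[ok] - 1L) * 5L + code[ok]
        rcur <- rcur + l; qcur <- qcur + l
      } else if (o == "D") {
        acc[[j]] <- (rcur:(rcur + l - 1L) - 1L) * 5L + 5L
        rcur <- rcur + l
      } else if (o == "N") {
        rcur <- rcur + l
      } else if (o == "I") {
        ins_pos <- c(ins_pos, rcur - 1L)
        ins_seq <- c(ins_seq, intToUtf8(sc[qcur:(qcur + l - 1L)]))
        qcur <- qcur + l
      } else if (o == "S") {
        qcur <- qcur + l
      }
    }
    idx_all[[i]] <- unlist(acc, use.names = FALSE)
  }
  tab <- tabulate(unlist(idx_all, use.names = FALSE),
                  nbins = contig_len * 5L)
  counts <- matrix(tab, ncol = 5L, byrow = TRUE,
                   dimnames = list(NULL, .BASE5))
  ins <- if (length(ins_pos))
    data.table::data.table(pos = ins_pos, seq = ins_seq)[, .N, by = .(pos, seq)]
  else data.table::data.table(pos = integer(0), seq = character(0), N = integer(0))
  list(counts = counts, ins = ins)
}

.gt_from_fraction <- function(f, het_min = 0.2, het_max = 0.8) {
  ifelse(f < het_min, "0/0", ifelse(f <= het_max, "0/1", "1/1"))
}

#' Genotype short variants from deduplicated pileups
#'
#' Substitutions, deletions and insertions are discovered per sample at
#' allele fraction >= `het_min` and genotyped in every sample by allele
#' fraction (see module notes). Positions inside `mask` intervals (by
#' default the locus's STR and CT-rich regions plus 50-base flanks) are not
#' genotyped here.
#'
#' @param reads deduplicated alignment table; flagged duplicates are
#'   excluded.
#' @param locus a `LocusModel` (reference sequence and default masks).
#' @param min_depth minimum depth to genotype a sample (default 10).
#' @param min_base_qv minimum base QV for a base to count (default 13).
#' @param het_min,het_max allele-fraction thresholds (defaults 0.2 / 0.8).
#' @param mask list of intervals excluded from genotyping, or `NULL` for the
#'   locus default.
#' @return long-format `data.table`: one row per (variant, sample) with
#'   genotype, depth, allele depths and a quality flag.
#' @export
pileup_genotype <- function(reads, locus, min_depth = 10L, min_base_qv = 13L,
                            het_min = 0.2, het_max = 0.8, mask = NULL) {
  stopifnot(nrow(reads) > 0L)
  if (!all(reads$contig == locus$contig_name))
    stop("reads aligned to a different contig than the reference")
  r <- reads[is.na(is_duplicate) | !is_duplicate]
  if (is.null(mask)) {
    mask <- list(locus$str_region + c(-50L, 50L),
                 locus$ct_rich_region + c(-50L, 50L))
  }
  masked <- logical(locus$length)
  for (mi in mask) masked[max(1L, mi[1]):min(locus$length, mi[2])] <- TRUE
  refc <- s2c(locus$ref_seq)
  ref_code <- match(refc, .BASE5)

  samples <- sort(unique(r$sample_id))
  piles <- lapply(samples, function(s)
    .sample_pileup(r[sample_id == s], locus$length, min_base_qv))
  names(piles) <- samples

  # ---- discovery across samples ----
  snp_sites <- integer(0)
  del_sites <- integer(0)
  ins_sites <- data.table::data.table(pos = integer(0), seq = character(0),
                                      N = integer(0))
  for (s in samples) {
    cnt <- piles[[s]]$counts
    base_depth <- rowSums(cnt[, 1:4])
    depth <- base_depth + cnt[, 5]
    alt_cnt <- {
      tmp <- cnt[, 1:4]
      tmp[cbind(seq_len(nrow(tmp)), pmin(ref_code, 4L))] <- 0L
      row_max_int(tmp)
    }
    f <- ifelse(base_depth > 0, alt_cnt / base_depth, 0)
    snp_sites <- union(snp_sites,
                       which(depth >= min_depth & f >= het_min & !masked))
    fd <- ifelse(depth > 0, cnt[, 5] / depth, 0)
    del_sites <- union(del_sites,
                       which(depth >= min_depth & fd >= het_min & !masked))
    ins <- piles[[s]]$ins
    if (nrow(ins)) {
      ins[, depth_at := depth[pos]]
      cand <- ins[depth_at >= min_depth & N / depth_at >= het_min &
                    !masked[pos], .(pos, seq, N)]
      ins_sites <- rbind(ins_sites, cand)
    }
  }
  snp_sites <- sort(snp_sites)
  # collapse insertion candidates to the dominant sequence per anchor
  if (nrow(ins_sites)) {
    ins_sites <- ins_sites[, .(N = sum(N)), by = .(pos, seq)]
    ins_sites <- ins_sites[order(pos, -N)][, head(.SD, 1L), by = pos]
  }
  # merge consecutive deletion positions into runs
  del_runs <- if (length(del_sites)) {
    ds <- sort(del_sites)
    grp <- cumsum(c(1L, diff(ds) != 1L))
    data.table::data.table(pos = ds, grp = grp)[, .(
      start = min(pos), len = .N), by = grp][, .(start, len)]
  } else data.table::data.table(start = integer(0), len = integer(0))

  # pooled top alt base per SNP site
  pooled <- Reduce(`+`, lapply(piles, `[[`, "counts"))
  alt_base_at <- function(pos) {
    cnt <- pooled[pos, 1:4]
    cnt[pmin(ref_code[pos], 4L)] <- 0L
    .BASE5[which.max(cnt)]
  }

  out <- list()
  for (s in samples) {
    cnt <- piles[[s]]$counts
    base_depth <- rowSums(cnt[, 1:4])
    depth <- base_depth + cnt[, 5]
    if (length(snp_sites)) {
      alt <- vapply(snp_sites, alt_base_at, character(1))
      alt_d <- cnt[cbind(snp_sites, match(alt, .BASE5))]
      ref_d <- cnt[cbind(snp_sites, pmin(ref_code[snp_sites], 4L))]
      f <- ifelse(base_depth[snp_sites] > 0, alt_d / base_depth[snp_sites], 0)
      gt <- .gt_from_fraction(f, het_min, het_max)
      low <- depth[snp_sites] < min_depth
      out[[length(out) + 1L]] <- data.table::data.table(
        contig = locus$contig_name, pos = snp_sites, type = "snp",
        ref_allele = refc[snp_sites], alt_allele = alt, sample_id = s,
        genotype = ifelse(low, "./.", gt),
        depth = depth[snp_sites], ref_depth = ref_d, alt_depth = alt_d,
        qual_flag = ifelse(low, "low_depth", "pass"))
    }
    if (nrow(del_runs)) {
      dd <- cnt[del_runs$start, 5]
      dp <- depth[del_runs$start]
      f <- ifelse(dp > 0, dd / dp, 0)
      gt <- .gt_from_fraction(f, het_min, het_max)
      low <- dp < min_depth
      anchor <- del_runs$start - 1L
      out[[length(out) + 1L]] <- data.table::data.table(
        contig = locus$contig_name, pos = anchor, type = "del",
        ref_allele = vapply(seq_len(nrow(del_runs)), function(i)
          c2s(refc[anchor[i]:(del_runs$start[i] + del_runs$len[i] - 1L)]),
          character(1)),
        alt_allele = refc[anchor], sample_id = s,
        genotype = ifelse(low, "./.", gt),
        depth = dp, ref_depth = dp - dd, alt_depth = dd,
        qual_flag = ifelse(low, "low_depth", "pass"))
    }
    if (nrow(ins_sites)) {
      ins_s <- piles[[s]]$ins
      nmatch <- ins_sites[, {
        m <- ins_s[pos == .BY$pos & seq == .BY$seq]
        .(n = if (nrow(m)) m$N[1] else 0L)
      }, by = .(pos, seq)]
      dp <- depth[ins_sites$pos]
      f <- ifelse(dp > 0, nmatch$n / dp, 0)
      gt <- .gt_from_fraction(f, het_min, het_max)
      low <- dp < min_depth
      out[[length(out) + 1L]] <- data.table::data.table(
        contig = locus$contig_name, pos = ins_sites$pos, type = "ins",
        ref_allele = refc[ins_sites$pos],
        alt_allele = paste0(refc[ins_sites$pos], ins_sites$seq), sample_id = s,
        genotype = ifelse(low, "./.", gt),
        depth = dp, ref_depth = dp - nmatch$n, alt_depth = nmatch$n,
        qual_flag = ifelse(low, "low_depth", "pass"))
    }
  }
  calls <- data.table::rbindlist(out)
  if (nrow(calls) == 0L) {
    calls <- data.table::data.table(
      contig = character(0), pos = integer(0), type = character(0),
      ref_allele = character(0), alt_allele = character(0),
      sample_id = character(0), genotype = character(0), depth = numeric(0),
      ref_depth = numeric(0), alt_depth = numeric(0), qual_flag = character(0))
  } else {
    data.table::setorder(calls, pos, type, sample_id)
  }
  calls[]
}

# rowMax for an integer matrix without extra dependencies
row_max_int <- function(m) {
  do.call(pmax, as.data.frame(m))
}

## ---- read-level alleles at het sites --------------------------------------

# Query base and QV of one read at given reference positions, via a single
# CIGAR walk (no full expansion). Positions not aligned as M return NA.
.bases_at <- function(cigar, start, seq, qual, targets) {
  cg <- parse_cigar(cigar)
  rcur <- start; qcur <- 1L
  base <- rep(NA_character_, length(targets))
  qv_out <- rep(NA_integer_, length(targets))
  qv <- char_to_qv(qual)
  for (j in seq_along(cg$op)) {
    l <- cg$len[j]; o <- cg$op[j]
    if (o == "M") {
      hit <- which(targets >= rcur & targets < rcur + l)
      if (length(hit)) {
        qpos <- qcur + (targets[hit] - rcur)
        base[hit] <- substring(seq, qpos, qpos)
        qv_out[hit] <- qv[qpos]
      }
      rcur <- rcur + l; qcur <- qcur + l
    } else if (o %in% c("D", "N")) {
      rcur <- rcur + l
    } else if (o %in% c("I", "S")) {
      qcur <- qcur + l
    }
  }
  list(base = base, qv = qv_out)
}

# For one sample: allele (0 = ref, 1 = alt, NA = other/low-QV) carried by
# each read at each het site it covers.
.read_alleles <- function(reads, sites, min_base_qv = 13L) {
  out <- list()
  site_pos <- sites$pos
  for (i in seq_len(nrow(reads))) {
    cover <- which(site_pos >= reads$start[i] & site_pos <= reads$end[i])
    if (length(cover) == 0L) next
    ba <- .bases_at(reads$cigar[i], reads$start[i], reads$seq[i],
                    reads$qual[i], site_pos[cover])
    ok <- !is.na(ba$base) & ba$qv >= min_base_qv
    if (!any(ok)) next
    m <- cover[ok]
    allele <- ifelse(ba$base[ok] == sites$alt_allele[m], 1L,
                     ifelse(ba$base[ok] == sites$ref_allele[m], 0L,
                            NA_integer_))
    keep <- !is.na(allele)
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.table::data.table(
      read_id = reads$read_id[i], pos = site_pos[m][keep],
      allele = allele[keep])
  }
  data.table::rbindlist(out)
}

# cis/trans read support for every co-covered pair of het sites
.pair_support <- function(alleles) {
  if (nrow(alleles) == 0L)
    return(data.table::data.table(pos1 = integer(0), pos2 = integer(0),
                                  cis = integer(0), trans = integer(0)))
  pairs <- alleles[alleles, on = "read_id", allow.cartesian = TRUE][pos < i.pos]
  if (nrow(pairs) == 0L)
    return(data.table::data.table(pos1 = integer(0), pos2 = integer(0),
                                  cis = integer(0), trans = integer(0)))
  pairs[, .(cis = sum(allele == i.allele), trans = sum(allele != i.allele)),
        by = .(pos1 = pos, pos2 = i.pos)]
}

#' Flag het calls that do not phase with any nearby partner
#'
#' Automated stand-in for manual review of suspicious variants: for each pair
#' of het sites co-covered by at least `min_pair_reads` reads, the two
#' consistent diploid configurations (cis or trans) should absorb nearly all
#' reads. A het call whose best pairing leaves more than `max_minority` of
#' co-covering reads in minority configurations for every available partner
#' is flagged `phase_inconsistent` and its genotype set to missing. Isolated
#' het calls with no adequately co-covered partner are left unflagged.
#'
#' @param calls output of [pileup_genotype()].
#' @param reads deduplicated alignment table.
#' @param min_pair_reads minimum co-covering reads to judge a pair
#'   (default 8).
#' @param max_minority maximum tolerated minority-configuration fraction
#'   (default 0.2).
#' @param min_base_qv minimum base QV (default 13).
#' @return `calls` with `qual_flag`/`genotype` updated.
#' @export
phase_consistency_filter <- function(calls, reads, min_pair_reads = 8L,
                                     max_minority = 0.2, min_base_qv = 13L) {
  calls <- data.table::copy(calls)
  r <- reads[is.na(is_duplicate) | !is_duplicate]
  for (s in unique(calls$sample_id)) {
    hets <- calls[sample_id == s & genotype == "0/1" & type == "snp" &
                    qual_flag == "pass"]
    if (nrow(hets) < 2L) next
    al <- .read_alleles(r[sample_id == s], hets, min_base_qv)
    sup <- .pair_support(al)
    sup <- sup[cis + trans >= min_pair_reads]
    if (nrow(sup) == 0L) next
    sup[, minority := pmin(cis, trans) / (cis + trans)]
    per_site <- rbind(sup[, .(pos = pos1, minority)],
                      sup[, .(pos = pos2, minority)])
    bad <- per_site[, .(best = min(minority)), by = pos][best > max_minority, pos]
    if (length(bad)) {
      calls[sample_id == s & type == "snp" & pos %in% bad &
              genotype == "0/1",
            `:=`(qual_flag = "phase_inconsistent", genotype = "./.")]
    }
  }
  calls[]
}

## ---- read-backed phasing ---------------------------------------------------

#' Read-backed phasing of heterozygous calls
#'
#' Builds, per sample, a graph over passing het sites with an edge wherever
#' at least one read covers both sites informatively. Each edge is oriented
#' by the majority configuration (cis or trans) and weighted by the majority
#' margin |cis - trans|; tied edges are removed. Haplotype assignments are
#' propagated over a maximum spanning tree of each connected component, and
#' components with at least two sites become phase blocks.
#'
#' @param calls output of [pileup_genotype()] (het pass calls are used).
#' @param reads deduplicated alignment table.
#' @param min_base_qv minimum base QV (default 13).
#' @return list of `PhaseBlock` objects: sample_id, contig, start, end and a
#'   site table with haplotype assignments (`0|1` / `1|0`).
#' @export
read_backed_phase <- function(calls, reads, min_base_qv = 13L) {
  blocks <- list()
  r <- reads[is.na(is_duplicate) | !is_duplicate]
  for (s in sort(unique(calls$sample_id))) {
    hets <- calls[sample_id == s & genotype == "0/1" & type == "snp" &
                    qual_flag == "pass"]
    if (nrow(hets) < 2L) next
    al <- .read_alleles(r[sample_id == s], hets, min_base_qv)
    sup <- .pair_support(al)
    sup <- sup[cis != trans]           # remove tied edges
    if (nrow(sup) == 0L) next
    sup[, `:=`(weight = abs(cis - trans), trans_edge = trans > cis)]
    g <- igraph::graph_from_data_frame(
      sup[, .(from = as.character(pos1), to = as.character(pos2),
              weight = weight, trans_edge = trans_edge)],
      directed = FALSE,
      vertices = data.frame(name = as.character(sort(unique(c(sup$pos1, sup$pos2))))))
    mst <- igraph::mst(g, weights = -igraph::E(g)$weight)
    comps <- igraph::components(mst)
    for (ci in seq_len(comps$no)) {
      members <- names(comps$membership)[comps$membership == ci]
      if (length(members) < 2L) next
      sub <- igraph::induced_subgraph(mst, members)
      root <- members[1]
      hapA <- setNames(rep(NA_integer_, length(members)), members)
      hapA[root] <- 0L
      # orientation propagation over the tree from the (arbitrary) root
      edges <- igraph::as_data_frame(sub, what = "edges")
      both <- rbind(data.frame(a = edges$from, b = edges$to, t = edges$trans_edge),
                    data.frame(a = edges$to, b = edges$from, t = edges$trans_edge))
      adj <- split(both[, c("b", "t")], both$a)
      stack <- root
      while (length(stack)) {
        v <- stack[[1]]; stack <- stack[-1]
        nb <- adj[[v]]
        if (is.null(nb)) next
        for (k in seq_len(nrow(nb))) {
          w <- nb$b[k]
          if (is.na(hapA[w])) {
            hapA[w] <- if (nb$t[k]) 1L - hapA[v] else hapA[v]
            stack <- c(stack, w)
          }
        }
      }
      site_pos <- as.integer(members)
      ord <- order(site_pos)
      sites <- data.table::data.table(
        pos = site_pos[ord],
        phased_gt = ifelse(hapA[members][ord] == 0L, "0|1", "1|0"))
      sites <- merge(sites, hets[, .(pos, ref_allele, alt_allele)],
                     by = "pos", sort = TRUE)
      blocks[[length(blocks) + 1L]] <- structure(list(
        sample_id = s, contig = hets$contig[1],
        start = min(sites$pos), end = max(sites$pos),
        sites = sites), class = "PhaseBlock")
    }
  }
  blocks
}

#' Per-sample phasing summary over a region
#'
#' Total phased span (sum of block widths), its fraction of the region, and
#' the longest block, per sample.
#'
#' @param blocks list of `PhaseBlock`.
#' @param region interval `c(start, end)`.
#' @param samples optional sample ids to report (defaults to those with
#'   blocks).
#' @return `data.table` with sample_id, n_blocks, total_phased_span,
#'   fraction_of_region, longest_block.
#' @export
phasing_summary <- function(blocks, region, samples = NULL) {
  if (length(region) != 2L || region[2] <= region[1] - 1L)
    stop("region must have positive length")
  region_len <- region[2] - region[1] + 1L
  dt <- data.table::rbindlist(lapply(blocks, function(b)
    data.table::data.table(sample_id = b$sample_id, start = b$start,
                           end = b$end)))
  if (is.null(samples))
    samples <- if (nrow(dt)) sort(unique(dt$sample_id)) else character(0)
  out <- lapply(samples, function(s) {
    sub <- if (nrow(dt)) dt[sample_id == s] else dt
    if (nrow(sub) == 0L)
      return(data.table::data.table(sample_id = s, n_blocks = 0L,
                                    total_phased_span = 0,
                                    fraction_of_region = 0,
                                    longest_block = 0))
    span <- sum(sub$end - sub$start + 1L)
    data.table::data.table(sample_id = s, n_blocks = nrow(sub),
                           total_phased_span = span,
                           fraction_of_region = span / region_len,
                           longest_block = max(sub$end - sub$start + 1L))
  })
  data.table::rbindlist(out)
}
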