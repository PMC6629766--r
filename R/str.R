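## Repeat-region haplotyping. Pileup genotypers handle low-complexity and
## length-polymorphic regions poorly, so these regions are resolved directly:
## extract the query subsequence of every read that fully spans the region,
## cluster subsequences by size and then sequence similarity, build a
## per-cluster consensus by star alignment, and genotype each sample from its
## one or two surviving clusters.

#' Extract region-spanning query subsequences
#'
#' For every non-duplicate read fully covering `[region - flank,
#' region + flank]`, returns the query bases between the aligned flank
#' anchors (the last aligned base before the region and the first aligned
#' base after it), i.e. the read's version of the region including any
#' insertions.
#'
#' @param reads alignment table.
#' @param region interval `c(start, end)`.
#' @param flank required anchored flank in bases (default 20).
#' @return `data.table` with read_id, sample_id, sequence.
#' @export
extract_spanning <- function(reads, region, flank = 20L) {
  r <- reads[is.na(is_duplicate) | !is_duplicate]
  r <- r[start <= region[1] - flank & end >= region[2] + flank]
  if (nrow(r) == 0L) {
    warning("no reads span the region")
    return(data.table::data.table(read_id = character(0),
                                  sample_id = character(0),
                                  sequence = character(0)))
  }
  out <- vector("list", nrow(r))
  for (i in seq_len(nrow(r))) {
    # single CIGAR walk: query index of the last aligned base before the
    # region and the first aligned base after it
    cg <- parse_cigar(r$cigar[i])
    rcur <- r$start[i]; qcur <- 1L
    a <- NA_integer_; b <- NA_integer_
    for (j in seq_along(cg$op)) {
      l <- cg$len[j]; o <- cg$op[j]
      if (o == "M") {
        rend <- rcur + l - 1L
        if (rcur < region[1])
          a <- qcur + (min(rend, region[1] - 1L) - rcur)
        if (is.na(b) && rend > region[2])
          b <- qcur + (max(rcur, region[2] + 1L) - rcur)
        rcur <- rcur + l; qcur <- qcur + l
      } else if (o %in% c("D", "N")) {
        rcur <- rcur + l
      } else if (o %in% c("I", "S")) {
        qcur <- qcur + l
      }
    }
    if (is.na(a) || is.na(b) || b - a < 2L) next
    out[[i]] <- data.table::data.table(
      read_id = r$read_id[i], sample_id = r$sample_id[i],
      sequence = substr(r$seq[i], a + 1L, b - 1L))
  }
  data.table::rbindlist(out)
}

#' Cluster subsequences by size, then sequence similarity
#'
#' Two-pass clustering mirroring the stated order "by size and sequence
#' similarity": first single-linkage on length with gap tolerance
#' `size_tol`, then, within each size bin, single-linkage on pairwise edit
#' distance with threshold `ceil(0.05 x mean bin length)`. Clusters with
#' fewer than `min_support` members are discarded.
#'
#' @param subs `data.table` from [extract_spanning()] (one sample's reads).
#' @param size_tol maximum length gap joined into one size bin (default 2).
#' @param dist_frac edit-distance threshold as a fraction of mean length
#'   (default 0.05).
#' @param min_support minimum cluster size (default 3).
#' @return list of `data.table`s (the clusters), ordered by decreasing
#'   support.
#' @export
cluster_by_size_and_similarity <- function(subs, size_tol = 2L,
                                           dist_frac = 0.05,
                                           min_support = 3L) {
  if (nrow(subs) < min_support) {
    warning("fewer subsequences than min_support; no clusters")
    return(list())
  }
  s <- data.table::copy(subs)
  s[, len := nchar(sequence)]
  data.table::setorder(s, len, read_id)
  # size bins: chain lengths whose successive gaps are <= size_tol
  bin <- cumsum(c(1L, diff(s$len) > size_tol))
  clusters <- list()
  for (b in unique(bin)) {
    grp <- s[bin == b]
    if (nrow(grp) == 1L) {
      clusters[[length(clusters) + 1L]] <- grp
      next
    }
    thr <- ceiling(dist_frac * mean(grp$len))
    d <- utils::adist(grp$sequence)
    g <- igraph::graph_from_adjacency_matrix(d <= thr, mode = "undirected",
                                             diag = FALSE)
    memb <- igraph::components(g)$membership
    for (m in unique(memb))
      clusters[[length(clusters) + 1L]] <- grp[memb == m]
  }
  clusters <- Filter(function(cl) nrow(cl) >= min_support, clusters)
  if (length(clusters) == 0L) {
    warning("all clusters below min_support")
    return(list())
  }
  clusters[order(-vapply(clusters, nrow, integer(1)))]
}

#' Majority consensus of a cluster by star alignment
#'
#' Members are globally aligned to an anchor member (the one closest to the
#' cluster's median length; ties by read id), and each anchor column takes
#' the majority base over aligned member bases (gaps vote for deletion);
#' ties keep the anchor's base. Insertions relative to the anchor are kept
#' only when a majority of members share an insertion at the same anchor
#' gap, in which case the most common inserted string is used.
#'
#' @param cluster `data.table` with a `sequence` column.
#' @return consensus DNA string.
#' @export
cluster_consensus <- function(cluster) {
  stopifnot(nrow(cluster) > 0L)
  seqs <- cluster$sequence
  if (nrow(cluster) == 1L) return(seqs[1])
  lens <- nchar(seqs)
  med <- stats::median(lens)
  ord <- order(abs(lens - med), cluster$read_id)
  anchor <- seqs[ord[1]]
  others <- seqs[-ord[1]]
  n_members <- length(seqs)
  la <- nchar(anchor)
  votes <- matrix(0L, nrow = la, ncol = 5L,
                  dimnames = list(NULL, c("A", "C", "G", "T", "-")))
  anchor_chars <- s2c(anchor)
  votes[cbind(seq_len(la), match(anchor_chars, colnames(votes)))] <- 1L
  ins_tab <- list()  # anchor gap position -> inserted strings

  pa_all <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(others),
                                          Biostrings::DNAString(anchor),
                                          type = "global")
  ap_all <- as.character(Biostrings::alignedPattern(pa_all))
  as_all <- as.character(Biostrings::alignedSubject(pa_all))
  for (oi in seq_along(others)) {
    ap <- s2c(ap_all[oi])
    as_ <- s2c(as_all[oi])
    acol <- cumsum(as_ != "-")       # anchor coordinate per alignment column
    is_ins <- as_ == "-"
    keep <- !is_ins & ap %in% c("A", "C", "G", "T", "-")
    if (any(keep)) {
      idx <- cbind(acol[keep], match(ap[keep], colnames(votes)))
      for (r in seq_len(nrow(idx)))
        votes[idx[r, 1], idx[r, 2]] <- votes[idx[r, 1], idx[r, 2]] + 1L
    }
    if (any(is_ins)) {
      runs <- rle(is_ins)
      endpos <- cumsum(runs$lengths)
      startpos <- endpos - runs$lengths + 1L
      for (k in which(runs$values)) {
        gap_at <- acol[startpos[k]]   # insertion after this anchor position
        ins_seq <- c2s(ap[startpos[k]:endpos[k]])
        key <- as.character(gap_at)
        ins_tab[[key]] <- c(ins_tab[[key]], ins_seq)
      }
    }
  }

  cons <- character(la)
  for (i in seq_len(la)) {
    v <- votes[i, ]
    top <- max(v)
    winners <- names(v)[v == top]
    cons[i] <- if (length(winners) == 1L) winners else anchor_chars[i]
  }
  pieces <- ifelse(cons == "-", "", cons)
  # majority insertions
  for (key in names(ins_tab)) {
    if (length(ins_tab[[key]]) > n_members / 2) {
      tab <- sort(table(ins_tab[[key]]), decreasing = TRUE)
      gap_at <- as.integer(key)
      if (gap_at >= 1L && gap_at <= la)
        pieces[gap_at] <- paste0(pieces[gap_at], names(tab)[1])
      }
  }
  c2s(pieces[pieces != ""])
}

#' Longest run of consecutive exact repeat units
#'
#' Maximum number of back-to-back exact copies of `unit` anywhere in `seq`;
#' interrupted repeats count their longest uninterrupted run.
#'
#' @param seq DNA string.
#' @param unit repeat unit (length >= 1).
#' @return integer unit count (0 if the unit never occurs).
#' @export
count_repeat_units <- function(seq, unit) {
  if (!nzchar(unit)) stop("repeat unit must be non-empty")
  k <- nchar(unit)
  if (nchar(seq) < k) return(0L)
  hits <- Biostrings::start(Biostrings::matchPattern(unit, Biostrings::DNAString(seq)))
  if (length(hits) == 0L) return(0L)
  best <- 0L
  # longest chain of occurrences advancing by exactly one unit length;
  # occurrences may overlap (phases), so chain per start
  hitset <- as.integer(hits)
  runlen <- setNames(integer(length(hitset)), hitset)
  for (h in rev(hitset)) {
    nxt <- as.character(h + k)
    runlen[as.character(h)] <- 1L + if (nxt %in% names(runlen)) runlen[[nxt]] else 0L
  }
  max(runlen)
}

#' Genotype a repeat region per sample from its consensus clusters
#'
#' Two surviving clusters give a heterozygous genotype, one gives a
#' homozygous genotype; more than two keeps the two best-supported and flags
#' the sample; none is reported unresolved. Alleles are labelled with the
#' repeat unit count (`(TTG)12`) when a `unit` is given, or with the closest
#' catalog haplotype (smallest edit distance) when a `catalog` is given.
#' By convention allele1 is the better-supported allele.
#'
#' @param clusters list of clusters for one sample (from
#'   [cluster_by_size_and_similarity()]).
#' @param sample_id sample name.
#' @param region_name region label.
#' @param unit repeat unit for unit-count alleles, or `NULL`.
#' @param catalog named character vector/list of haplotype sequences, or
#'   `NULL`.
#' @return one-row `data.table`: sample_id, region_name, allele1, allele2,
#'   unit_count1/2, support1/2, flag.
#' @export
genotype_region <- function(clusters, sample_id, region_name,
                            unit = NULL, catalog = NULL) {
  flag <- ""
  if (length(clusters) == 0L) {
    return(data.table::data.table(
      sample_id = sample_id, region_name = region_name,
      allele1 = NA_character_, allele2 = NA_character_,
      unit_count1 = NA_integer_, unit_count2 = NA_integer_,
      support1 = 0L, support2 = 0L, flag = "unresolved"))
  }
  if (length(clusters) > 2L) {
    flag <- "extra_clusters"
    clusters <- clusters[1:2]
  }
  cons <- vapply(clusters, cluster_consensus, character(1))
  support <- vapply(clusters, nrow, integer(1))
  if (length(cons) == 1L) {       # homozygous
    cons <- c(cons, cons)
    support <- c(support, support)
  }
  ord <- order(-support)
  cons <- cons[ord]; support <- support[ord]
  label <- function(cs) {
    if (!is.null(unit)) {
      sprintf("(%s)%d", unit, count_repeat_units(cs, unit))
    } else if (!is.null(catalog)) {
      d <- utils::adist(cs, unlist(catalog))
      names(catalog)[which.min(d)]
    } else cs
  }
  uc <- if (!is.null(unit))
    vapply(cons, count_repeat_units, integer(1), unit = unit)
  else c(NA_integer_, NA_integer_)
  data.table::data.table(
    sample_id = sample_id, region_name = region_name,
    allele1 = label(cons[1]), allele2 = label(cons[2]),
    unit_count1 = uc[1], unit_count2 = uc[2],
    support1 = support[1], support2 = support[2], flag = flag)
}

#' Full repeat-region genotyping across samples
#'
#' Convenience wrapper: extract spanning subsequences, cluster per sample,
#' and genotype, for one region.
#'
#' @param reads deduplicated alignment table.
#' @param region interval.
#' @param region_name label for the output.
#' @param unit,catalog see [genotype_region()].
#' @param flank,size_tol,dist_frac,min_support clustering parameters.
#' @return `data.table`, one row per sample.
#' @export
genotype_repeat_region <- function(reads, region, region_name,
                                   unit = NULL, catalog = NULL,
                                   flank = 20L, size_tol = 2L,
                                   dist_frac = 0.05, min_support = 3L) {
  subs <- extract_spanning(reads, region, flank)
  out <- list()
  for (s in sort(unique(reads$sample_id))) {
    cl <- suppressWarnings(cluster_by_size_and_similarity(
      subs[sample_id == s], size_tol, dist_frac, min_support))
    out[[s]] <- genotype_region(cl, s, region_name, unit, catalog)
  }
  data.table::rbindlist(out)
}
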