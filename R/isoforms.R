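## Full-length cDNA isoform analysis: collapse aligned full-length reads
## into isoforms by their junction chains, filter on canonical splice motifs
## and full-length read support, classify splice patterns against the
## six-exon gene model, tabulate per-sample abundance, validate junctions
## against short-read support, and predict ORF consequences.

# Mode-seeded greedy 1-D clustering: repeatedly take the most frequent value
# (ties -> smallest) and absorb everything within +/- tol.
.cluster_ends <- function(vals, tol) {
  remaining <- sort(unique(vals))
  cluster_of <- rep(NA_integer_, length(vals))
  modes <- integer(0)
  cl <- 0L
  while (length(remaining)) {
    tab <- table(vals[vals %in% remaining])
    mode <- as.integer(names(tab)[which.max(tab)])
    cl <- cl + 1L
    take <- !is.na(vals) & abs(vals - mode) <= tol & is.na(cluster_of)
    cluster_of[take] <- cl
    modes[cl] <- mode
    remaining <- setdiff(remaining, vals[take])
  }
  list(cluster = cluster_of, modes = modes)
}

#' Collapse aligned full-length reads into isoforms
#'
#' Reads are grouped by identical ordered junction chains (introns from the
#' alignment's N operations). Within a chain group, 5' ends are clustered
#' with tolerance `tol5` and 3' ends with `tol3` (clusters seeded at modes,
#' greedy assignment); each (chain, 5' cluster, 3' cluster) combination is
#' one isoform whose representative ends are the cluster modes. Reads
#' without junctions are grouped by >= 50% reciprocal overlap.
#'
#' @param fl_reads aligned full-length read table.
#' @param strand transcribed strand of the reads (decides which genomic side
#'   is 5'; default `"-"`).
#' @param tol5,tol3 end-clustering tolerances in bases (defaults 50 / 100).
#' @return list with `isoforms` (list; id, contig, strand, chain, junctions,
#'   fl_counts) and `assignment` (`data.table` read_id -> isoform_id).
#' @export
collapse_flnc <- function(fl_reads, strand = "-", tol5 = 50L, tol3 = 100L) {
  stopifnot(nrow(fl_reads) > 0L)
  introns <- vector("list", nrow(fl_reads))
  for (i in seq_len(nrow(fl_reads)))
    introns[[i]] <- cigar_introns(fl_reads$cigar[i], fl_reads$start[i])
  chain_key <- vapply(introns, function(x)
    paste(x$intron_start, x$intron_end, sep = "-", collapse = ";"),
    character(1))
  if (all(chain_key == "")) warning("unspliced-only input; only mono-exon isoforms")

  r <- data.table::data.table(
    idx = seq_len(nrow(fl_reads)), read_id = fl_reads$read_id,
    sample_id = fl_reads$sample_id, start = fl_reads$start,
    end = fl_reads$end, chain_key = chain_key)
  minus <- strand == "-"
  tol_left <- if (minus) tol3 else tol5    # genomic left end tolerance
  tol_right <- if (minus) tol5 else tol3

  isoforms <- list()
  assignment <- list()
  contig <- fl_reads$contig[1]

  for (ck in sort(unique(r$chain_key[r$chain_key != ""]))) {
    grp <- r[chain_key == ck]
    cl_l <- .cluster_ends(grp$start, tol_left)
    cl_r <- .cluster_ends(grp$end, tol_right)
    combos <- unique(data.table::data.table(l = cl_l$cluster, r = cl_r$cluster))
    data.table::setorder(combos, l, r)
    intr <- introns[[grp$idx[1]]]
    for (j in seq_len(nrow(combos))) {
      sel <- cl_l$cluster == combos$l[j] & cl_r$cluster == combos$r[j]
      rep_start <- cl_l$modes[combos$l[j]]
      rep_end <- cl_r$modes[combos$r[j]]
      ex_starts <- c(rep_start, intr$intron_end + 1L)
      ex_ends <- c(intr$intron_start - 1L, rep_end)
      counts <- table(grp$sample_id[sel])
      isoforms[[length(isoforms) + 1L]] <- list(
        contig = contig, strand = strand,
        chain = cbind(start = ex_starts, end = ex_ends),
        junctions = data.table::copy(intr),
        fl_counts = setNames(as.integer(counts), names(counts)))
      assignment[[length(assignment) + 1L]] <- data.table::data.table(
        read_id = grp$read_id[sel], iso_idx = length(isoforms))
    }
  }

  mono <- r[chain_key == ""]
  if (nrow(mono)) {
    ov <- outer(seq_len(nrow(mono)), seq_len(nrow(mono)), function(i, j) {
      inter <- pmax(0L, pmin(mono$end[i], mono$end[j]) -
                      pmax(mono$start[i], mono$start[j]) + 1L)
      wi <- mono$end[i] - mono$start[i] + 1L
      wj <- mono$end[j] - mono$start[j] + 1L
      inter >= 0.5 * wi & inter >= 0.5 * wj
    })
    g <- igraph::graph_from_adjacency_matrix(ov, mode = "undirected",
                                             diag = FALSE)
    memb <- igraph::components(g)$membership
    for (m in sort(unique(memb))) {
      sel <- memb == m
      tab_s <- table(mono$start[sel]); tab_e <- table(mono$end[sel])
      rep_start <- as.integer(names(tab_s)[which.max(tab_s)])
      rep_end <- as.integer(names(tab_e)[which.max(tab_e)])
      counts <- table(mono$sample_id[sel])
      isoforms[[length(isoforms) + 1L]] <- list(
        contig = contig, strand = strand,
        chain = cbind(start = rep_start, end = rep_end),
        junctions = data.table::data.table(intron_start = integer(0),
                                           intron_end = integer(0)),
        fl_counts = setNames(as.integer(counts), names(counts)))
      assignment[[length(assignment) + 1L]] <- data.table::data.table(
        read_id = mono$read_id[sel], iso_idx = length(isoforms))
    }
  }

  # deterministic ids: by decreasing total support, then chain coordinates
  totals <- vapply(isoforms, function(x) sum(x$fl_counts), integer(1))
  keys <- vapply(isoforms, function(x)
    paste(c(t(x$chain)), collapse = ","), character(1))
  ord <- order(-totals, keys)
  isoforms <- isoforms[ord]
  for (i in seq_along(isoforms)) isoforms[[i]]$id <- sprintf("ISO_%03d", i)
  names(isoforms) <- vapply(isoforms, `[[`, character(1), "id")
  amap <- data.table::rbindlist(assignment)
  amap[, isoform_id := sprintf("ISO_%03d", match(iso_idx, ord))]
  amap[, iso_idx := NULL]
  list(isoforms = isoforms, assignment = amap)
}

#' Filter isoforms on splice motifs, support and genomic polyA
#'
#' Drops isoforms with any junction whose strand-oriented motif is not GT-AG
#' or GC-AG, isoforms supported by fewer than `min_fl` total full-length
#' reads, and (optionally) likely intra-priming artifacts whose genomic
#' downstream of the 3' end is adenine-rich (>= `polya_min_a` A in
#' `polya_window` bases on the transcribed strand).
#'
#' @param isoforms isoform list (see [collapse_flnc()]).
#' @param locus a `LocusModel`.
#' @param min_fl minimum total full-length read support (default 20).
#' @param polya_check enable the genomic polyA artifact check (default TRUE).
#' @param polya_min_a,polya_window polyA rule parameters (defaults 12 / 20).
#' @return list with `retained` (isoform list) and `dropped`
#'   (`data.table` id, reason).
#' @export
filter_isoforms <- function(isoforms, locus, min_fl = 20L,
                            polya_check = TRUE, polya_min_a = 12L,
                            polya_window = 20L) {
  retained <- list()
  dropped <- list()
  for (iso in isoforms) {
    reason <- NULL
    if (nrow(iso$junctions)) {
      motifs <- vapply(seq_len(nrow(iso$junctions)), function(j)
        junction_motif(locus$ref_seq, iso$junctions$intron_start[j],
                       iso$junctions$intron_end[j], iso$strand), character(1))
      if (!all(motifs %in% c("GT-AG", "GC-AG")))
        reason <- "noncanonical_junction"
    }
    if (is.null(reason) && sum(iso$fl_counts) < min_fl)
      reason <- "low_fl_support"
    if (is.null(reason) && polya_check) {
      if (iso$strand == "-") {
        end3 <- min(iso$chain[, "start"])
        win <- substr(locus$ref_seq, max(1L, end3 - polya_window), end3 - 1L)
        n_a <- sum(s2c(win) == "T")   # A on the transcribed strand
      } else {
        end3 <- max(iso$chain[, "end"])
        win <- substr(locus$ref_seq, end3 + 1L,
                      min(locus$length, end3 + polya_window))
        n_a <- sum(s2c(win) == "A")
      }
      if (n_a >= polya_min_a) reason <- "intrapriming"
    }
    if (is.null(reason)) retained[[iso$id]] <- iso
    else dropped[[length(dropped) + 1L]] <-
        data.table::data.table(id = iso$id, reason = reason)
  }
  list(retained = retained,
       dropped = if (length(dropped)) data.table::rbindlist(dropped)
                 else data.table::data.table(id = character(0),
                                             reason = character(0)))
}

#' Classify an isoform's splice pattern against the six-exon gene model
#'
#' Precedence: `Skip3` (exon 3 skipped while exon 5 is present), `Skip5`
#' (exon 5 skipped), `Alt5` (first exon or first junction outside every
#' annotated first-exon option, including novel intron-internal starts),
#' `Alt3` (last exon not overlapping annotated exon 6, i.e. a novel or
#' premature 3' end), else `AllExons` (all six exons, any annotated start,
#' any 3' UTR length). "Skipped" means flanked: the isoform has exons both
#' transcriptionally upstream and downstream of the missing exon.
#'
#' @param iso an isoform (list with chain, strand, contig).
#' @param locus a `LocusModel`.
#' @return one of `"AllExons"`, `"Skip3"`, `"Skip5"`, `"Alt5"`, `"Alt3"`.
#' @export
classify_splice_pattern <- function(iso, locus) {
  if (iso$contig != locus$contig_name)
    stop("isoform on contig ", iso$contig, " but locus is ", locus$contig_name)
  ex <- locus$gene$exons
  minus <- locus$strand == "-"
  ch <- iso$chain
  overlaps <- function(a, b) a[1] <= b[2] && b[1] <= a[2]
  present <- vapply(1:6, function(i)
    any(vapply(seq_len(nrow(ch)), function(k)
      overlaps(ch[k, ], ex[i, ]), logical(1))), logical(1))

  # transcript-order extremes of the isoform (genomic)
  tx_hi <- max(ch)   # genomic high edge
  tx_lo <- min(ch)
  upstream_of <- function(i) {   # any isoform exon transcriptionally before exon i
    if (minus) any(ch[, "start"] > ex[i, 2]) else any(ch[, "end"] < ex[i, 1])
  }
  downstream_of <- function(i) {
    if (minus) any(ch[, "end"] < ex[i, 1]) else any(ch[, "start"] > ex[i, 2])
  }
  skipped <- function(i) !present[i] && upstream_of(i) && downstream_of(i)

  if (skipped(3L) && present[5L]) return("Skip3")
  if (skipped(5L)) return("Skip5")

  # first-exon check: the 5'-most exon must match an annotated option at its
  # junction-side boundary (exact) or, for single-exon isoforms, overlap one
  first_row <- if (minus) which.max(ch[, "start"]) else which.min(ch[, "start"])
  fe <- ch[first_row, ]
  opts <- locus$gene$alt_first_exons
  fe_ok <- any(vapply(opts, function(o) {
    if (nrow(ch) == 1L) return(overlaps(fe, o))
    if (minus) fe[1] == o[1] else fe[2] == o[2]
  }, logical(1)))
  if (!fe_ok) return("Alt5")

  last_row <- if (minus) which.min(ch[, "start"]) else which.max(ch[, "start"])
  le <- ch[last_row, ]
  if (!overlaps(le, ex[6, ])) return("Alt3")
  "AllExons"
}

#' Per-sample isoform (or splice-class) abundance table
#'
#' Percent of each sample's retained full-length reads per isoform, or
#' aggregated by splice class. Class percentages sum to 100 per sample.
#'
#' @param isoforms retained isoform list with `splice_class` filled when
#'   `by_class = TRUE`.
#' @param by_class aggregate rows by splice class (default FALSE).
#' @return `data.table`; first column `id` (isoform or class), one column
#'   per sample.
#' @export
abundance <- function(isoforms, by_class = FALSE) {
  samples <- sort(unique(unlist(lapply(isoforms, function(x) names(x$fl_counts)))))
  counts <- data.table::rbindlist(lapply(isoforms, function(iso) {
    v <- setNames(rep(0L, length(samples)), samples)
    v[names(iso$fl_counts)] <- iso$fl_counts
    cbind(data.table::data.table(
      id = if (by_class) iso$splice_class else iso$id),
      data.table::as.data.table(as.list(v)))
  }))
  if (by_class) counts <- counts[, lapply(.SD, sum), by = id]
  totals <- counts[, vapply(.SD, sum, numeric(1)), .SDcols = samples]
  zero <- names(totals)[totals == 0]
  if (length(zero)) warning("sample(s) with zero FL reads: ",
                            paste(zero, collapse = ", "))
  pct <- data.table::copy(counts)
  for (s in samples)
    pct[[s]] <- 100 * pct[[s]] / totals[[s]]
  pct
}

#' Validate isoform junctions against a short-read support table
#'
#' Labels each junction supported when its short-read count reaches
#' `min_support`; junctions absent from the table count 0. An isoform is
#' `confirmed` when all of its novel (unannotated) junctions are supported.
#' With no table, junctions are labelled `unknown`.
#'
#' @param isoforms isoform list.
#' @param locus a `LocusModel` (for the annotated junction set).
#' @param support `data.table` with intron_start, intron_end, count, or
#'   `NULL`.
#' @param min_support minimum short-read count (default 10).
#' @return list with `junctions` (per-junction report) and `isoforms`
#'   (id, confirmed).
#' @export
validate_junctions <- function(isoforms, locus, support, min_support = 10L) {
  ann <- annotated_junctions(locus)
  ann_key <- paste(ann$intron_start, ann$intron_end)
  jn <- list()
  conf <- list()
  for (iso in isoforms) {
    j <- data.table::copy(iso$junctions)
    if (nrow(j) == 0L) {
      conf[[iso$id]] <- data.table::data.table(id = iso$id, confirmed = TRUE)
      next
    }
    j[, isoform_id := iso$id]
    j[, annotated := paste(intron_start, intron_end) %in% ann_key]
    if (is.null(support)) {
      j[, count := NA_integer_]
      j[, status := "unknown"]
      confirmed <- NA
    } else {
      cnt <- support$count[match(paste(j$intron_start, j$intron_end),
                                 paste(support$intron_start, support$intron_end))]
      j[, count := ifelse(is.na(cnt), 0L, cnt)]
      j[, status := ifelse(count >= min_support, "supported", "unsupported")]
      confirmed <- all(j[annotated == FALSE, status] == "supported")
    }
    jn[[iso$id]] <- j
    conf[[iso$id]] <- data.table::data.table(id = iso$id, confirmed = confirmed)
  }
  list(junctions = data.table::rbindlist(jn),
       isoforms = data.table::rbindlist(conf))
}

#' Annotated junction set of the locus gene model
#'
#' The five canonical introns plus the introns implied by annotated
#' alternative first exons.
#'
#' @param locus a `LocusModel`.
#' @return `data.table` with intron_start, intron_end.
#' @export
annotated_junctions <- function(locus) {
  ex <- locus$gene$exons
  out <- lapply(1:5, function(i) {
    iv <- .intron_interval(ex, locus$strand, i)
    data.table::data.table(intron_start = iv[1], intron_end = iv[2])
  })
  # alternative first exon splices to exon 2 with its own donor
  for (nm in setdiff(names(locus$gene$alt_first_exons), "exon1")) {
    o <- locus$gene$alt_first_exons[[nm]]
    iv <- if (locus$strand == "-") c(.intron_interval(ex, "-", 1L)[1], o[1] - 1L)
          else c(o[2] + 1L, .intron_interval(ex, "+", 1L)[2])
    out[[length(out) + 1L]] <- data.table::data.table(intron_start = iv[1],
                                                      intron_end = iv[2])
  }
  unique(data.table::rbindlist(out))
}

#' Synthetic short-read junction support for the simulated study
#'
#' Annotated junctions receive large counts (order 10^6); novel junctions of
#' the planted repertoire receive moderate counts at or above the default
#' confirmation threshold, mirroring rare but real novel junctions.
#'
#' @param locus a `LocusModel`.
#' @param repertoire planted repertoire (default `build_repertoire(locus)`).
#' @return `data.table` with intron_start, intron_end, count.
#' @export
make_junction_support <- function(locus, repertoire = build_repertoire(locus)) {
  ann <- annotated_junctions(locus)
  ann[, count := 1200000L]
  novel <- list()
  for (iso in repertoire) {
    ch <- iso$chain
    if (nrow(ch) < 2L) next
    intr <- data.table::data.table(intron_start = ch[-nrow(ch), 2] + 1L,
                                   intron_end = ch[-1, 1] - 1L)
    novel[[length(novel) + 1L]] <- intr
  }
  novel <- unique(data.table::rbindlist(novel))
  novel <- novel[!paste(intron_start, intron_end) %in%
                   ann[, paste(intron_start, intron_end)]]
  if (nrow(novel)) novel[, count := c(2519L, 44L)[(seq_len(.N) %% 2L) + 1L]]
  rbind(ann, novel)
}

#' Predict the ORF consequence of an isoform
#'
#' Translates from the annotated start codon when the transcript contains
#' it, otherwise from the ATG giving the longest ORF. Status: `canonical`
#' when the protein has the annotated length; `frame_maintained_shorter`
#' when the protein is shorter but terminates at the annotated stop codon
#' (e.g. in-frame exon skipping); `truncated` when a premature or lost stop
#' shortens the protein elsewhere; `none` when no ORF of >= 50 codons
#' exists.
#'
#' @param iso an isoform (chain + strand).
#' @param locus a `LocusModel`.
#' @param min_codons minimum ORF length in codons (default 50).
#' @return list with `orf_status`, `protein_length`, `protein`.
#' @export
predict_orf <- function(iso, locus, min_codons = 50L) {
  tx <- transcript_sequence(iso$chain, locus)
  g <- locus$gene
  start_tx <- .genome_to_tx(iso$chain, g$cds_start, locus$strand)
  if (is.na(start_tx) ||
      substr(tx, start_tx, start_tx + 2L) != "ATG") {
    # fall back to the ATG with the longest ORF
    atgs <- gregexpr("ATG", tx, fixed = TRUE)[[1]]
    if (atgs[1] == -1L) return(list(orf_status = "none", protein_length = 0L,
                                    protein = ""))
    prots <- vapply(atgs, function(a) translate_from(tx, a), character(1))
    best <- which.max(nchar(prots))
    start_tx <- atgs[best]
  }
  prot <- translate_from(tx, start_tx)
  plen <- nchar(prot)
  if (plen < min_codons)
    return(list(orf_status = "none", protein_length = plen, protein = prot))

  stop_tx <- start_tx + 3L * plen            # first base of the stop codon
  has_stop <- stop_tx + 2L <= nchar(tx) &&
    substr(tx, stop_tx, stop_tx + 2L) %in% c("TAA", "TAG", "TGA")
  annotated_stop_first <- if (locus$strand == "-") g$cds_stop + 2L
                          else g$cds_stop - 2L
  stop_genomic <- if (has_stop) .tx_to_genome(iso$chain, stop_tx, locus$strand)
                  else NA_integer_

  status <- if (plen == g$protein_length_aa) {
    "canonical"
  } else if (has_stop && !is.na(stop_genomic) &&
             stop_genomic == annotated_stop_first) {
    "frame_maintained_shorter"
  } else {
    "truncated"
  }
  list(orf_status = status, protein_length = plen, protein = prot)
}

# transcript coordinate of a genomic position within an exon chain (NA when
# the position is not exonic)
.genome_to_tx <- function(chain, gpos, strand) {
  rows <- if (strand == "-") rev(seq_len(nrow(chain))) else seq_len(nrow(chain))
  acc <- 0L
  for (i in rows) {
    s <- chain[i, 1]; e <- chain[i, 2]
    if (gpos >= s && gpos <= e) {
      return(acc + if (strand == "-") e - gpos + 1L else gpos - s + 1L)
    }
    acc <- acc + (e - s + 1L)
  }
  NA_integer_
}

# genomic position of a transcript coordinate
.tx_to_genome <- function(chain, txpos, strand) {
  rows <- if (strand == "-") rev(seq_len(nrow(chain))) else seq_len(nrow(chain))
  acc <- 0L
  for (i in rows) {
    s <- chain[i, 1]; e <- chain[i, 2]
    w <- e - s + 1L
    if (txpos <= acc + w) {
      off <- txpos - acc
      return(if (strand == "-") e - off + 1L else s + off - 1L)
    }
    acc <- acc + w
  }
  NA_integer_
}
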