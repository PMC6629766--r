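## Synthetic locus model: a single-contig reference carrying a six-exon gene
## (minus strand by default), a polymorphic CT-rich low-complexity region, a
## TTG triplet repeat, alternative first exons, variable 3' UTR lengths and
## novel intron-internal start/end exons. Everything downstream is exercised
## against this model and its recorded ground truth.

# Fixed transcript-side geometry (bases). Exon 3 and exon 5 are wholly coding,
# codon-aligned and multiples of 3, so skipping either preserves the frame.
.GENE_GEOMETRY <- list(
  exon1_len = 300L,          # first exon, all 5' UTR
  exon2_utr5 = 100L,
  exon2_cds = 102L,          # multiple of 3: exon 3 starts on a codon boundary
  exon3_cds = 126L,
  exon4_cds = 120L,
  exon5_cds = 33L,
  exon6_cds = 45L,           # includes the stop codon
  utr3_options = c(300L, 1000L, 1800L, 2600L),
  intron_weights = c(4, 3, 6, 60, 4)  # intron 4 dominates, as in the locus
)

#' Build a synthetic diploid gene locus
#'
#' Generates a reference contig of the requested length carrying a six-exon
#' gene on the chosen strand, with canonical (GT-AG / GC-AG) splice motifs
#' planted at every annotated junction, an alternative first exon inside
#' intron 1, four 3' UTR length options (300-2600 bases), a novel
#' intron-internal start exon and a novel intron-internal last exon inside
#' intron 4, a polymorphic CT-rich region with a four-haplotype catalog, and
#' a TTG triplet repeat with 16 units in the reference.
#'
#' @param seed integer seed; the same seed yields a byte-identical locus.
#' @param length contig length in bases (default 114000, minimum 20000).
#' @param strand gene strand, `"-"` (default) or `"+"`.
#' @param protein_length_aa length of the canonical protein (default 141).
#' @return an object of class `LocusModel`: reference sequence, gene model,
#'   repeat region definitions and haplotype catalogs.
#' @export
build_locus <- function(seed = 1L, length = 114000L, strand = "-",
                        protein_length_aa = 141L) {
  length <- as.integer(length)
  if (length < 20000L)
    stop("locus length must be >= 20000 to host 6 exons and repeat regions")
  stopifnot(strand %in% c("+", "-"))
  g <- .GENE_GEOMETRY

  with_seed(seed, {
    ref <- random_dna(length)

    exon_lens <- c(
      g$exon1_len,
      g$exon2_utr5 + g$exon2_cds,
      g$exon3_cds,
      g$exon4_cds,
      g$exon5_cds,
      g$exon6_cds + max(g$utr3_options)
    )
    margin <- max(1000L, as.integer(round(0.06 * length)))
    intron_total <- length - 2L * margin - sum(exon_lens)
    if (intron_total < 10000L)
      stop("locus length too small to host the gene between margins")
    intron_lens <- as.integer(round(g$intron_weights / sum(g$intron_weights) *
                                      intron_total))

    # Genomic placement. Transcript order is exon 1 .. exon 6; on the minus
    # strand that runs from high genomic coordinates down.
    exons <- matrix(NA_integer_, nrow = 6L, ncol = 2L,
                    dimnames = list(paste0("exon", 1:6), c("start", "end")))
    if (strand == "-") {
      cur <- length - margin
      for (i in 1:6) {
        exons[i, ] <- c(cur - exon_lens[i] + 1L, cur)
        cur <- cur - exon_lens[i]
        if (i < 6) cur <- cur - intron_lens[i]
      }
    } else {
      cur <- margin + 1L
      for (i in 1:6) {
        exons[i, ] <- c(cur, cur + exon_lens[i] - 1L)
        cur <- cur + exon_lens[i]
        if (i < 6) cur <- cur + intron_lens[i]
      }
    }

    gene <- list(
      exons = exons,
      strand = strand,
      exon_lens = exon_lens,
      utr3_options = g$utr3_options,
      protein_length_aa = as.integer(protein_length_aa)
    )

    # Coding sequence: ATG + (protein_length_aa - 1) non-stop codons + TAA.
    codons <- .non_stop_codons()
    cds <- c("ATG", sample(codons, protein_length_aa - 1L, replace = TRUE), "TAA")
    cds_seq <- s2c(paste(cds, collapse = ""))
    n_cds <- length(cds_seq)
    stopifnot(n_cds == (protein_length_aa + 1L) * 3L)
    stopifnot(n_cds == g$exon2_cds + g$exon3_cds + g$exon4_cds +
                g$exon5_cds + g$exon6_cds)

    # Transcript coordinates of the CDS within the canonical (longest-UTR)
    # transcript, then planted into the genome strand-aware.
    cds_tx_start <- g$exon1_len + g$exon2_utr5 + 1L
    tx_map <- .tx_to_genome_map(gene)
    cds_gpos <- tx_map[cds_tx_start:(cds_tx_start + n_cds - 1L)]
    if (strand == "-") {
      ref[cds_gpos] <- chartr("ACGT", "TGCA", cds_seq)
    } else {
      ref[cds_gpos] <- cds_seq
    }
    gene$cds_start <- cds_gpos[1L]                 # genomic pos of the ATG 'A'
    gene$cds_stop <- cds_gpos[n_cds]               # genomic pos of last stop base
    gene$cds_tx_start <- cds_tx_start

    # 3' transcript end options (genomic coordinate of the transcript end).
    stop_boundary <- gene$cds_stop
    gene$utr3_ends <- if (strand == "-") stop_boundary - g$utr3_options
                      else stop_boundary + g$utr3_options
    names(gene$utr3_ends) <- paste0("U", g$utr3_options)

    # Plant canonical splice motifs at all annotated introns. Intron 2 uses a
    # GC donor so the GC-AG class is represented.
    donors <- c("GT", "GC", "GT", "GT", "GT")
    for (i in 1:5) {
      intr <- .intron_interval(exons, strand, i)
      ref <- .plant_motifs(ref, intr, strand, donor = donors[i])
    }

    # Alternative first exon inside intron 1 (own donor, shares the exon-2
    # acceptor). Large enough separation from exon 1 that 5' end clustering
    # can never merge the two options.
    i1 <- .intron_interval(exons, strand, 1L)
    alt1_len <- 250L
    if (strand == "-") {
      a_start <- i1[1] + as.integer(0.45 * (i1[2] - i1[1]))
      alt1 <- c(a_start, a_start + alt1_len - 1L)
      ref <- .plant_motifs(ref, c(i1[1], alt1[1] - 1L), strand,
                           donor = "GT", acceptor = NA)
    } else {
      a_end <- i1[2] - as.integer(0.45 * (i1[2] - i1[1]))
      alt1 <- c(a_end - alt1_len + 1L, a_end)
      ref <- .plant_motifs(ref, c(alt1[2] + 1L, i1[2]), strand,
                           donor = "GT", acceptor = NA)
    }
    gene$alt_first_exons <- list(exon1 = unname(exons[1, ]), exon1b = alt1)

    # Intron 4 furniture: CT-rich region, TTG repeat, novel last exon, novel
    # start exon, and a deliberately noncanonical junction boundary for the
    # decoy isoform. Positions are fractions of the intron so any locus
    # length >= 20 kb hosts them without overlap.
    i4 <- .intron_interval(exons, strand, 4L)
    i4_len <- i4[2] - i4[1] + 1L
    at_frac <- function(f) i4[1] + as.integer(round(f * i4_len))

    ct_catalog <- .make_ct_catalog()
    ct_len <- nchar(ct_catalog[[1]])
    ct_region <- c(at_frac(0.62), at_frac(0.62) + ct_len - 1L)
    ref[ct_region[1]:ct_region[2]] <- s2c(ct_catalog[[1]])

    str_unit <- "TTG"
    str_units_ref <- 16L
    str_len <- nchar(str_unit) * str_units_ref
    str_region <- c(at_frac(0.45), at_frac(0.45) + str_len - 1L)
    ref[str_region[1]:str_region[2]] <- s2c(strrep(str_unit, str_units_ref))
    # keep the 30-base flanks free of stray TTG units so unit counting in
    # extracted subsequences reflects the planted allele
    fl <- 30L
    lo <- (str_region[1] - fl):(str_region[1] - 1L)
    hi <- (str_region[2] + 1L):(str_region[2] + fl)
    ref[lo] <- scrub_unit(ref[lo], str_unit)
    ref[hi] <- scrub_unit(ref[hi], str_unit)
    # a stray unit straddling the boundary would inflate the count
    ref[str_region[1] - 1L] <- "C"
    ref[str_region[2] + 1L] <- "A"

    nl_len <- 240L
    novel_last_exon <- c(at_frac(0.30), at_frac(0.30) + nl_len - 1L)
    ns_len <- 300L
    novel_start_exon <- c(at_frac(0.12), at_frac(0.12) + ns_len - 1L)
    if (strand == "-") {
      # novel last exon: acceptor on its low-coordinate intron side is the
      # exon-4 donor side; the new acceptor sits just above the exon
      ref <- .plant_motifs(ref, c(novel_last_exon[2] + 1L, i4[2]), strand,
                           donor = NA, acceptor = "AG")
      # novel start exon: its own donor just below the exon start
      ref <- .plant_motifs(ref, c(i4[1], novel_start_exon[1] - 1L), strand,
                           donor = "GT", acceptor = NA)
      # decoy: exon 4 extended 7 bases into intron 4; boundary motif broken
      decoy_exon4 <- c(exons[4, 1] - 7L, exons[4, 2])
      ref[(exons[4, 1] - 9L):(exons[4, 1] - 8L)] <- c("A", "A")
    } else {
      ref <- .plant_motifs(ref, c(i4[1], novel_last_exon[1] - 1L), strand,
                           donor = NA, acceptor = "AG")
      ref <- .plant_motifs(ref, c(novel_start_exon[2] + 1L, i4[2]), strand,
                           donor = "GT", acceptor = NA)
      decoy_exon4 <- c(exons[4, 1], exons[4, 2] + 7L)
      ref[(exons[4, 2] + 8L):(exons[4, 2] + 9L)] <- c("A", "A")
    }

    locus <- structure(list(
      contig_name = "locus1",
      ref_seq = c2s(ref),
      length = length,
      strand = strand,
      gene = gene,
      ct_rich_region = ct_region,
      ct_catalog = ct_catalog,
      str_region = str_region,
      str_unit = str_unit,
      reference_unit_count = str_units_ref,
      novel_start_exon = novel_start_exon,
      novel_last_exon = novel_last_exon,
      decoy_exon4 = decoy_exon4,
      seed = as.integer(seed)
    ), class = "LocusModel")
    validate_locus(locus)
    locus
  })
}

.non_stop_codons <- function() {
  all3 <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES,
                            stringsAsFactors = FALSE), 1, paste, collapse = "")
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

# Genomic coordinate for each transcript position of the canonical
# (longest-UTR, canonical first exon) transcript, in transcript order.
.tx_to_genome_map <- function(gene) {
  ex <- gene$exons
  if (gene$strand == "-") {
    unlist(lapply(1:6, function(i) ex[i, 2]:ex[i, 1]))
  } else {
    unlist(lapply(1:6, function(i) ex[i, 1]:ex[i, 2]))
  }
}

# Genomic interval of intron i (between transcript exons i and i+1).
.intron_interval <- function(exons, strand, i) {
  if (strand == "-") c(exons[i + 1L, 2] + 1L, exons[i, 1] - 1L)
  else c(exons[i, 2] + 1L, exons[i + 1L, 1] - 1L)
}

# Write donor/acceptor dinucleotides of an intron into the reference,
# strand-aware. For a minus-strand gene the transcribed-strand donor GT is
# the genomic complement "AC" at the intron's high end, and the acceptor AG
# is "CT" at its low end.
.plant_motifs <- function(ref, intron, strand, donor = "GT", acceptor = "AG") {
  if (strand == "-") {
    if (!is.na(donor))
      ref[(intron[2] - 1L):intron[2]] <- rev(chartr("ACGT", "TGCA", s2c(donor)))
    if (!is.na(acceptor))
      ref[intron[1]:(intron[1] + 1L)] <- rev(chartr("ACGT", "TGCA", s2c(acceptor)))
  } else {
    if (!is.na(donor))
      ref[intron[1]:(intron[1] + 1L)] <- s2c(donor)
    if (!is.na(acceptor))
      ref[(intron[2] - 1L):intron[2]] <- s2c(acceptor)
  }
  ref
}

# Four CT-rich haplotypes: entries of similar length differ by many
# substitutions, entries of different length by indel blocks, so size +
# similarity clustering separates every pair.
.make_ct_catalog <- function() {
  base_len <- 229L
  h1 <- sample(c("C", "T"), base_len, replace = TRUE, prob = c(0.55, 0.45))
  h2 <- append(h1, sample(c("C", "T"), 12L, replace = TRUE), after = 100L)
  h3 <- h1[-(60:74)]
  h4 <- h1
  idx <- sample(seq_len(base_len), 20L)
  h4[idx] <- ifelse(h1[idx] == "C", "T", "C")
  list(H1 = c2s(h1), H2 = c2s(h2), H3 = c2s(h3), H4 = c2s(h4))
}

#' Validate a LocusModel against its invariants
#'
#' Checks exon ordering and containment, canonical splice motifs on the
#' transcribed strand at every annotated junction, the reference repeat
#' content of the STR region, codon-aligned exon 3 / exon 5 (so skipping
#' preserves the reading frame), and that the canonical transcript translates
#' to the configured protein length.
#'
#' @param locus a `LocusModel`.
#' @return invisibly `TRUE`; stops on violation.
#' @export
validate_locus <- function(locus) {
  ex <- locus$gene$exons
  stopifnot(all(ex[, 1] <= ex[, 2]), all(ex >= 1), all(ex <= locus$length))
  ord <- order(ex[, 1])
  stopifnot(all(diff(ex[ord, 1]) > 0),
            all(ex[ord, 2][-6] < ex[ord, 1][-1]))  # non-overlapping

  # splice motifs at annotated introns + novel elements
  for (i in 1:5) {
    intr <- .intron_interval(ex, locus$strand, i)
    m <- junction_motif(locus$ref_seq, intr[1], intr[2], locus$strand)
    stopifnot(m %in% c("GT-AG", "GC-AG"))
  }

  stopifnot(substr(locus$ref_seq, locus$str_region[1], locus$str_region[2]) ==
              strrep(locus$str_unit, locus$reference_unit_count))

  g <- .GENE_GEOMETRY
  stopifnot(g$exon3_cds %% 3L == 0L, g$exon5_cds %% 3L == 0L)

  tx <- transcript_sequence(canonical_chain(locus), locus)
  aa <- translate_from(tx, locus$gene$cds_tx_start)
  stopifnot(nchar(aa) == locus$gene$protein_length_aa)
  invisible(TRUE)
}

# Donor-acceptor motif of an intron on the transcribed strand.
junction_motif <- function(ref_seq, intron_start, intron_end, strand) {
  if (strand == "-") {
    donor <- revcomp(substr(ref_seq, intron_end - 1L, intron_end))
    acceptor <- revcomp(substr(ref_seq, intron_start, intron_start + 1L))
  } else {
    donor <- substr(ref_seq, intron_start, intron_start + 1L)
    acceptor <- substr(ref_seq, intron_end - 1L, intron_end)
  }
  paste0(donor, "-", acceptor)
}

## ---- isoform repertoire ----------------------------------------------------

# Exon chain (genomic-ascending matrix) for a transcript built from the
# canonical model with a chosen first exon and 3' UTR length.
.chain <- function(locus, first_exon = "exon1", utr = 2600L,
                   skip = integer(0)) {
  g <- locus$gene
  ex <- g$exons
  keep <- setdiff(2:5, skip)
  e6 <- if (g$strand == "-") c(g$utr3_ends[paste0("U", utr)], ex[6, 2])
        else c(ex[6, 1], g$utr3_ends[paste0("U", utr)])
  fe <- g$alt_first_exons[[first_exon]]
  rows <- rbind(e6, ex[keep, , drop = FALSE], fe)
  rows <- rows[order(rows[, 1]), , drop = FALSE]
  .as_chain(rows)
}

# exon-chain matrices carry start/end column names and no row names
.as_chain <- function(m) {
  m <- unname(m)
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

canonical_chain <- function(locus, utr = 2600L) .chain(locus, utr = utr)

#' Planted isoform repertoire for the synthetic locus
#'
#' Thirteen valid isoforms — seven with all six exons (two first-exon options
#' crossed with 3' UTR lengths, one dominant), two exon-3-skipping, two
#' exon-5-skipping, one with a novel intron-internal start exon, and one with
#' a novel intron-internal last exon — plus, optionally, two decoys: one with
#' a noncanonical junction and one planted at 19 total full-length reads so
#' the support filter removes it.
#'
#' @param locus a `LocusModel`.
#' @param include_decoys plant the two decoy isoforms (default `TRUE`).
#' @return a list of isoform definitions with truth class labels and the
#'   default relative abundance mix.
#' @export
build_repertoire <- function(locus, include_decoys = TRUE) {
  ex <- locus$gene$exons
  minus <- locus$strand == "-"
  iso <- list()
  add <- function(id, chain, class, mix, fixed_total = NA_integer_) {
    iso[[id]] <<- list(id = id, chain = chain, class_truth = class,
                       mix = mix, fixed_total = fixed_total)
  }
  all_mix_other <- 0.41 / 6
  add("iso_E1a_U1000", .chain(locus, "exon1", 1000L), "AllExons", 0.55)
  add("iso_E1a_U300",  .chain(locus, "exon1", 300L),  "AllExons", all_mix_other)
  add("iso_E1a_U1800", .chain(locus, "exon1", 1800L), "AllExons", all_mix_other)
  add("iso_E1a_U2600", .chain(locus, "exon1", 2600L), "AllExons", all_mix_other)
  add("iso_E1b_U300",  .chain(locus, "exon1b", 300L), "AllExons", all_mix_other)
  add("iso_E1b_U1000", .chain(locus, "exon1b", 1000L), "AllExons", all_mix_other)
  add("iso_E1b_U2600", .chain(locus, "exon1b", 2600L), "AllExons", all_mix_other)
  add("iso_skip3_U300",  .chain(locus, "exon1", 300L, skip = 3L), "Skip3", 0.0025)
  add("iso_skip3_U2600", .chain(locus, "exon1", 2600L, skip = 3L), "Skip3", 0.0025)
  add("iso_skip5_U1000", .chain(locus, "exon1", 1000L, skip = 5L), "Skip5", 0.01)
  add("iso_skip5_E1b_U300", .chain(locus, "exon1b", 300L, skip = 5L), "Skip5", 0.01)

  # novel start inside intron 4, splicing to exon 5
  e6 <- if (minus) c(locus$gene$utr3_ends[["U1000"]], ex[6, 2])
        else c(ex[6, 1], locus$gene$utr3_ends[["U1000"]])
  ns_rows <- rbind(e6, ex[5, ], locus$novel_start_exon)
  ns_rows <- ns_rows[order(ns_rows[, 1]), , drop = FALSE]
  add("iso_novel_start", .as_chain(ns_rows), "Alt5", 0.01)

  # novel last exon inside intron 4 (transcript ends before exon 5/6)
  nl_rows <- rbind(locus$novel_last_exon, ex[2:4, ],
                   locus$gene$alt_first_exons$exon1)
  nl_rows <- nl_rows[order(nl_rows[, 1]), , drop = FALSE]
  add("iso_novel_end", .as_chain(nl_rows), "Alt3", 0.005)

  if (include_decoys) {
    dec <- .chain(locus, "exon1", 300L)
    i4row <- which(dec[, 1] == ex[4, 1] & dec[, 2] == ex[4, 2])
    dec[i4row, ] <- locus$decoy_exon4
    add("decoy_noncanonical", dec, "decoy", 0, fixed_total = 120L)
    add("decoy_lowfl", .chain(locus, "exon1b", 1800L), "decoy", 0,
        fixed_total = 19L)
  }
  iso
}

# Named relative-abundance vector over non-fixed repertoire members.
repertoire_mix <- function(repertoire) {
  mix <- vapply(repertoire, function(x) x$mix, numeric(1))
  mix <- mix[mix > 0]
  mix / sum(mix)
}

## ---- transcript sequence & translation ------------------------------------

#' Spliced transcript sequence of an exon chain
#'
#' @param chain matrix of genomic exon intervals (ascending).
#' @param locus a `LocusModel` (supplies reference and strand).
#' @return transcript sequence, 5' to 3' on the transcribed strand.
#' @export
transcript_sequence <- function(chain, locus) {
  pieces <- vapply(seq_len(nrow(chain)), function(i)
    substr(locus$ref_seq, chain[i, 1], chain[i, 2]), character(1))
  if (locus$strand == "-") {
    c2s(vapply(rev(pieces), function(p) revcomp(p), character(1)))
  } else {
    c2s(pieces)
  }
}

# Translate a transcript from a given transcript coordinate up to the first
# stop codon; returns the peptide (possibly empty). Used by locus validation;
# ORF analysis proper lives in predict_orf().
translate_from <- function(tx_seq, tx_start) {
  if (tx_start < 1 || tx_start + 2L > nchar(tx_seq)) return("")
  orf <- substr(tx_seq, tx_start, nchar(tx_seq))
  orf <- substr(orf, 1, 3L * (nchar(orf) %/% 3L))
  if (nchar(orf) < 3L) return("")
  aa <- suppressWarnings(
    as.character(Biostrings::translate(Biostrings::DNAString(orf))))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) substr(aa, 1, stop_at - 1L) else aa
}
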