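## Plain-text interchange formats. Alignments travel as SAM, the reference
## as FASTA (+ .fai), gene/isoform models as GFF3 and variant calls as
## VCF 4.2, so every stage can be run, inspected and replaced independently
## with standard tooling.

#' Write alignments as a sorted SAM file
#'
#' Sample identity is carried as a read group (`RG`); simulator ground truth
#' travels in optional tags (`XH` haplotype of origin, `XF` PCR family,
#' `XI` source isoform) so downstream stages can be validated from the file
#' alone. Duplicate reads get the 0x400 FLAG bit.
#'
#' @param reads alignment `data.table` (as produced by the simulators).
#' @param path output path.
#' @param locus a `LocusModel` (for the `@SQ` header line).
#' @return the path, invisibly.
#' @export
write_sam <- function(reads, path, locus) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", locus$contig_name, locus$length),
    sprintf("@RG\tID:%s\tSM:%s", unique(reads$sample_id), unique(reads$sample_id)),
    "@PG\tID:locuskit\tPN:locuskit"
  ), con)
  if (nrow(reads) == 0L) return(invisible(path))
  r <- data.table::copy(reads)
  data.table::setorder(r, start, read_id)
  flag <- ifelse(r$strand == "-", 16L, 0L)
  if ("is_duplicate" %in% names(r))
    flag <- flag + ifelse(!is.na(r$is_duplicate) & r$is_duplicate, 1024L, 0L)
  tags <- paste0("RG:Z:", r$sample_id)
  if ("hap" %in% names(r)) tags <- paste0(tags, "\tXH:i:", r$hap)
  if ("family_id" %in% names(r))
    tags <- ifelse(is.na(r$family_id), tags,
                   paste0(tags, "\tXF:Z:", r$family_id))
  if ("true_isoform" %in% names(r))
    tags <- ifelse(is.na(r$true_isoform), tags,
                   paste0(tags, "\tXI:Z:", r$true_isoform))
  lines <- paste(r$read_id, flag, r$contig, r$start, 60L, r$cigar,
                 "*", 0L, 0L, r$seq, r$qual, tags, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a SAM file back into an alignment table
#'
#' Restores the columns the simulators emit, including ground-truth tags
#' when present.
#'
#' @param path SAM file path.
#' @return alignment `data.table`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) return(data.table::data.table())
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  nf <- length(f)
  dt <- data.table::data.table(
    read_id = f[[1]], flag = as.integer(f[[2]]), contig = f[[3]],
    start = as.integer(f[[4]]), cigar = f[[6]], seq = f[[10]], qual = f[[11]])
  dt[, strand := ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")]
  dt[, is_duplicate := bitwAnd(flag, 1024L) > 0L]
  dt[, flag := NULL]
  # optional tags live in remaining fields
  tagv <- function(prefix, cast = identity) {
    out <- rep(NA_character_, nrow(dt))
    for (j in 12:nf) {
      if (j > length(f)) break
      col <- f[[j]]
      hit <- !is.na(col) & startsWith(col, prefix)
      out[hit] <- substring(col[hit], nchar(prefix) + 1L)
    }
    cast(out)
  }
  dt[, sample_id := tagv("RG:Z:")]
  dt[, hap := tagv("XH:i:", as.integer)]
  dt[, family_id := tagv("XF:Z:")]
  dt[, true_isoform := tagv("XI:Z:")]
  dt[, end := mapply(reference_end, cigar, start)]
  dt[, mean_qv := vapply(qual, mean_read_qv, numeric(1))]
  dt[, read_type := ifelse(grepl("N", cigar, fixed = TRUE), "flnc", "gdna")]
  data.table::setcolorder(dt, c("read_id", "sample_id", "contig", "start",
                                "end", "strand", "cigar", "seq", "qual"))
  dt[]
}

#' Write the locus reference as FASTA with a .fai index
#' @param locus a `LocusModel`.
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
write_locus_fasta <- function(locus, path) {
  dna <- Biostrings::DNAStringSet(setNames(locus$ref_seq, locus$contig_name))
  Biostrings::writeXStringSet(dna, path, width = 80L)
  offset <- nchar(locus$contig_name) + 2L  # ">name\n"
  fai <- sprintf("%s\t%d\t%d\t%d\t%d", locus$contig_name, locus$length,
                 offset, 80L, 81L)
  writeLines(fai, paste0(path, ".fai"))
  invisible(path)
}

#' Write the annotated gene model as GFF3
#'
#' Emits the gene, the canonical transcript with its six exons, and the
#' alternative first exons, using 1-based inclusive coordinates.
#'
#' @param locus a `LocusModel`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gene_gff3 <- function(locus, path) {
  ex <- locus$gene$exons
  st <- locus$strand
  gene_lo <- min(ex); gene_hi <- max(ex)
  row <- function(type, s, e, id, parent = NULL) {
    attrs <- paste0("ID=", id)
    if (!is.null(parent)) attrs <- paste0(attrs, ";Parent=", parent)
    sprintf("%s\tlocuskit\t%s\t%d\t%d\t.\t%s\t.\t%s",
            locus$contig_name, type, s, e, st, attrs)
  }
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", locus$contig_name, locus$length),
             row("gene", gene_lo, gene_hi, "gene1"),
             row("mRNA", gene_lo, gene_hi, "tx_canonical", "gene1"))
  for (i in 1:6)
    lines <- c(lines, row("exon", ex[i, 1], ex[i, 2],
                          paste0("exon", i), "tx_canonical"))
  alt <- locus$gene$alt_first_exons$exon1b
  lines <- c(lines, row("exon", alt[1], alt[2], "exon1b", "gene1"))
  writeLines(lines, path)
  invisible(path)
}

#' Write collapsed isoforms as GFF3
#' @param isoforms list of isoforms (see [collapse_flnc()]).
#' @param contig contig name.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_isoform_gff3 <- function(isoforms, contig, path) {
  lines <- "##gff-version 3"
  for (iso in isoforms) {
    ch <- iso$chain
    attrs <- paste0("ID=", iso$id)
    if (!is.null(iso$splice_class))
      attrs <- paste0(attrs, ";splice_class=", iso$splice_class)
    lines <- c(lines, sprintf("%s\tlocuskit\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              contig, min(ch), max(ch), iso$strand, attrs))
    for (i in seq_len(nrow(ch)))
      lines <- c(lines, sprintf("%s\tlocuskit\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                                contig, ch[i, 1], ch[i, 2], iso$strand, iso$id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write genotyped (optionally phased) calls as a multi-sample VCF 4.2
#'
#' Phased genotypes use `|` with a `PS` tag equal to the phase-block start.
#'
#' @param calls long-format call `data.table` (one row per variant x sample)
#'   with columns contig, pos, ref_allele, alt_allele, sample_id, genotype,
#'   depth, ref_depth, alt_depth, qual_flag and optionally phased_gt, ps.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(calls, path) {
  samples <- sort(unique(calls$sample_id))
  has_ps <- "ps" %in% names(calls)
  fmt <- if (has_ps) "GT:DP:AD:PS" else "GT:DP:AD"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=locuskit",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    if (has_ps)
      "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    "##FILTER=<ID=low_depth,Description=\"Depth below threshold\">",
    "##FILTER=<ID=phase_inconsistent,Description=\"Fails phase consistency\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  keys <- unique(calls[, .(contig, pos, ref_allele, alt_allele)])
  data.table::setorder(keys, pos)
  lines <- character(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    k <- keys[i]
    sub <- calls[contig == k$contig & pos == k$pos &
                   alt_allele == k$alt_allele]
    flags <- setdiff(unique(sub$qual_flag), "pass")
    filt <- if (length(flags) == 0L) "PASS" else paste(flags, collapse = ";")
    cells <- vapply(samples, function(s) {
      row <- sub[sample_id == s]
      if (nrow(row) == 0L)
        return(if (has_ps) "./.:.:.:." else "./.:.:.")
      gt <- if (has_ps && !is.na(row$phased_gt[1])) row$phased_gt[1]
            else row$genotype[1]
      ad <- paste(row$ref_depth[1], row$alt_depth[1], sep = ",")
      if (has_ps) {
        ps <- if (!is.na(row$ps[1])) row$ps[1] else "."
        paste(gt, row$depth[1], ad, ps, sep = ":")
      } else paste(gt, row$depth[1], ad, sep = ":")
    }, character(1))
    lines[i] <- paste(c(k$contig, k$pos, ".", k$ref_allele, k$alt_allele,
                        ".", filt, ".", fmt, cells), collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
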