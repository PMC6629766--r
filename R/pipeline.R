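## End-to-end orchestration: simulate -> dedup -> variants -> phase ->
## str-genotype -> isoforms -> cdna-snps -> report. Stage outputs are plain
## standard formats (SAM/VCF/GFF3/TSV) under one output directory, so any
## stage can be re-run, inspected or replaced independently; re-running with
## the same configuration and seed is byte-identical.

#' Pipeline configuration
#'
#' All module parameters in one validated list. Unknown keys are rejected.
#'
#' @param seed master seed; every stage derives its randomness from it.
#' @param out_dir output directory.
#' @param n_samples number of simulated samples (default 12).
#' @param locus_length reference length (default 114000).
#' @param strand gene strand (default "-").
#' @param sim named list of overrides for [read_sim_config()].
#' @param min_depth,min_base_qv gDNA genotyper thresholds.
#' @param min_pair_reads,max_minority phase-consistency thresholds.
#' @param str_flank,str_size_tol,str_dist_frac,str_min_support repeat
#'   haplotyper parameters.
#' @param tol5,tol3 isoform end-clustering tolerances.
#' @param min_fl minimum isoform full-length support (default 20).
#' @param min_junction_support short-read junction confirmation threshold
#'   (default 10).
#' @param snp named list of overrides for [snp_caller_params()].
#' @return object of class `RunConfig`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("locuskit_run_"),
                       n_samples = 12L, locus_length = 114000L,
                       strand = "-", sim = list(), min_depth = 10L,
                       min_base_qv = 13L, min_pair_reads = 8L,
                       max_minority = 0.2, str_flank = 20L,
                       str_size_tol = 2L, str_dist_frac = 0.05,
                       str_min_support = 3L, tol5 = 50L, tol3 = 100L,
                       min_fl = 20L, min_junction_support = 10L,
                       snp = list()) {
  known_sim <- names(formals(read_sim_config))
  if (length(setdiff(names(sim), known_sim)))
    stop("unknown sim config key(s): ",
         paste(setdiff(names(sim), known_sim), collapse = ", "))
  known_snp <- names(formals(snp_caller_params))
  if (length(setdiff(names(snp), known_snp)))
    stop("unknown snp config key(s): ",
         paste(setdiff(names(snp), known_snp), collapse = ", "))
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_samples = as.integer(n_samples),
                 locus_length = as.integer(locus_length), strand = strand,
                 sim = sim, min_depth = min_depth, min_base_qv = min_base_qv,
                 min_pair_reads = min_pair_reads, max_minority = max_minority,
                 str_flank = str_flank, str_size_tol = str_size_tol,
                 str_dist_frac = str_dist_frac,
                 str_min_support = str_min_support, tol5 = tol5, tol3 = tol3,
                 min_fl = min_fl,
                 min_junction_support = min_junction_support, snp = snp),
            class = "RunConfig")
}

.stage_log <- function(stage, ...) {
  kv <- list(...)
  echo <- paste(names(kv), unlist(kv), sep = "=", collapse = " ")
  message(sprintf("[locuskit] stage=%s %s", stage, echo))
}

.PIPELINE_STAGES <- c("simulate", "dedup", "variants", "phase", "str",
                      "isoforms", "cdna_snps", "report")

#' Run the pipeline end to end (or selected stages)
#'
#' Stages run in dependency order. The locus model and sample truths are
#' reconstructed deterministically from the seed; alignment inputs of later
#' stages are read back from the SAM files written by earlier stages, so
#' stages can be run in separate calls against the same `out_dir`.
#'
#' @param config a `RunConfig`.
#' @param stages subset of `c("simulate", "dedup", "variants", "phase",
#'   "str", "isoforms", "cdna_snps", "report")`; default all.
#' @return invisibly, a list of in-memory stage artifacts.
#' @export
run_pipeline <- function(config = run_config(), stages = .PIPELINE_STAGES) {
  stopifnot(inherits(config, "RunConfig"))
  stages <- match.arg(stages, .PIPELINE_STAGES, several.ok = TRUE)
  stages <- .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  need <- function(f, stage) {
    if (!file.exists(p(f)))
      stop("missing ", f, "; run stage '", stage, "' first")
    p(f)
  }

  locus <- build_locus(seed = config$seed, length = config$locus_length,
                       strand = config$strand)
  repertoire <- build_repertoire(locus)
  truths <- make_sample_truths(locus, n_samples = config$n_samples,
                               seed = config$seed, repertoire = repertoire)
  cfg <- do.call(read_sim_config, c(list(seed = config$seed), config$sim))
  art <- list(locus = locus, truths = truths, repertoire = repertoire,
              cfg = cfg)

  if ("simulate" %in% stages) {
    .stage_log("simulate", seed = config$seed, n_samples = config$n_samples,
               locus_length = config$locus_length,
               mean_fragment = cfg$gdna_mean_fragment,
               duplicate_rate = cfg$duplicate_rate,
               flnc_per_sample = cfg$flnc_reads_per_sample)
    g <- simulate_gdna(locus, truths, cfg)
    f <- simulate_flnc(locus, truths, cfg, repertoire)
    write_locus_fasta(locus, p("reference.fasta"))
    write_gene_gff3(locus, p("gene.gff3"))
    write_sam(g$reads, p("gdna.sam"), locus)
    write_sam(f$reads, p("flnc.sam"), locus)
    data.table::fwrite(g$dup_truth, p("truth_duplicates.tsv"), sep = "\t")
    data.table::fwrite(f$iso_truth, p("truth_isoforms.tsv"), sep = "\t")
    data.table::fwrite(variant_truth_table(truths), p("truth_variants.tsv"),
                       sep = "\t")
    data.table::fwrite(make_junction_support(locus, repertoire),
                       p("junction_support.tsv"), sep = "\t")
    art$gdna <- g
    art$flnc <- f
  }

  if ("dedup" %in% stages) {
    reads <- if (!is.null(art$gdna)) art$gdna$reads
             else read_sam(need("gdna.sam", "simulate"))
    .stage_log("dedup", n_reads = nrow(reads))
    deduped <- mark_duplicates(reads)
    covs <- coverage_summary(deduped, c(1L, locus$length))
    write_sam(deduped, p("gdna.dedup.sam"), locus)
    data.table::fwrite(covs, p("coverage_summary.tsv"), sep = "\t")
    .stage_log("dedup", n_duplicates = sum(deduped$is_duplicate))
    art$deduped <- deduped
    art$coverage <- covs
  }

  if (any(c("variants", "phase") %in% stages) && is.null(art$deduped))
    art$deduped <- read_sam(need("gdna.dedup.sam", "dedup"))

  if ("variants" %in% stages) {
    .stage_log("variants", min_depth = config$min_depth,
               min_base_qv = config$min_base_qv)
    calls <- pileup_genotype(art$deduped, locus,
                             min_depth = config$min_depth,
                             min_base_qv = config$min_base_qv)
    calls <- phase_consistency_filter(calls, art$deduped,
                                      min_pair_reads = config$min_pair_reads,
                                      max_minority = config$max_minority,
                                      min_base_qv = config$min_base_qv)
    write_vcf(calls, p("variants.vcf"))
    data.table::fwrite(calls, p("variant_calls.tsv"), sep = "\t")
    .stage_log("variants", n_sites = length(unique(calls$pos)))
    art$calls <- calls
  }

  if ("phase" %in% stages) {
    if (is.null(art$calls))
      art$calls <- data.table::fread(need("variant_calls.tsv", "variants"))
    .stage_log("phase", min_base_qv = config$min_base_qv)
    blocks <- read_backed_phase(art$calls, art$deduped,
                                min_base_qv = config$min_base_qv)
    summ <- phasing_summary(blocks, c(1L, locus$length),
                            samples = vapply(truths, `[[`, "", "sample_id"))
    phased <- .apply_phasing(art$calls, blocks)
    write_vcf(phased, p("variants.phased.vcf"))
    data.table::fwrite(summ, p("phasing_summary.tsv"), sep = "\t")
    .stage_log("phase", n_blocks = length(blocks),
               longest = if (length(blocks)) max(summ$longest_block) else 0)
    art$blocks <- blocks
    art$phasing_summary <- summ
  }

  if ("str" %in% stages) {
    if (is.null(art$deduped))
      art$deduped <- read_sam(need("gdna.dedup.sam", "dedup"))
    .stage_log("str", flank = config$str_flank, size_tol = config$str_size_tol,
               min_support = config$str_min_support)
    str_gt <- genotype_repeat_region(
      art$deduped, locus$str_region, "TTG_repeat", unit = locus$str_unit,
      flank = config$str_flank, size_tol = config$str_size_tol,
      dist_frac = config$str_dist_frac,
      min_support = config$str_min_support)
    ct_gt <- genotype_repeat_region(
      art$deduped, locus$ct_rich_region, "CT_rich", catalog = locus$ct_catalog,
      flank = config$str_flank, size_tol = config$str_size_tol,
      dist_frac = config$str_dist_frac,
      min_support = config$str_min_support)
    data.table::fwrite(str_gt, p("str_genotypes.tsv"), sep = "\t")
    data.table::fwrite(ct_gt, p("ct_genotypes.tsv"), sep = "\t")
    tab1 <- str_gt[, .(Sample = sample_id,
                       Genotype = paste0(allele1, "/", allele2))]
    data.table::fwrite(tab1, p("table1_str_genotypes.tsv"), sep = "\t")
    art$str_gt <- str_gt
    art$ct_gt <- ct_gt
  }

  if (any(c("isoforms", "cdna_snps") %in% stages) && is.null(art$flnc)) {
    art$flnc <- list(reads = read_sam(need("flnc.sam", "simulate")))
  }

  if ("isoforms" %in% stages) {
    .stage_log("isoforms", tol5 = config$tol5, tol3 = config$tol3,
               min_fl = config$min_fl,
               min_junction_support = config$min_junction_support)
    coll <- collapse_flnc(art$flnc$reads, strand = locus$strand,
                          tol5 = config$tol5, tol3 = config$tol3)
    filt <- filter_isoforms(coll$isoforms, locus, min_fl = config$min_fl)
    retained <- filt$retained
    for (id in names(retained)) {
      retained[[id]]$splice_class <-
        classify_splice_pattern(retained[[id]], locus)
      orf <- predict_orf(retained[[id]], locus)
      retained[[id]]$orf_status <- orf$orf_status
      retained[[id]]$protein_length <- orf$protein_length
      retained[[id]]$protein <- orf$protein
    }
    support <- data.table::fread(need("junction_support.tsv", "simulate"))
    jval <- validate_junctions(retained, locus, support,
                               min_support = config$min_junction_support)
    ab <- abundance(retained)
    ab_class <- abundance(retained, by_class = TRUE)
    write_isoform_gff3(retained, locus$contig_name, p("isoforms.gff3"))
    data.table::fwrite(filt$dropped, p("isoforms_dropped.tsv"), sep = "\t")
    data.table::fwrite(ab, p("isoform_abundance.tsv"), sep = "\t")
    tab2 <- data.table::copy(ab_class)
    data.table::setnames(tab2, "id", "GROUP")
    data.table::fwrite(tab2, p("table2_abundance_by_class.tsv"), sep = "\t")
    data.table::fwrite(jval$junctions, p("junction_report.tsv"), sep = "\t")
    prot <- vapply(retained, `[[`, character(1), "protein")
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(prot[nchar(prot) > 0]), p("proteins.fasta"))
    data.table::fwrite(coll$assignment, p("read_isoform_assignment.tsv"),
                       sep = "\t")
    .stage_log("isoforms", n_collapsed = length(coll$isoforms),
               n_retained = length(retained))
    art$collapse <- coll
    art$retained <- retained
    art$dropped <- filt$dropped
    art$abundance <- ab
    art$abundance_by_class <- ab_class
    art$junction_validation <- jval
  }

  if ("cdna_snps" %in% stages) {
    params <- do.call(snp_caller_params, config$snp)
    if (is.null(art$collapse)) {
      assignment <- data.table::fread(need("read_isoform_assignment.tsv",
                                           "isoforms"))
      retained_ids <- setdiff(unique(assignment$isoform_id),
                              data.table::fread(
                                need("isoforms_dropped.tsv", "isoforms"))$id)
    } else {
      assignment <- art$collapse$assignment
      retained_ids <- names(art$retained)
    }
    .stage_log("cdna_snps", min_base_qv = params$min_base_qv,
               min_cov = params$min_cov, alpha = params$alpha,
               homopolymer_len = params$homopolymer_len,
               min_gt_reads = params$min_gt_reads)
    pile <- flnc_pileup(art$flnc$reads, locus$length, params,
                        assignment = assignment, retained_ids = retained_ids)
    snps <- call_snps(pile, locus, params)
    gts <- genotype_cdna_snps(snps, pile, params)
    links <- if (!is.null(art$retained))
      link_snps_to_isoforms(snps, art$retained) else NULL
    data.table::fwrite(snps, p("cdna_snps.tsv"), sep = "\t")
    data.table::fwrite(gts, p("cdna_snp_genotypes.tsv"), sep = "\t")
    tab3 <- .table3_shape(snps, gts)
    data.table::fwrite(tab3, p("table3_cdna_snps.tsv"), sep = "\t")
    .stage_log("cdna_snps", n_tested = if (nrow(snps)) snps$m[1] else 0,
               n_called = sum(snps$called))
    art$cdna_snps <- snps
    art$cdna_genotypes <- gts
    art$snp_links <- links
  }

  if ("report" %in% stages) {
    counts <- list(
      seed = config$seed,
      n_samples = config$n_samples,
      n_gdna_reads = if (!is.null(art$deduped)) nrow(art$deduped) else NA,
      n_duplicates = if (!is.null(art$deduped))
        sum(art$deduped$is_duplicate) else NA,
      n_variant_sites = if (!is.null(art$calls))
        length(unique(art$calls$pos)) else NA,
      n_phase_blocks = if (!is.null(art$blocks)) length(art$blocks) else NA,
      n_isoforms_retained = if (!is.null(art$retained))
        length(art$retained) else NA,
      n_cdna_snps = if (!is.null(art$cdna_snps))
        sum(art$cdna_snps$called) else NA)
    jsonlite::write_json(counts, p("run_summary.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    art$summary <- counts
  }

  invisible(art)
}

# attach phased genotypes (0|1 / 1|0 with a PS phase-set tag) to het calls
.apply_phasing <- function(calls, blocks) {
  out <- data.table::copy(calls)
  out[, phased_gt := NA_character_]
  out[, ps := NA_integer_]
  for (b in blocks) {
    out[sample_id == b$sample_id & type == "snp" & pos %in% b$sites$pos,
        `:=`(phased_gt = b$sites$phased_gt[match(pos, b$sites$pos)],
             ps = b$start)]
  }
  out
}

# Table-3-shaped summary: one row per called SNP, samples listed per
# genotype class.
.table3_shape <- function(snps, gts) {
  called <- snps[called == TRUE]
  if (nrow(called) == 0L)
    return(data.table::data.table(Coord = integer(0), Ref = character(0),
                                  Alt = character(0), Homo_Ref = character(0),
                                  Homo_Alt = character(0), Het = character(0),
                                  Inconclusive = character(0)))
  rows <- lapply(seq_len(nrow(called)), function(i) {
    g <- gts[pos == called$pos[i]]
    lst <- function(cls) paste(sort(g[genotype == cls, sample_id]),
                               collapse = ",")
    data.table::data.table(
      Coord = called$pos[i], Ref = called$ref_base[i],
      Alt = called$alt_base[i], Homo_Ref = lst("homo_ref"),
      Homo_Alt = lst("homo_alt"), Het = lst("het"),
      Inconclusive = lst("inconclusive"))
  })
  data.table::rbindlist(rows)
}
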