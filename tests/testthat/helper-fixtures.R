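# Shared fixtures, cached for the test session: expensive simulations are
# built once and reused across files.

lk_cache <- new.env(parent = emptyenv())
lk_fixture <- function(name, expr) {
  if (!exists(name, envir = lk_cache)) assign(name, expr, envir = lk_cache)
  get(name, envir = lk_cache)
}

small_locus <- function() lk_fixture("locus30", build_locus(seed = 7, length = 30000))
small_truths <- function()
  lk_fixture("truths30", make_sample_truths(small_locus(), 2, seed = 3))
small_gdna <- function() lk_fixture("gdna30", simulate_gdna(
  small_locus(), small_truths(),
  read_sim_config(seed = 11, gdna_coverage_range = NULL,
                  gdna_mean_coverage = 40)))
small_dedup <- function()
  lk_fixture("dedup30", mark_duplicates(small_gdna()$reads))
small_calls <- function()
  lk_fixture("calls30", pileup_genotype(small_dedup(), small_locus()))

# full-scale study fixtures (12 samples over the default 114 kb locus)
study_locus <- function() lk_fixture("locus_full", build_locus(seed = 1))
study_truths <- function()
  lk_fixture("truths_full", make_sample_truths(study_locus(), 12, seed = 1))
study_gdna <- function() lk_fixture("gdna_full", simulate_gdna(
  study_locus(), study_truths(), read_sim_config(seed = 1)))
study_dedup <- function()
  lk_fixture("dedup_full", mark_duplicates(study_gdna()$reads))
study_flnc <- function() lk_fixture("flnc_full", simulate_flnc(
  study_locus(), study_truths(), read_sim_config(seed = 1)))
study_isoforms <- function() lk_fixture("iso_full", {
  coll <- collapse_flnc(study_flnc()$reads, strand = study_locus()$strand)
  filt <- filter_isoforms(coll$isoforms, study_locus())
  retained <- filt$retained
  for (id in names(retained))
    retained[[id]]$splice_class <-
      classify_splice_pattern(retained[[id]], study_locus())
  list(coll = coll, retained = retained, dropped = filt$dropped)
})

# One synthetic aligned read, for constructed pileups.
synth_read <- function(locus, start, bases, sample_id = "S1", qv = 40L,
                       read_id = paste0("r", start), strand = "+",
                       cigar = NULL) {
  n <- nchar(bases)
  if (is.null(cigar)) cigar <- paste0(n, "M")
  qual <- locuskit:::qv_to_char(rep(qv, n))
  data.table::data.table(
    read_id = read_id, sample_id = sample_id, contig = locus$contig_name,
    start = as.integer(start),
    end = locuskit:::reference_end(cigar, as.integer(start)),
    strand = strand, cigar = cigar, seq = bases, qual = qual,
    mean_qv = mean(rep(qv, n)), is_duplicate = NA)
}

# A minimal locus-like object around an arbitrary reference string.
mini_locus <- function(seq, strand = "+") {
  structure(list(contig_name = "mini", ref_seq = seq, length = nchar(seq),
                 strand = strand,
                 str_region = c(1L, 1L), ct_rich_region = c(1L, 1L)),
            class = "LocusModel")
}

## ---- independent oracles ---------------------------------------------------

# Brute-force hypergeometric tail P(X >= a) for the 2x2 table [[a,b],[c,d]].
brute_hyper_p <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c
  n1 <- a + b
  ks <- a:min(K, n1)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n1 - ks) - lchoose(N, n1)))
}

# Brute-force longest run of exact unit copies: try every start position.
brute_longest_run <- function(seq, unit) {
  k <- nchar(unit)
  n <- nchar(seq)
  best <- 0L
  for (s in seq_len(max(n - k + 1L, 0L))) {
    cnt <- 0L
    pos <- s
    while (pos + k - 1L <= n && substr(seq, pos, pos + k - 1L) == unit) {
      cnt <- cnt + 1L
      pos <- pos + k
    }
    best <- max(best, cnt)
  }
  best
}

# Brute-force union width of 1-based inclusive intervals.
brute_union_width <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  covered <- logical(max(ends))
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  sum(covered)
}

# Truth-derived switch-error count for one phase block (global flip allowed).
block_switch_errors <- function(block, truth_tab) {
  tv <- truth_tab[sample_id == block$sample_id & type == "snp"]
  m <- merge(block$sites, tv, by = "pos")
  m <- m[(hap1 + hap2) == 1L]          # truly heterozygous in truth
  if (nrow(m) < 2L) return(0L)
  data.table::setorder(m, pos)
  assigned_hap <- ifelse(m$phased_gt == "1|0", 1L, 2L) # hap carrying alt, side A
  truth_hap <- ifelse(m$hap1 == 1L, 1L, 2L)
  agree <- assigned_hap == truth_hap
  sum(diff(agree) != 0L)
}
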