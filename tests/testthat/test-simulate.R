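test_that("simulator output is fully determined by the seed", {
  locus <- small_locus()
  tr <- small_truths()
  cfg <- read_sim_config(seed = 21, gdna_coverage_range = NULL,
                         gdna_mean_coverage = 10, flnc_reads_per_sample = 50)
  g1 <- simulate_gdna(locus, tr, cfg)
  g2 <- simulate_gdna(locus, tr, cfg)
  expect_identical(g1$reads, g2$reads)
  expect_identical(g1$dup_truth, g2$dup_truth)
  f1 <- simulate_flnc(locus, tr, cfg)
  f2 <- simulate_flnc(locus, tr, cfg)
  expect_identical(f1$reads, f2$reads)
  cfg2 <- read_sim_config(seed = 22, gdna_coverage_range = NULL,
                          gdna_mean_coverage = 10, flnc_reads_per_sample = 50)
  expect_false(identical(simulate_gdna(locus, tr, cfg2)$reads, g1$reads))
})

test_that("every simulated read records its source (truth completeness)", {
  g <- small_gdna()
  expect_true(all(!is.na(g$reads$hap)))
  expect_true(all(!is.na(g$reads$family_id)))
  expect_setequal(g$dup_truth$read_id, g$reads$read_id)
  f <- simulate_flnc(small_locus(), small_truths(),
                     read_sim_config(seed = 5, flnc_reads_per_sample = 50))
  expect_true(all(!is.na(f$reads$true_isoform)))
  expect_true(all(!is.na(f$reads$hap)))
  expect_setequal(f$iso_truth$read_id, f$reads$read_id)
})

test_that("duplicate_rate 0 yields no duplicate truth flags", {
  cfg <- read_sim_config(seed = 2, duplicate_rate = 0,
                         gdna_coverage_range = NULL, gdna_mean_coverage = 10)
  g <- simulate_gdna(small_locus(), small_truths(), cfg)
  expect_identical(sum(g$dup_truth$true_duplicate), 0L)
})

test_that("requested mean coverage is realised within 15%", {
  locus <- study_locus()
  tr <- study_truths()[1]
  cfg <- read_sim_config(seed = 3, gdna_coverage_range = NULL,
                         gdna_mean_coverage = 40, duplicate_rate = 0)
  g <- simulate_gdna(locus, tr, cfg)
  expect_gt(nrow(g$reads), 500)
  total_bases <- sum(as.numeric(g$reads$end - g$reads$start + 1L))
  cov <- total_bases / locus$length
  expect_lt(abs(cov - 40) / 40, 0.15)
})

test_that("planted het SNPs appear at intermediate allele fraction in pileup", {
  locus <- small_locus()
  tr <- small_truths()
  d <- small_dedup()
  vt <- variant_truth_table(tr)
  hets <- vt[type == "snp" & gt == "0/1" & sample_id == tr[[1]]$sample_id]
  pile <- locuskit:::.sample_pileup(
    d[sample_id == tr[[1]]$sample_id & !is_duplicate], locus$length, 13L)
  checked <- 0L
  for (i in seq_len(nrow(hets))) {
    cnt <- pile$counts[hets$pos[i], ]
    depth <- sum(cnt[1:4])
    if (depth < 20) next
    f <- cnt[hets$alt[i]] / depth
    expect_gte(f, 0.25)
    expect_lte(f, 0.75)
    checked <- checked + 1L
  }
  expect_gt(checked, 5)
})

test_that("zero requested coverage warns and yields no reads", {
  cfg <- read_sim_config(seed = 2, gdna_coverage_range = NULL,
                         gdna_mean_coverage = 0)
  expect_warning(g <- simulate_gdna(small_locus(), small_truths()[1], cfg),
                 "zero coverage")
  expect_identical(nrow(g$reads), 0L)
})

test_that("single-isoform mix produces only that junction chain", {
  locus <- small_locus()
  rep <- build_repertoire(locus, include_decoys = FALSE)
  tr <- small_truths()[1]
  tr[[1]]$isoform_mix <- c(iso_E1a_U1000 = 1)
  cfg <- read_sim_config(seed = 9, flnc_reads_per_sample = 100)
  f <- simulate_flnc(locus, tr, cfg, repertoire = rep)
  expect_identical(nrow(f$reads), 100L)
  chains <- vapply(seq_len(nrow(f$reads)), function(i) {
    intr <- locuskit:::cigar_introns(f$reads$cigar[i], f$reads$start[i])
    paste(intr$intron_start, intr$intron_end, collapse = ";")
  }, character(1))
  expect_identical(length(unique(chains)), 1L)
  ch <- rep$iso_E1a_U1000$chain
  expected <- paste(ch[-nrow(ch), 2] + 1L, ch[-1, 1] - 1L, collapse = ";")
  expect_identical(chains[1], expected)
})

test_that("a rare isoform is sampled at its planted frequency", {
  locus <- small_locus()
  rep <- build_repertoire(locus, include_decoys = FALSE)
  tr <- small_truths()[1]
  tr[[1]]$isoform_mix <- c(iso_E1a_U1000 = 0.98, iso_skip5_U1000 = 0.02)
  cfg <- read_sim_config(seed = 13, flnc_reads_per_sample = 5000)
  f <- simulate_flnc(locus, tr, cfg, repertoire = rep)
  obs <- mean(f$iso_truth$isoform_id == "iso_skip5_U1000")
  sd3 <- 3 * sqrt(0.02 * 0.98 / 5000)
  expect_lt(abs(obs - 0.02), sd3)
})

test_that("planted short and long 3' UTR ends form two distinct end groups", {
  locus <- small_locus()
  rep <- build_repertoire(locus, include_decoys = FALSE)
  tr <- small_truths()[1]
  tr[[1]]$isoform_mix <- c(iso_E1a_U300 = 0.5, iso_E1a_U2600 = 0.5)
  cfg <- read_sim_config(seed = 17, flnc_reads_per_sample = 200)
  f <- simulate_flnc(locus, tr, cfg, repertoire = rep)
  # minus strand: the transcript 3' end is the genomic start
  ends <- f$reads$start
  expect_identical(length(unique(kmeans_1d <- cut(ends, 2))), 2L)
  gap <- diff(sort(unique(tapply(ends, f$iso_truth$isoform_id, median))))
  expect_gt(gap, 2000)
})

test_that("a mix naming an undefined isoform fails loudly", {
  tr <- small_truths()[1]
  tr[[1]]$isoform_mix <- c(iso_unknown = 1)
  expect_error(simulate_flnc(small_locus(), tr, read_sim_config(seed = 1)),
               "iso_unknown")
})
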