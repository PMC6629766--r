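test_that("locus builder satisfies its invariants across seeds and strands", {
  for (seed in 1:3) {
    locus <- build_locus(seed = seed, length = 30000)
    expect_true(validate_locus(locus))
    expect_identical(nchar(locus$ref_seq), locus$length)
    expect_identical(
      substr(locus$ref_seq, locus$str_region[1], locus$str_region[2]),
      strrep(locus$str_unit, locus$reference_unit_count))
  }
  plus <- build_locus(seed = 4, length = 30000, strand = "+")
  expect_true(validate_locus(plus))
})

test_that("same seed gives byte-identical loci, different seeds differ", {
  a <- build_locus(seed = 1, length = 20000)
  b <- build_locus(seed = 1, length = 20000)
  expect_identical(a$ref_seq, b$ref_seq)
  expect_identical(a$gene$exons, b$gene$exons)
  expect_false(identical(build_locus(seed = 2, length = 20000)$ref_seq,
                         a$ref_seq))
})

test_that("too-small locus is rejected", {
  expect_error(build_locus(seed = 1, length = 10000), "20000")
})

test_that("default locus is 114 kb with a six-exon minus-strand gene", {
  locus <- study_locus()
  expect_identical(locus$length, 114000L)
  expect_identical(nrow(locus$gene$exons), 6L)
  expect_identical(locus$strand, "-")
  expect_identical(locus$gene$protein_length_aa, 141L)
  expect_identical(locus$reference_unit_count, 16L)
  # 3' UTR options span 300-2600 bases
  expect_identical(range(locus$gene$utr3_options), c(300L, 2600L))
})

test_that("exon 3 and exon 5 skipping preserves the reading frame", {
  locus <- small_locus()
  tx3 <- transcript_sequence(locuskit:::.chain(locus, skip = 3L), locus)
  tx5 <- transcript_sequence(locuskit:::.chain(locus, skip = 5L), locus)
  aa3 <- locuskit:::translate_from(tx3, locus$gene$cds_tx_start)
  aa5 <- locuskit:::translate_from(tx5, locus$gene$cds_tx_start)
  expect_identical(nchar(aa3), 99L)    # 141 - 126/3
  expect_identical(nchar(aa5), 130L)   # 141 - 33/3
})

test_that("planted repertoire has 13 valid isoforms plus 2 decoys", {
  rep <- build_repertoire(study_locus(), include_decoys = TRUE)
  classes <- vapply(rep, `[[`, character(1), "class_truth")
  expect_identical(sum(classes != "decoy"), 13L)
  expect_identical(sum(classes == "decoy"), 2L)
  counts <- as.integer(table(classes)[c("AllExons", "Skip3", "Skip5",
                                        "Alt5", "Alt3")])
  expect_identical(counts, c(7L, 2L, 2L, 1L, 1L))
  expect_equal(sum(repertoire_mix(rep)), 1)
  # class-level planted mix matches the study design
  mix <- repertoire_mix(rep)
  by_class <- tapply(mix, classes[names(mix)], sum)
  expect_equal(as.numeric(by_class[c("AllExons", "Skip3", "Skip5", "Alt5",
                                     "Alt3")]),
               c(0.96, 0.005, 0.02, 0.01, 0.005))
})

test_that("sample truths honour requested repeat genotypes and abundances", {
  locus <- small_locus()
  tr <- make_sample_truths(locus, 12, seed = 1)
  expect_length(tr, 12)
  expect_identical(vapply(tr, `[[`, character(1), "condition"),
                   rep(c("PD", "N", "DLB"), each = 4))
  # default triplet-repeat genotype table is carried through
  expect_identical(c(tr[[1]]$hap1$str_units, tr[[1]]$hap2$str_units),
                   c(15L, 15L))
  expect_identical(sort(c(tr[[11]]$hap1$str_units, tr[[11]]$hap2$str_units)),
                   c(9L, 15L))
  # all four CT-rich catalog haplotypes occur in the cohort
  cts <- unlist(lapply(tr, function(x) c(x$hap1$ct_hap, x$hap2$ct_hap)))
  expect_setequal(unique(cts), 1:4)
  for (x in tr) expect_equal(sum(x$isoform_mix), 1)
})
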