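test_that("spanning extraction returns the reference slice for perfect reads", {
  locus <- small_locus()
  region <- locus$str_region
  s <- region[1] - 100L
  e <- region[2] + 100L
  perfect <- synth_read(locus, s, substr(locus$ref_seq, s, e), read_id = "ok")
  inside <- synth_read(locus, s, substr(locus$ref_seq, s, region[1] + 10L),
                       read_id = "short")
  subs <- extract_spanning(rbind(perfect, inside), region)
  expect_identical(subs$read_id, "ok")
  expect_identical(subs$sequence,
                   substr(locus$ref_seq, region[1], region[2]))
})

test_that("extraction length tracks the planted repeat allele", {
  locus <- small_locus()
  tr <- small_truths()     # PD-1 is (TTG)15/(TTG)15 by default
  d <- small_dedup()
  subs <- extract_spanning(d[sample_id == "PD-1"], locus$str_region)
  ref_len <- locus$str_region[2] - locus$str_region[1] + 1L
  expected <- ref_len + 3L * (15L - locus$reference_unit_count)
  expect_gt(nrow(subs), 5)
  expect_lte(stats::median(abs(nchar(subs$sequence) - expected)), 1)
})

test_that("size clustering separates length classes and keeps support rule", {
  a <- strrep("ACGTT", 8)             # 40 bases
  b <- strrep("GT", 23)               # 46 bases -> gap 6 > size_tol
  subs <- data.table::data.table(
    read_id = sprintf("r%02d", 1:20), sample_id = "S1",
    sequence = c(rep(a, 10), rep(b, 10)))
  cl <- cluster_by_size_and_similarity(subs)
  expect_length(cl, 2)
  expect_setequal(vapply(cl, nrow, integer(1)), c(10L, 10L))

  one <- cluster_by_size_and_similarity(subs[sequence == a])
  expect_length(one, 1)

  expect_warning(tiny <- cluster_by_size_and_similarity(subs[1:2]),
                 "min_support")
  expect_length(tiny, 0)
})

test_that("similarity splits same-length haplotypes within a size bin", {
  locus <- small_locus()
  h1 <- locus$ct_catalog$H1
  h4 <- locus$ct_catalog$H4            # same length, 20 substitutions apart
  subs <- data.table::data.table(
    read_id = sprintf("r%02d", 1:16), sample_id = "S1",
    sequence = c(rep(h1, 8), rep(h4, 8)))
  cl <- cluster_by_size_and_similarity(subs)
  expect_length(cl, 2)
})

test_that("consensus is exact for identical members and robust to minorities", {
  s <- strrep("ACGTGTTGCA", 5)
  cl <- data.table::data.table(read_id = sprintf("r%d", 1:5), sequence = s)
  expect_identical(cluster_consensus(cl), s)

  mut <- s
  substr(mut, 12, 12) <- "A"
  cl2 <- data.table::data.table(read_id = sprintf("r%d", 1:10),
                                sequence = c(rep(s, 9), mut))
  expect_identical(cluster_consensus(cl2), s)
})

test_that("repeat-unit counting equals the printed examples", {
  flank_l <- "CCATG"
  flank_r <- "ACCAT"
  expect_identical(count_repeat_units(paste0(flank_l, strrep("TTG", 12), flank_r),
                                      "TTG"), 12L)
  expect_identical(count_repeat_units(strrep("TTG", 16), "TTG"), 16L)
  expect_identical(count_repeat_units("TTGTTGATTGTTG", "TTG"), 2L)
  expect_identical(count_repeat_units("ACGT", "TTG"), 0L)
  expect_error(count_repeat_units("ACGT", ""), "non-empty")
})

test_that("repeat-unit counting agrees with brute force on random strings", {
  set.seed(42)
  units <- c("TTG", "CT", "A", "ACG")
  for (i in 1:1000) {
    u <- sample(units, 1)
    s <- paste(sample(c("A", "C", "G", "T"), sample(10:60, 1), replace = TRUE),
               collapse = "")
    expect_identical(count_repeat_units(s, u), brute_longest_run(s, u))
  }
})

test_that("cluster counts map onto diploid repeat genotypes", {
  mk <- function(seq, n, prefix)
    data.table::data.table(read_id = sprintf("%s%02d", prefix, 1:n),
                           sample_id = "S1", sequence = seq)
  a15 <- paste0("CCA", strrep("TTG", 15), "ACC")
  a12 <- paste0("CCA", strrep("TTG", 12), "ACC")
  het <- genotype_region(list(mk(a15, 8, "a"), mk(a12, 6, "b")), "S1", "str",
                         unit = "TTG")
  expect_identical(het$allele1, "(TTG)15")
  expect_identical(het$allele2, "(TTG)12")
  expect_identical(c(het$support1, het$support2), c(8L, 6L))

  hom <- genotype_region(list(mk(a12, 9, "a")), "S1", "str", unit = "TTG")
  expect_identical(paste0(hom$allele1, "/", hom$allele2), "(TTG)12/(TTG)12")

  none <- genotype_region(list(), "S1", "str", unit = "TTG")
  expect_identical(none$flag, "unresolved")

  three <- genotype_region(list(mk(a15, 9, "a"), mk(a12, 6, "b"),
                                mk(a12, 4, "c")), "S1", "str", unit = "TTG")
  expect_identical(three$flag, "extra_clusters")
  expect_identical(c(three$support1, three$support2), c(9L, 6L))
})

test_that("catalog labelling picks the nearest haplotype", {
  locus <- small_locus()
  mk <- function(seq, n, prefix)
    data.table::data.table(read_id = sprintf("%s%02d", prefix, 1:n),
                           sample_id = "S1", sequence = seq)
  gt <- genotype_region(list(mk(locus$ct_catalog$H3, 7, "a"),
                             mk(locus$ct_catalog$H2, 5, "b")),
                        "S1", "ct", catalog = locus$ct_catalog)
  expect_identical(gt$allele1, "H3")
  expect_identical(gt$allele2, "H2")
})

test_that("homozygous samples never split into two clusters at low error", {
  locus <- small_locus()
  d <- small_dedup()
  # both small-study samples are homozygous for the repeat by default truth
  tr <- small_truths()
  for (s in vapply(tr, `[[`, "", "sample_id")) {
    u <- unique(c(tr[[which(vapply(tr, `[[`, "", "sample_id") == s)]]$hap1$str_units,
                  tr[[which(vapply(tr, `[[`, "", "sample_id") == s)]]$hap2$str_units))
    if (length(u) != 1L) next
    subs <- extract_spanning(d[sample_id == s], locus$str_region)
    cl <- cluster_by_size_and_similarity(subs[sample_id == s])
    expect_length(cl, 1)
  }
})
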