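# A pileup built directly from count specifications, bypassing reads.
mk_pileup <- function(len, spec, samples = "S1") {
  # spec: list of list(pos, base, count, sample)
  per_sample <- lapply(samples, function(s) {
    m <- matrix(0L, nrow = len, ncol = 4L,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    for (x in spec) if (x$sample == s) m[x$pos, x$base] <- x$count
    m
  })
  names(per_sample) <- samples
  list(pooled = Reduce(`+`, per_sample), per_sample = per_sample)
}

test_that("low-QV bases never reach the pileup counts", {
  locus <- small_locus()
  pos <- 5000L
  ref_b <- substr(locus$ref_seq, pos, pos)
  alt_b <- setdiff(c("A", "C", "G", "T"), ref_b)[1]
  reads <- data.table::rbindlist(c(
    lapply(1:50, function(i) synth_read(locus, pos, ref_b, qv = 30,
                                        read_id = sprintf("a%02d", i))),
    lapply(1:10, function(i) synth_read(locus, pos, alt_b, qv = 5,
                                        read_id = sprintf("b%02d", i)))))
  pile <- flnc_pileup(reads, locus$length)
  expect_identical(unname(pile$pooled[pos, ref_b]), 50L)
  expect_identical(unname(pile$pooled[pos, alt_b]), 0L)
})

test_that("coverage gate, Fisher test and Bonferroni govern calling", {
  seq <- paste(rep(c("A", "C", "G", "T"), length.out = 200), collapse = "")
  loc <- mini_locus(seq)
  ref40 <- substr(seq, 40, 40)
  alt40 <- setdiff(c("A", "C", "G", "T"), ref40)[1]
  # position 40: coverage 100 with 30 alt; position 41: coverage 39 (below
  # the gate); position 42: coverage 100, no alt
  ref41 <- substr(seq, 41, 41); ref42 <- substr(seq, 42, 42)
  pile <- mk_pileup(200, list(
    list(pos = 40L, base = ref40, count = 70L, sample = "S1"),
    list(pos = 40L, base = alt40, count = 30L, sample = "S1"),
    list(pos = 41L, base = ref41, count = 39L, sample = "S1"),
    list(pos = 42L, base = ref42, count = 100L, sample = "S1")))
  snps <- call_snps(pile, loc)
  expect_identical(snps$m[1], 2L)            # positions 40 and 42 tested
  expect_identical(snps[called == TRUE, pos], 40L)
  # frozen oracle: brute-force hypergeometric tail for [[30,70],[1,99]]
  expect_equal(snps[pos == 40L, raw_p], 1.336910439797899e-09,
               tolerance = 1e-12)
})

test_that("the caller's Fisher p equals the brute-force tail", {
  expect_equal(fisher_snp_p(30L, 70L, 100L, 0.005),
               brute_hyper_p(30L, 70L, 1L, 99L), tolerance = 1e-12)
  expect_equal(fisher_snp_p(5L, 195L, 200L, 0.005),
               brute_hyper_p(5L, 195L, 1L, 199L), tolerance = 1e-12)
})

test_that("homopolymer-adjacent significant sites are suppressed", {
  seq <- paste0(strrep("ACGT", 10), "AAAA", "C", strrep("GTCA", 10))
  loc <- mini_locus(seq)
  # the C right after the AAAA run is within the exclusion flank
  pos_c <- 45L
  expect_identical(substr(seq, pos_c, pos_c), "C")
  expect_true(homopolymer_mask(seq)[pos_c])
  pile <- mk_pileup(nchar(seq), list(
    list(pos = pos_c, base = "C", count = 60L, sample = "S1"),
    list(pos = pos_c, base = "T", count = 40L, sample = "S1")))
  snps <- call_snps(pile, loc)
  expect_identical(nrow(snps), 1L)
  expect_false(snps$called)
  expect_identical(snps$reason, "homopolymer")
})

test_that("the genotype evidence rule matches its quoted cases", {
  expect_identical(genotype_samples(6L, 6L), "het")
  expect_identical(genotype_samples(5L, 4L), "homo_ref")
  expect_identical(genotype_samples(4L, 5L), "homo_alt")
  expect_identical(genotype_samples(4L, 4L), "inconclusive")
})

test_that("per-sample genotyping reads counts from the per-sample pileup", {
  seq <- strrep("ACGT", 50)
  loc <- mini_locus(seq)
  ref_b <- substr(seq, 40, 40)
  alt_b <- setdiff(c("A", "C", "G", "T"), ref_b)[1]
  pile <- mk_pileup(200, list(
    list(pos = 40L, base = ref_b, count = 30L, sample = "S1"),
    list(pos = 40L, base = alt_b, count = 30L, sample = "S1"),
    list(pos = 40L, base = ref_b, count = 50L, sample = "S2"),
    list(pos = 40L, base = alt_b, count = 3L, sample = "S2")),
    samples = c("S1", "S2"))
  snps <- call_snps(pile, loc)
  gts <- genotype_cdna_snps(snps, pile)
  expect_identical(gts[sample_id == "S1", genotype], "het")
  expect_identical(gts[sample_id == "S2", genotype], "homo_ref")
})

test_that("SNPs link only to isoforms whose exons cover them", {
  isos <- list(
    long = list(id = "long", chain = cbind(start = c(100L, 500L),
                                           end = c(200L, 2000L))),
    short = list(id = "short", chain = cbind(start = c(100L, 500L),
                                             end = c(200L, 800L))))
  snps <- data.table::data.table(pos = c(150L, 1200L), called = TRUE)
  links <- link_snps_to_isoforms(snps, isos)
  expect_setequal(links$covering[["150"]], c("long", "short"))
  expect_identical(links$covering[["1200"]], "long")
  expect_identical(nrow(links$unlinkable_pairs), 0L)

  # mutually exclusive first exons -> disjoint covering sets
  isos2 <- list(
    a = list(id = "a", chain = cbind(start = 100L, end = 200L)),
    b = list(id = "b", chain = cbind(start = 300L, end = 400L)))
  snps2 <- data.table::data.table(pos = c(150L, 350L), called = TRUE)
  links2 <- link_snps_to_isoforms(snps2, isos2)
  expect_identical(nrow(links2$unlinkable_pairs), 1L)
})
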