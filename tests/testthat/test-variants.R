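# Constructed pileups around one position of the small locus.
.stack_reads <- function(locus, pos, bases, sample_id = "S1", qv = 40L) {
  data.table::rbindlist(lapply(seq_along(bases), function(i)
    synth_read(locus, pos, bases[i], sample_id = sample_id, qv = qv,
               read_id = sprintf("r%03d", i))))
}

test_that("allele fractions map to diploid genotypes", {
  locus <- small_locus()
  pos <- 5000L
  ref_b <- substr(locus$ref_seq, pos, pos)
  alt_b <- setdiff(c("A", "C", "G", "T"), ref_b)[1]
  # depth 30, alt 0 -> 0/0 at a het discovery site elsewhere; here we check
  # both a pure-reference and a balanced stack
  reads <- .stack_reads(locus, pos, c(rep(alt_b, 15), rep(ref_b, 15)))
  calls <- pileup_genotype(reads, locus, mask = list())
  expect_identical(calls[pos == 5000 & type == "snp", genotype], "0/1")
  expect_identical(calls[pos == 5000 & type == "snp", alt_allele], alt_b)

  reads_hom <- .stack_reads(locus, pos, rep(alt_b, 28))
  calls <- pileup_genotype(reads_hom, locus, mask = list())
  expect_identical(calls[pos == 5000 & type == "snp", genotype], "1/1")

  # pure reference stack discovers nothing
  calls <- pileup_genotype(.stack_reads(locus, pos, rep(ref_b, 30)), locus,
                           mask = list())
  expect_identical(nrow(calls), 0L)
})

test_that("low-QV bases are excluded and low depth is flagged missing", {
  locus <- small_locus()
  pos <- 6000L
  ref_b <- substr(locus$ref_seq, pos, pos)
  alt_b <- setdiff(c("A", "C", "G", "T"), ref_b)[1]
  # 20 ref at QV 40 plus 10 alt at QV 5: alt invisible after the QV filter
  reads <- rbind(.stack_reads(locus, pos, rep(ref_b, 20), qv = 40),
                 .stack_reads(locus, pos + 1L, rep(alt_b, 10), qv = 5))
  calls <- pileup_genotype(reads, locus, mask = list())
  expect_identical(nrow(calls[type == "snp" & pos == 6000]), 0L)

  # depth below min_depth -> ./.; variant discovered in a deep sample
  deep <- .stack_reads(locus, pos, c(rep(alt_b, 10), rep(ref_b, 10)), "S1")
  shallow <- .stack_reads(locus, pos, rep(alt_b, 5), "S2")
  calls <- pileup_genotype(rbind(deep, shallow), locus, mask = list())
  expect_identical(calls[sample_id == "S2" & type == "snp", genotype], "./.")
  expect_identical(calls[sample_id == "S2" & type == "snp", qual_flag],
                   "low_depth")
})

test_that("deletions are genotyped from alignment gaps", {
  locus <- small_locus()
  pos <- 7000L
  span <- 41L
  piece <- function(skip) {
    # read covering pos-20..pos+20 with a 3-base deletion at pos..pos+2
    if (skip) {
      seq <- paste0(substr(locus$ref_seq, pos - 20L, pos - 1L),
                    substr(locus$ref_seq, pos + 3L, pos + 20L))
      synth_read(locus, pos - 20L, seq, cigar = "20M3D18M")
    } else {
      synth_read(locus, pos - 20L, substr(locus$ref_seq, pos - 20L, pos + 20L))
    }
  }
  reads <- data.table::rbindlist(lapply(1:24, function(i) {
    r <- piece(i %% 2 == 0)
    r$read_id <- sprintf("d%02d", i)
    r
  }))
  calls <- pileup_genotype(reads, locus, mask = list())
  del <- calls[type == "del"]
  expect_identical(nrow(del), 1L)
  expect_identical(del$pos, pos - 1L)
  expect_identical(nchar(del$ref_allele), 4L)   # anchor + 3 deleted bases
  expect_identical(del$genotype, "0/1")
})

test_that("phase-consistent pairs pass and artifact sites are flagged", {
  locus <- small_locus()
  p1 <- 9000L; p2 <- 9400L; p3 <- 9200L
  rb <- function(p) substr(locus$ref_seq, p, p)
  ab <- function(p) setdiff(c("A", "C", "G", "T"), rb(p))[1]
  mk <- function(i, a1, a2, a3) {
    seq <- substr(locus$ref_seq, 8900L, 9500L)
    substr(seq, p1 - 8900L + 1L, p1 - 8900L + 1L) <- if (a1) ab(p1) else rb(p1)
    substr(seq, p3 - 8900L + 1L, p3 - 8900L + 1L) <- if (a3) ab(p3) else rb(p3)
    substr(seq, p2 - 8900L + 1L, p2 - 8900L + 1L) <- if (a2) ab(p2) else rb(p2)
    synth_read(locus, 8900L, seq, read_id = sprintf("p%03d", i))
  }
  # sites p1/p2 perfectly cis; site p3 random w.r.t. both
  reads <- data.table::rbindlist(lapply(1:20, function(i)
    mk(i, a1 = i <= 10, a2 = i <= 10, a3 = i %% 2 == 0)))
  calls <- pileup_genotype(reads, locus, mask = list())
  expect_setequal(calls[type == "snp", unique(pos)], c(p1, p2, p3))
  filt <- phase_consistency_filter(calls, reads)
  expect_identical(filt[pos == p1, qual_flag], "pass")
  expect_identical(filt[pos == p2, qual_flag], "pass")
  expect_identical(filt[pos == p3, qual_flag], "phase_inconsistent")
  expect_identical(filt[pos == p3, genotype], "./.")
})

test_that("isolated het calls with no co-covered partner stay unflagged", {
  locus <- small_locus()
  pos <- 11000L
  alt_b <- setdiff(c("A", "C", "G", "T"), substr(locus$ref_seq, pos, pos))[1]
  reads <- .stack_reads(locus, pos,
                        c(rep(alt_b, 10),
                          rep(substr(locus$ref_seq, pos, pos), 10)))
  calls <- pileup_genotype(reads, locus, mask = list())
  filt <- phase_consistency_filter(calls, reads)
  expect_identical(filt[pos == 11000, qual_flag], "pass")
})

test_that("concordant reads chain het sites into one phase block", {
  locus <- small_locus()
  ps <- c(9000L, 9200L, 9400L)
  rb <- function(p) substr(locus$ref_seq, p, p)
  ab <- function(p) setdiff(c("A", "C", "G", "T"), rb(p))[1]
  mk <- function(i, alt) {
    seq <- substr(locus$ref_seq, 8900L, 9500L)
    for (p in ps)
      substr(seq, p - 8900L + 1L, p - 8900L + 1L) <- if (alt) ab(p) else rb(p)
    synth_read(locus, 8900L, seq, read_id = sprintf("b%03d", i))
  }
  reads <- data.table::rbindlist(lapply(1:10, function(i) mk(i, i <= 5)))
  calls <- pileup_genotype(reads, locus, mask = list())
  blocks <- read_backed_phase(calls, reads)
  expect_length(blocks, 1)
  expect_identical(blocks[[1]]$sites$pos, ps)
  expect_identical(length(unique(blocks[[1]]$sites$phased_gt)), 1L) # all cis
})

test_that("het clusters separated by more than a read length split blocks", {
  locus <- small_locus()
  mk_cluster <- function(base_pos, prefix) {
    ps <- base_pos + c(0L, 150L)
    rb <- function(p) substr(locus$ref_seq, p, p)
    ab <- function(p) setdiff(c("A", "C", "G", "T"), rb(p))[1]
    data.table::rbindlist(lapply(1:10, function(i) {
      seq <- substr(locus$ref_seq, base_pos - 50L, base_pos + 200L)
      for (p in ps) {
        o <- p - (base_pos - 50L) + 1L
        substr(seq, o, o) <- if (i <= 5) ab(p) else rb(p)
      }
      synth_read(locus, base_pos - 50L, seq,
                 read_id = sprintf("%s%03d", prefix, i))
    }))
  }
  reads <- rbind(mk_cluster(5000L, "u"), mk_cluster(15000L, "v"))
  calls <- pileup_genotype(reads, locus, mask = list())
  blocks <- read_backed_phase(calls, reads)
  expect_length(blocks, 2)
})

test_that("phasing summary arithmetic matches hand computation", {
  blocks <- list(
    structure(list(sample_id = "S1", contig = "c", start = 1L, end = 10000L,
                   sites = NULL), class = "PhaseBlock"),
    structure(list(sample_id = "S1", contig = "c", start = 20001L,
                   end = 30000L, sites = NULL), class = "PhaseBlock"))
  s <- phasing_summary(blocks, c(1L, 100000L))
  expect_equal(s$fraction_of_region, 0.20)
  expect_equal(s$longest_block, 10000)
  s0 <- phasing_summary(list(), c(1L, 100000L), samples = "S1")
  expect_equal(s0$fraction_of_region, 0)
  expect_error(phasing_summary(blocks, c(5L, 4L)), "positive length")
})
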