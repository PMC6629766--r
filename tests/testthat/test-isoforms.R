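# Construct an aligned spliced read following an exon chain exactly.
chain_read <- function(locus, chain, sample_id = "S1",
                       read_id = "r1", qv = 40L) {
  pieces <- vapply(seq_len(nrow(chain)), function(i)
    substr(locus$ref_seq, chain[i, 1], chain[i, 2]), character(1))
  seq <- paste(pieces, collapse = "")
  lens <- chain[, 2] - chain[, 1] + 1L
  gaps <- chain[-1, 1] - chain[-nrow(chain), 2] - 1L
  cigar <- paste0(lens[1], "M")
  for (i in seq_along(gaps))
    cigar <- paste0(cigar, gaps[i], "N", lens[i + 1L], "M")
  synth_read(locus, chain[1, 1], seq, sample_id = sample_id,
             read_id = read_id, cigar = cigar, qv = qv,
             strand = locus$strand)
}

test_that("identical chains with jittered ends collapse to one isoform", {
  locus <- small_locus()
  rep <- build_repertoire(locus, include_decoys = FALSE)
  ch <- rep$iso_E1a_U1000$chain
  reads <- data.table::rbindlist(lapply(1:30, function(i) {
    ch2 <- ch
    ch2[1, 1] <- ch2[1, 1] - (i %% 20L)         # 3' jitter within tol
    ch2[nrow(ch2), 2] <- ch2[nrow(ch2), 2] + (i %% 10L)
    chain_read(locus, ch2, read_id = sprintf("r%02d", i))
  }))
  coll <- collapse_flnc(reads, strand = locus$strand)
  expect_length(coll$isoforms, 1)
  expect_identical(sum(coll$isoforms[[1]]$fl_counts), 30L)
})

test_that("3' ends separated by far more than tolerance become two isoforms", {
  locus <- small_locus()
  rep <- build_repertoire(locus, include_decoys = FALSE)
  reads <- rbind(
    data.table::rbindlist(lapply(1:10, function(i)
      chain_read(locus, rep$iso_E1a_U300$chain, read_id = sprintf("a%02d", i)))),
    data.table::rbindlist(lapply(1:10, function(i)
      chain_read(locus, rep$iso_E1a_U2600$chain, read_id = sprintf("b%02d", i)))))
  coll <- collapse_flnc(reads, strand = locus$strand)
  expect_length(coll$isoforms, 2)
})

test_that("collapse is invariant to read order", {
  locus <- small_locus()
  f <- simulate_flnc(locus, small_truths(),
                     read_sim_config(seed = 31, flnc_reads_per_sample = 300))
  coll1 <- collapse_flnc(f$reads, strand = locus$strand)
  set.seed(1)
  perm <- f$reads[sample(.N)]
  coll2 <- collapse_flnc(perm, strand = locus$strand)
  key <- function(coll) sort(vapply(coll$isoforms, function(x)
    paste(c(t(x$chain)), collapse = ","), character(1)))
  expect_identical(key(coll1), key(coll2))
})

test_that("mono-exon reads group by reciprocal overlap", {
  locus <- small_locus()
  reads <- data.table::rbindlist(list(
    synth_read(locus, 1000, strrep("A", 1000), read_id = "m1"),
    synth_read(locus, 1100, strrep("A", 1000), read_id = "m2"),
    synth_read(locus, 5000, strrep("A", 1000), read_id = "m3")))
  expect_warning(coll <- collapse_flnc(reads, strand = "+"), "unspliced")
  expect_length(coll$isoforms, 2)
})

test_that("junction-motif filter keeps canonical and drops the decoy", {
  locus <- small_locus()
  rep <- build_repertoire(locus, include_decoys = TRUE)
  mk_iso <- function(def, id, n = 25L) {
    list(id = id, contig = locus$contig_name, strand = locus$strand,
         chain = def$chain,
         junctions = data.table::data.table(
           intron_start = def$chain[-nrow(def$chain), 2] + 1L,
           intron_end = def$chain[-1, 1] - 1L),
         fl_counts = c(S1 = n))
  }
  isos <- list(ok = mk_iso(rep$iso_E1a_U300, "ok"),
               bad = mk_iso(rep$decoy_noncanonical, "bad"),
               weak = mk_iso(rep$iso_E1b_U300, "weak", n = 19L),
               edge = mk_iso(rep$iso_E1b_U1000, "edge", n = 20L))
  filt <- filter_isoforms(isos, locus)
  expect_setequal(names(filt$retained), c("ok", "edge"))
  expect_identical(filt$dropped[id == "bad", reason], "noncanonical_junction")
  expect_identical(filt$dropped[id == "weak", reason], "low_fl_support")
})

test_that("adenine-rich genomic downstream marks intra-priming artifacts", {
  # plus-strand toy reference: exon ends right before a 15-A run
  seq <- paste0(strrep("ACGTG", 40), strrep("A", 15), strrep("CGTAG", 40))
  loc <- mini_locus(seq, strand = "+")
  iso <- list(id = "x", contig = "mini", strand = "+",
              chain = cbind(start = 1L, end = 200L),
              junctions = data.table::data.table(intron_start = integer(0),
                                                 intron_end = integer(0)),
              fl_counts = c(S1 = 30L))
  filt <- filter_isoforms(list(x = iso), loc)
  expect_identical(filt$dropped$reason, "intrapriming")
  filt2 <- filter_isoforms(list(x = iso), loc, polya_check = FALSE)
  expect_length(filt2$retained, 1)
})

test_that("splice classes match the planted truth for the whole repertoire", {
  locus <- small_locus()
  rep <- build_repertoire(locus, include_decoys = FALSE)
  for (def in rep) {
    iso <- list(id = def$id, contig = locus$contig_name,
                strand = locus$strand, chain = def$chain)
    expect_identical(classify_splice_pattern(iso, locus), def$class_truth)
  }
})

test_that("classification rejects isoforms from another contig", {
  locus <- small_locus()
  iso <- list(id = "x", contig = "other", strand = "-",
              chain = cbind(start = 1L, end = 10L))
  expect_error(classify_splice_pattern(iso, locus), "contig")
})

test_that("abundance percentages are per-sample and classes sum to 100", {
  isos <- list(
    a = list(id = "a", splice_class = "AllExons",
             fl_counts = c(S1 = 50L, S2 = 10L)),
    b = list(id = "b", splice_class = "AllExons",
             fl_counts = c(S1 = 30L, S2 = 70L)),
    c = list(id = "c", splice_class = "Skip5",
             fl_counts = c(S1 = 20L, S2 = 20L)))
  ab <- abundance(isos)
  expect_equal(ab[id == "a", S1], 50)
  expect_equal(sum(ab$S2), 100)
  abc <- abundance(isos, by_class = TRUE)
  expect_equal(sum(abc$S1), 100)
  expect_equal(abc[id == "AllExons", S1], 80)
})

test_that("junction support thresholds follow the confirmation rule", {
  locus <- small_locus()
  rep <- build_repertoire(locus, include_decoys = FALSE)
  def <- rep$iso_novel_start
  iso <- list(id = "ns", contig = locus$contig_name, strand = locus$strand,
              chain = def$chain,
              junctions = data.table::data.table(
                intron_start = def$chain[-nrow(def$chain), 2] + 1L,
                intron_end = def$chain[-1, 1] - 1L),
              fl_counts = c(S1 = 30L))
  novel <- iso$junctions[2]   # the junction into the novel start exon
  sup <- function(cnt) data.table::data.table(
    intron_start = novel$intron_start, intron_end = novel$intron_end,
    count = cnt)
  at10 <- validate_junctions(list(ns = iso), locus, sup(10L))
  expect_true(all(at10$junctions[annotated == FALSE, status] == "supported"))
  expect_true(at10$isoforms$confirmed)
  at9 <- validate_junctions(list(ns = iso), locus, sup(9L))
  expect_false(at9$isoforms$confirmed)
  absent <- validate_junctions(list(ns = iso), locus,
                               sup(100L)[0])  # empty table: counts 0
  expect_true(all(absent$junctions[annotated == FALSE, status] ==
                    "unsupported"))
  unk <- validate_junctions(list(ns = iso), locus, NULL)
  expect_true(all(unk$junctions$status == "unknown"))
})

test_that("ORF prediction distinguishes canonical, in-frame-shorter and truncated", {
  locus <- small_locus()
  rep <- build_repertoire(locus, include_decoys = FALSE)
  orf_of <- function(def) predict_orf(list(chain = def$chain), locus)
  can <- orf_of(rep$iso_E1a_U2600)
  expect_identical(can$orf_status, "canonical")
  expect_identical(can$protein_length, 141L)
  expect_identical(orf_of(rep$iso_E1a_U300)$orf_status, "canonical")
  s3 <- orf_of(rep$iso_skip3_U300)
  expect_identical(s3$orf_status, "frame_maintained_shorter")
  expect_identical(s3$protein_length, 99L)
  s5 <- orf_of(rep$iso_skip5_U1000)
  expect_identical(s5$orf_status, "frame_maintained_shorter")
  expect_identical(s5$protein_length, 130L)
  expect_identical(orf_of(rep$iso_novel_end)$orf_status, "truncated")
})
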