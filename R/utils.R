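#' @import data.table
#' @importFrom stats rbinom rnorm runif setNames
#' @importFrom utils adist head tail
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never clobbers user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stage-specific seed from a master seed; stays below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 16807) %% 2147483629)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  sample(DNA_BASES, n, replace = TRUE)
}

revcomp <- function(s) {
  if (length(s) == 1L && nchar(s) != 1L) {
    # string form
    chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  } else {
    # character-vector form (one base per element)
    rev(chartr("ACGTacgt", "TGCAtgca", s))
  }
}

s2c <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
c2s <- function(x) paste(x, collapse = "")

# Phred+33 encoding; QVs up to 93 are representable.
qv_to_char <- function(qv) intToUtf8(pmin(qv, 93L) + 33L, multiple = FALSE)
char_to_qv <- function(qual) utf8ToInt(qual) - 33L

# Replace any occurrence of `unit` in a character vector of bases by breaking
# its middle base; used to keep repeat flanks free of stray units.
scrub_unit <- function(chars, unit) {
  k <- nchar(unit)
  u <- s2c(unit)
  n <- length(chars)
  if (n < k) return(chars)
  repeat {
    hit <- FALSE
    for (i in seq_len(n - k + 1L)) {
      if (all(chars[i:(i + k - 1L)] == u)) {
        mid <- i + k %/% 2L
        chars[mid] <- setdiff(DNA_BASES, chars[mid])[1L]
        hit <- TRUE
      }
    }
    if (!hit) break
  }
  chars
}

## ---- CIGAR arithmetic ------------------------------------------------------

parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  list(len = lens, op = ops)
}

# Per-aligned-position table for one read: one row per reference position
# consumed (M rows carry the query base and QV, D rows carry NA). Insertions
# and intron gaps (N) consume no reference rows.
expand_alignment <- function(cigar, start, seq, qual = NULL) {
  cg <- parse_cigar(cigar)
  nref <- sum(cg$len[cg$op %in% c("M", "D", "N", "=", "X")])
  ref_pos <- integer(0)
  qpos <- integer(0)
  op_out <- character(0)
  rcur <- start
  qcur <- 1L
  for (i in seq_along(cg$op)) {
    l <- cg$len[i]
    o <- cg$op[i]
    if (o %in% c("M", "=", "X")) {
      ref_pos <- c(ref_pos, rcur:(rcur + l - 1L))
      qpos <- c(qpos, qcur:(qcur + l - 1L))
      op_out <- c(op_out, rep("M", l))
      rcur <- rcur + l
      qcur <- qcur + l
    } else if (o == "D") {
      ref_pos <- c(ref_pos, rcur:(rcur + l - 1L))
      qpos <- c(qpos, rep(NA_integer_, l))
      op_out <- c(op_out, rep("D", l))
      rcur <- rcur + l
    } else if (o == "N") {
      rcur <- rcur + l
    } else if (o %in% c("I", "S")) {
      qcur <- qcur + l
    }
  }
  bases <- rep(NA_character_, length(ref_pos))
  qvs <- rep(NA_integer_, length(ref_pos))
  has_q <- !is.na(qpos)
  if (any(has_q)) {
    sc <- s2c(seq)
    bases[has_q] <- sc[qpos[has_q]]
    if (!is.null(qual)) qvs[has_q] <- char_to_qv(qual)[qpos[has_q]]
  }
  data.table::data.table(ref_pos = ref_pos, qpos = qpos, op = op_out,
                         base = bases, qv = qvs)
}

# Reference intervals skipped by N operations (introns) for one read.
cigar_introns <- function(cigar, start) {
  cg <- parse_cigar(cigar)
  out_s <- integer(0); out_e <- integer(0)
  rcur <- start
  for (i in seq_along(cg$op)) {
    l <- cg$len[i]; o <- cg$op[i]
    if (o %in% c("M", "D", "=", "X")) {
      rcur <- rcur + l
    } else if (o == "N") {
      out_s <- c(out_s, rcur)
      out_e <- c(out_e, rcur + l - 1L)
      rcur <- rcur + l
    }
  }
  data.table::data.table(intron_start = out_s, intron_end = out_e)
}

reference_end <- function(cigar, start) {
  cg <- parse_cigar(cigar)
  start + sum(cg$len[cg$op %in% c("M", "D", "N", "=", "X")]) - 1L
}

mean_read_qv <- function(qual) mean(char_to_qv(qual))

## ---- intervals -------------------------------------------------------------

interval_union_width <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = starts, end = ends))
  sum(IRanges::width(ir))
}

in_interval <- function(pos, interval) {
  pos >= interval[1] & pos <= interval[2]
}
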