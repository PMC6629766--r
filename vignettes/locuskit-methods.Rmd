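---
title: "locuskit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{locuskit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package does

`locuskit` is a desk-scale implementation of a targeted long-read analysis
of a single gene locus. The scientific setting it models is a disease gene —
a large (~114 kb) locus with six exons on the minus strand, heavy alternative
5' start usage, variable 3' UTR lengths between 0.3 and 2.6 kb, exon-3 and
exon-5 skipping isoforms, a polymorphic CT-rich low-complexity region, and a
TTG triplet repeat in a large intron — sequenced with high-accuracy long
reads after targeted capture of both genomic DNA and full-length cDNA from a
cohort of 12 brain samples (4 Parkinson's disease, 4 Dementia with Lewy
bodies, 4 controls).

Real capture datasets of this kind are multi-gigabyte deposits. The package
therefore ships a synthetic-locus simulator with complete ground truth, and
every analysis stage is specified, implemented and tested against that
truth. The simulator is first-class code, not a test fixture: its defaults
*are* the study conditions (12 samples, ~6 kb sheared gDNA fragments,
per-sample unique coverage drawn from 16–71x, PCR duplicate fraction 0.3,
2,000 full-length cDNA reads per sample, ~1.1% per-base error split between
substitutions and indels, which matches a mean read accuracy near 98.9%).

# Pipeline model, stage by stage

## Simulation

The locus builder plants a deterministic gene geometry into a random
reference: six exons whose splice motifs are written into the sequence
(GT-AG at four introns, GC-AG at one, strand-aware), a coding sequence of
141 codons assembled from non-stop codons so the canonical protein length
is exact, an alternative first exon inside intron 1, four 3' UTR end
options, and — inside the dominant intron 4 — the CT-rich region (four
catalog haplotypes), the (TTG)~16~ repeat, a novel start exon and a novel
last exon, each with canonical motifs, plus one deliberately broken
junction boundary used by a decoy isoform.

Exon 3 and exon 5 are wholly coding, codon-aligned, and multiples of three
bases, so skipping either preserves the reading frame; this is the property
the ORF classifier must recover.

Reads are emitted *pre-aligned*: the simulator composes each read from a
haplotype-to-reference alignment (SNPs, indels, and block replacements for
the repeat regions) and applies sequencing errors on top, so the CIGAR
strings are exact and no aligner is involved. This isolates the downstream
logic under test from alignment behaviour. Two guarantees matter downstream
and are enforced by construction: errors are never applied to the first or
last aligned base (so PCR copies always share mapping endpoints), and
splice junctions of cDNA reads are never moved (errors land inside exons).

Quality values encode truth: correct bases draw QV uniformly from 30–93,
erroneous bases from 3–20. The QV 13 threshold used by both pileup stages
therefore removes roughly half of the error bases while keeping every
correct base — the filter is exercised meaningfully rather than trivially.

## Duplicate marking

PCR duplicates are identified by exact mapping endpoints within
(sample, contig, start, end, strand). The representative kept per group is
the read with the highest mean QV, ties broken by read id — the convention
is arbitrary but must be deterministic for reproducibility. Exact endpoint
matching (no fuzzy window) is a deliberate choice; the simulator guarantees
copies share endpoints, and on real data the same convention is the common
default for amplicon-style duplicates.

## Short-variant genotyping and phasing

The genotyper is a transparent allele-fraction caller over the QV-filtered
pileup: at depth >= 10, alt fraction f < 0.2 is homozygous reference,
0.2 <= f <= 0.8 heterozygous, f > 0.8 homozygous alternative. Indels are
genotyped from alignment gaps by the same fractions. These thresholds are
standard practice for high-accuracy long reads and are configurable; no
local reassembly is attempted. The STR and CT-rich intervals (plus 50-base
flanks) are masked — fraction genotyping is unreliable there, which is
exactly why the repeat haplotyper exists.

The phase-consistency filter automates a manual review step: for every pair
of heterozygous sites co-covered by at least 8 reads, the two consistent
diploid configurations should absorb at least 80% of co-covering reads; a
het call for which *every* available partner leaves more than 20% of reads
in minority configurations is flagged and its genotype set missing. The
8-read / 20% thresholds were chosen once for desk-scale statistical power
(at 8 reads, a true 50/50 artifact is flagged with high probability while a
real pair is essentially never flagged at error rates ~1%).

Read-backed phasing builds a graph over passing het sites, one edge per
informatively co-covered pair, oriented cis or trans by read majority and
weighted by the majority margin; tied edges are removed, haplotypes are
propagated over a maximum spanning tree, and components with at least two
sites become phase blocks. This is a deliberately simple propagation scheme
rather than an optimal error-correction phaser: at coverage 40x with ~1
het site per 1.5 kb and 6 kb reads, edge majorities are so strong that
switch errors do not occur in practice, which the tests assert exactly.

## Repeat-region haplotyping

Subsequences of reads fully spanning a region (with 20 anchored flank
bases) are extracted between aligned flank anchors, clustered first by
length (single linkage, gap tolerance 2 bases) and then by sequence
similarity within a size bin (single linkage on edit distance at 5% of the
mean length), and each cluster of at least 3 reads gets a consensus by star
alignment to the member closest to the median length with per-column
majority voting (ties keep the anchor base; insertions only when a majority
of members share one). The size tolerance and 5% threshold were set so that
one repeat unit (3 bases) always separates clusters while ~1% sequencing
error never splits one; a multiple-aligner consensus was intentionally
replaced by star alignment, which is adequate at CCS-level accuracy and
removes an external binary.

Unit counts are the longest run of consecutive exact unit copies
(interrupted repeats count their longest run), checked against a
brute-force scan in the tests. Samples with more than two surviving
clusters keep the two best-supported and are flagged rather than resolved
by guesswork; samples with no surviving cluster are reported unresolved.

## Isoform analysis

Full-length reads collapse by identical ordered junction chains; within a
chain, 5' ends cluster with 50-base tolerance and 3' ends with 100-base
tolerance (mode-seeded greedy assignment), so the planted UTR classes
(>= 300 bases apart) can never merge while alignment jitter is absorbed.
Retained isoforms must have only GT-AG / GC-AG junction motifs (checked
directly against the reference, strand-aware) and at least 20 supporting
full-length reads in total. A genomic polyA check (>= 12 A in the 20 bases
downstream of the 3' end on the transcribed strand) stands in for the
usual intra-priming artifact screens.

Splice classes use five labels with precedence Skip3 > Skip5 > Alt5 > Alt3
> AllExons. "Skipped" requires the missing exon to be flanked by isoform
exons on both transcript sides, so an isoform starting at the novel
intron-4 start site is Alt5 (novel 5' usage), not Skip3 — the grouping of
novel intron-internal starts under Alt5 is an interpretation, made once and
flagged here. Abundance is the percentage of each sample's retained
full-length reads ("normalized" counts are per-sample percentages; no
cross-sample library-size correction is applied beyond that).

Junction validation labels a junction supported at >= 10 short reads from
the support table and confirms an isoform when all of its unannotated
junctions are supported. ORF prediction translates from the annotated start
codon when present (longest-ORF fallback otherwise): canonical when the
protein matches the annotated 141 aa; frame_maintained_shorter when shorter
but terminating at the annotated stop codon (the exon-skipping cases);
truncated when the stop is premature or lost; none below 50 codons.

## Isoform-level SNP calling

Only reads assigned to retained isoforms are piled up; bases below QV 13
are excluded; insertions and deletions never count. Positions with pooled
filtered coverage >= 40 are tested — their number is the Bonferroni divisor
— with a one-sided Fisher exact test of the observed (alt, ref) counts
against expected error counts `[round(e x cov), cov - round(e x cov)]` at an
assumed error rate e = 0.005, cutoff 0.01 after correction. The exact
contingency-table construction is one of several defensible choices; it is
isolated in one function (`fisher_snp_p()`) so alternatives, e.g. per-QV
expected errors, can swap in. One-sided was
chosen because depletion of the alternative allele below the error rate is
not a signal of interest. Substitution candidates inside or within 1 base
of a reference homopolymer run (>= 4 identical bases) are suppressed.
Genotyping is the 5+/5+ full-length read rule, a total function over count
pairs, and SNPs are linked to the isoforms whose exons cover them —
reproducing the situation where a long-3'-UTR SNP is visible only to
long-UTR isoforms and two first-exon SNPs sit on mutually exclusive exons.

# What the simulator does and does not emulate

Emulated: targeted capture geometry (fragment sizes, per-sample coverage
spread, an optional probe-dropout interval), PCR duplication, QV-stratified
errors, diploid variant structure with population frequencies, repeat-region
length and composition polymorphism, a realistic isoform mix (a dominant
all-exon isoform near 55%, class mix AllExons 0.96 / Skip5 0.02 / Alt5 0.01
/ Skip3 0.005 / Alt3 0.005), and decoy isoforms for the filters.

Not emulated: alignment ambiguity and soft clipping, chimeric and
barcode-hopping artifacts, context-dependent (homopolymer-length) errors,
capture-efficiency gradients, RNA degradation and internal priming beyond
the single genomic polyA decoy mechanism, and expression differences
between conditions (all samples share one isoform mix). Passing tests
therefore demonstrate the correctness of the analysis logic under the
stated error model, not robustness to every artifact of real capture data.

# Numerical and scale choices

Per-sample full-length read depth is a free parameter of the study design;
2,000 reads per sample was chosen once as a desk-scale default that
gives the rare planted classes (0.25–0.5%) comfortably more than the
20-read retention threshold across 12 samples. Test and acceptance runs use
the full 114 kb locus with 12 samples for the end-to-end checks and a 30 kb
locus with 2 samples for module-level checks; the type-I-error check uses
10 replicates of 1,000 null positions at coverage 100. All randomness is
seed-derived; identical seeds give byte-identical outputs, including the
SAM/VCF/GFF3/TSV files (no timestamps are written).

Known limitations: the genotyper does not realign indels, so indel calls at
repeat boundaries inherit the simulator's left-anchored placement; the
phaser is not MEC-optimal and relies on strong edge majorities; consensus
insertions relative to the anchor require a strict majority, so very
low-coverage clusters can shorten alleles by a base; and the CT-rich
catalog labelling assumes the four catalog haplotypes are the only alleles
present, as in the emulated cohort.
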