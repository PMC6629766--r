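#!/usr/bin/env Rscript
# Stage 2 — mark PCR duplicates by mapping endpoints and summarise unique
# coverage per sample. Duplicates share (sample, contig, start, end, strand);
# the highest-mean-QV read of each group is kept.
#
# Reads results/run/gdna.sam; writes gdna.dedup.sam and coverage_summary.tsv.

library(locuskit)

cfg <- run_config(seed = 1L, out_dir = "results/run")
art <- run_pipeline(cfg, stages = "dedup")

cat(sprintf("flagged %d of %d reads as duplicates (%.1f%%)\n",
            sum(art$deduped$is_duplicate), nrow(art$deduped),
            100 * mean(art$deduped$is_duplicate)))
cat("unique coverage per sample:\n")
print(art$coverage)
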