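#!/usr/bin/env Rscript
# Stage 4 — resolve the two repeat regions the pileup genotyper masks:
# extract read subsequences spanning each region, cluster by size then
# sequence similarity, build per-cluster consensus sequences, and genotype
# each sample (TTG unit counts; CT-rich catalog haplotypes).
#
# Writes str_genotypes.tsv, ct_genotypes.tsv and table1_str_genotypes.tsv.

library(locuskit)

cfg <- run_config(seed = 1L, out_dir = "results/run")
art <- run_pipeline(cfg, stages = "str")

cat("TTG repeat genotypes:\n")
print(art$str_gt[, .(sample_id, allele1, allele2, support1, support2)])
cat("CT-rich region haplotypes:\n")
print(art$ct_gt[, .(sample_id, allele1, allele2, support1, support2)])
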