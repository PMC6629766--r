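#!/usr/bin/env Rscript
# Stage 7 — aggregate the run: stage counts and the three table-shaped
# reports, written as run_summary.json alongside the per-stage TSVs.

library(locuskit)

cfg <- run_config(seed = 1L, out_dir = "results/run")
art <- run_pipeline(cfg)   # all stages, deterministic re-run

cat("run summary:\n")
str(art$summary)
cat("\nreport files under", cfg$out_dir, ":\n")
print(list.files(cfg$out_dir))
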