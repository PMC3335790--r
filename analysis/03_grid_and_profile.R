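#!/usr/bin/env Rscript
# Run the full pipeline on the kept chains: superpose everything onto
# one reference, build the receptor-pair averaged RMSD/identity grid,
# and the per-position averaged deviation profile.

suppressPackageStartupMessages(library(tmbundle))
src <- "results/synthetic_census"

res <- run_pipeline(list(
  structure_dir = src,
  ledger = file.path(src, "ledger_kept.tsv"),
  map_dir = file.path(src, "maps"),
  reference = read.delim(file.path(src, "ledger_kept.tsv"))$entry_id[1L],
  method = "ssm",
  output_dir = "results/pipeline",
  seed = 1L
))

grid <- res$grid
self <- grid$receptor_a == grid$receptor_b
cat(sprintf("receptor-pair groups: %d (%d self, %d cross)\n",
            nrow(grid), sum(self), sum(!self)))
cat(sprintf("chain pairs averaged: %d\n", sum(grid$n)))
cat(sprintf("self-pair mean rmsd: %.2f A (noise floor); cross-pair mean: %.2f A\n",
            mean(grid$mean[self]), mean(grid$mean[!self])))
cat(sprintf("profile: mean deviation %.2f A, max %.2f A\n",
            mean(res$profile$mean_dev), max(res$profile$mean_dev)))
cat("tables under results/pipeline/\n")
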