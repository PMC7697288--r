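#!/usr/bin/env Rscript
# Generate the synthetic reprogramming experiment used by the downstream
# analysis steps: a four-condition design (start fibroblast-like cells,
# vector controls, reprogramming intermediates, target pluripotent-like
# cells) with planted sub-reprogramome classes and per-gene reprogramming
# completeness, written as plain TSV alongside the ground truth.

suppressPackageStartupMessages(library(reprolegit))

out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20201115

cfg <- simulation_config()  # the default emulated design
sim <- simulate_experiment(cfg, seed = seed)

counts <- sim$counts
write.table(data.frame(gene = rownames(counts$counts), counts$counts,
                       check.names = FALSE),
            file.path(out_dir, "counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(counts$metadata, file.path(out_dir, "metadata.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth, file.path(out_dir, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Simulated %d genes x %d samples (seed %d)\n",
            nrow(counts$counts), ncol(counts$counts), seed))
print(table(planted_class = sim$truth$class))
print(table(planted_category = sim$truth$category))
cat("wrote counts.tsv, metadata.tsv, truth.tsv under", out_dir, "\n")
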