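#!/usr/bin/env Rscript
# Generate the synthetic study dataset: a 757-gene neuroinflammation-style
# panel with housekeeping / positive / negative control probes, one pooled
# sham group and vehicle- / inhibitor-treated injured arms at days 3, 7 and
# 28 (n = 3 per group), with planted temporal archetypes, treatment
# modifiers and ground-truth labels.

library(tempodeg)

seed <- 42
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config()
sim <- simulate_panel(cfg, seed = seed)

write_count_table(sim$counts, file.path(out, "counts.csv"))
write.csv(sim$samples, file.path(out, "samples.csv"), row.names = FALSE)
write_result_table(sim$truth, file.path(out, "truth.csv"))

ann <- sim$annotations
ann$pathways <- vapply(ann$pathways, paste, character(1), collapse = ";")
ann$marker_classes <- vapply(ann$marker_classes, paste, character(1), collapse = ";")
write.csv(ann, file.path(out, "annotations.csv"), row.names = FALSE)

message(sprintf("simulated %d genes x %d samples (seed %d)",
                length(sim$counts$gene_ids), length(sim$counts$sample_ids), seed))
message(sprintf("planted: %d genes with injury effects, %d with treatment modifiers",
                sum(sim$truth$expected_pattern != "none"),
                sum(sim$truth$modifier != "none")))
message("wrote counts, samples, truth and annotations under ", out)
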