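#!/usr/bin/env Rscript
# Per-timepoint differential expression against the pooled sham group, for
# both injured arms: Welch t on log2 normalized counts, signed fold change,
# BH FDR across the panel per contrast, no fold-change cutoff. Also ranks
# the complement genes by baseline expression in sham brains.

library(tempodeg)

norm_df <- read.csv("results/norm/normalized.csv", check.names = FALSE)
norm <- as.matrix(norm_df[, -1])
rownames(norm) <- norm_df$gene_id
counts <- read_count_table("results/sim/counts.csv")
samples <- read_sample_sheet("results/sim/samples.csv")
endo <- counts$gene_ids[counts$code_class == "Endogenous"]
out <- "results/de"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sham <- select_samples(samples, group = "sham", timepoint = "baseline")
for (arm in c("vehicle", "CR2-Crry")) {
  tag <- if (arm == "vehicle") "vehicle" else "treated"
  for (tp in c("d3", "d7", "d28")) {
    grp <- select_samples(samples, group = "TBI", treatment = arm, timepoint = tp)
    res <- compare_groups(norm[endo, ], grp, sham, fdr_mode = "standard")
    write_result_table(res, file.path(out, sprintf("de_%s_%s.csv", tag, tp)))
    message(sprintf("%s %s vs sham: %d up, %d down (FDR < 0.05)",
                    tag, tp, sum(res$direction == "up"),
                    sum(res$direction == "down")))
  }
}

# baseline complement expression in the uninjured brain
comp <- complement_annotations()
present <- intersect(comp$gene_id, endo)
rank <- baseline_expression_ranking(norm, sham, genes = present,
                                    annotations = comp)
write.csv(rank, file.path(out, "baseline_complement_ranking.csv"),
          row.names = FALSE)
message(sprintf("baseline complement ranking: %s most expressed (%.0f mean counts)",
                rank$gene_id[1], rank$mean_count[1]))
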