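#!/usr/bin/env Rscript
# Effect of complement inhibition on each gene's trajectory: treated-arm DE
# sets, pattern-effect categories (inhibited / induced / shortened /
# extended / shifted / unchanged), per-timepoint level tests with
# conditional FDR, marker-class report, and a PCA embedding of all samples.

library(tempodeg)

norm_df <- read.csv("results/norm/normalized.csv", check.names = FALSE)
norm <- as.matrix(norm_df[, -1]); rownames(norm) <- norm_df$gene_id
counts <- read_count_table("results/sim/counts.csv")
samples <- read_sample_sheet("results/sim/samples.csv")
endo <- counts$gene_ids[counts$code_class == "Endogenous"]
out <- "results/treatment"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tps <- c("d3", "d7", "d28")
read_de <- function(tag, tp) {
  contrast_results_from_comparison(
    read_comparison_table(sprintf("results/de/de_%s_%s.csv", tag, tp),
                          columns = c(gene = "gene_id", fc = "fc_signed",
                                      p = "p_value")),
    fdr_mode = "standard")
}
veh_sets <- de_timepoint_sets(lapply(setNames(tps, tps), read_de, tag = "vehicle"))
trt_sets <- de_timepoint_sets(lapply(setNames(tps, tps), read_de, tag = "treated"))

level_tests <- do.call(rbind, lapply(tps, function(tp) {
  level_effect_tests(norm[endo, ], samples, tp)
}))
write_result_table(level_tests, file.path(out, "level_tests.csv"))

treat <- summarize_treatment_effects(veh_sets$profiles, trt_sets$profiles,
                                     level_tests)
write_result_table(treat$records, file.path(out, "treatment_records.csv"))
write.csv(treat$category_counts, file.path(out, "category_counts.csv"),
          row.names = FALSE)

message("treatment-effect categories:")
for (i in seq_len(nrow(treat$category_counts))) {
  message(sprintf("  %-10s %d", treat$category_counts$pattern_effect[i],
                  treat$category_counts$n[i]))
}
r7 <- treat$reduced_among_up[treat$reduced_among_up$timepoint == "d7", ]
message(sprintf("genes remaining upregulated at d7 with reduced level: %d of %d",
                r7$n_reduced_among_up, r7$n_remained_up))
cu <- veh_sets$profiles$gene_id[veh_sets$profiles$pattern_label == "consistent_up"]
message(sprintf("consistently upregulated genes unaffected by inhibition: %d",
                length(intersect(cu, treat$unaffected_genes))))

markers <- marker_report(level_tests, panel_genes = endo)
write.csv(markers, file.path(out, "marker_report.csv"), row.names = FALSE)
for (cls in c("A1", "A2")) {
  row <- markers[markers$marker_class == cls, ]
  message(sprintf("%s markers reduced under inhibition: %d of %d (%s)",
                  cls, row$n_reduced, row$n_on_panel, row$reduced_genes))
}

pca <- pca_embedding(norm[endo, ], n_components = 2)
coords <- merge(pca$coordinates, samples, by = "sample_id")
write.csv(coords, file.path(out, "pca_coordinates.csv"), row.names = FALSE)
message(sprintf("PCA: PC1 %.0f%%, PC2 %.0f%% of variance",
                100 * pca$explained_variance[1], 100 * pca$explained_variance[2]))
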