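#!/usr/bin/env Rscript
# Temporal classification of the vehicle-arm DEGs: per-gene DE time-point
# sets with canonical pattern labels, and the peak-change analysis
# (pairwise injured-vs-injured contrasts with conditional FDR).

library(tempodeg)

norm_df <- read.csv("results/norm/normalized.csv", check.names = FALSE)
norm <- as.matrix(norm_df[, -1]); rownames(norm) <- norm_df$gene_id
counts <- read_count_table("results/sim/counts.csv")
samples <- read_sample_sheet("results/sim/samples.csv")
endo <- counts$gene_ids[counts$code_class == "Endogenous"]
out <- "results/temporal"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tps <- c("d3", "d7", "d28")
read_de <- function(tag, tp) {
  contrast_results_from_comparison(
    read_comparison_table(sprintf("results/de/de_%s_%s.csv", tag, tp),
                          columns = c(gene = "gene_id", fc = "fc_signed",
                                      p = "p_value")),
    fdr_mode = "standard")
}
veh <- lapply(setNames(tps, tps), read_de, tag = "vehicle")
sets <- de_timepoint_sets(veh)
write_result_table(sets$profiles, file.path(out, "profiles_vehicle.csv"))
write.csv(sets$counts, file.path(out, "deg_counts_vehicle.csv"), row.names = FALSE)

tally <- sort(table(sets$profiles$pattern_label), decreasing = TRUE)
message("vehicle-arm pattern tally:")
for (nm in names(tally)) message(sprintf("  %-22s %d", nm, tally[[nm]]))

peaks <- peak_change_analysis(norm[endo, ], samples, sets$profiles)
write_result_table(peaks, file.path(out, "peak_sets.csv"))
peak_str <- vapply(peaks$peak_set, paste, character(1), collapse = "+")
cu <- sets$profiles$pattern_label == "consistent_up"
message(sprintf("consistently upregulated genes peaking at d3+d7: %d",
                sum(cu & peak_str == "d3+d7")))
message(sprintf("consistently upregulated genes peaking at d7+d28: %d (%s)",
                sum(cu & peak_str == "d7+d28"),
                paste(sets$profiles$gene_id[cu & peak_str == "d7+d28"],
                      collapse = ", ")))
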