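#!/usr/bin/env Rscript
# Pathway-level view: median signed fold change and DEG counts per panel
# pathway and time point, and a hypergeometric over-representation analysis
# of the consistently upregulated unaffected genes against pathway gene
# sets derived from the annotation table (in GMT form).

library(tempodeg)

samples <- read_sample_sheet("results/sim/samples.csv")
ann_df <- read_gene_annotations("results/sim/annotations.csv")
out <- "results/pathways"
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
labels <- data.frame(gene_id = sets$profiles$gene_id,
                     label = sets$profiles$pattern_label)

ps <- pathway_deg_summary(veh, ann_df, labels = labels)
write.csv(ps$summary, file.path(out, "pathway_summary.csv"), row.names = FALSE)
write.csv(ps$label_counts, file.path(out, "pathway_pattern_counts.csv"),
          row.names = FALSE)

d7 <- ps$summary[ps$summary$timepoint == "d7" & ps$summary$n_up > 0, ]
top <- d7[order(-d7$median_fc_up), ][1, ]
message(sprintf("highest median upregulation at d7: %s (median FC %.1f, %d DEGs)",
                top$pathway, top$median_fc_up, top$n_up))

# write the annotation pathways as GMT and test the consistently
# upregulated genes for over-representation
long <- annotation_pathway_long(ann_df)
gmt_path <- file.path(out, "panel_pathways.gmt")
by_pw <- split(long$gene_id, long$pathway)
writeLines(vapply(names(by_pw), function(nm) {
  paste(c(nm, "panel annotation", unique(by_pw[[nm]])), collapse = "\t")
}, character(1)), gmt_path)
gene_sets <- read_gmt(gmt_path)

selected <- sets$profiles$gene_id[sets$profiles$pattern_label == "consistent_up"]
universe <- sets$profiles$gene_id
ora <- ora_hypergeometric(selected, universe, gene_sets)
write.csv(ora, file.path(out, "ora_consistent_up.csv"), row.names = FALSE)
sig <- ora[ora$significant, ]
message(sprintf("ORA of %d consistently upregulated genes: %d significant set(s)%s",
                length(selected), nrow(sig),
                if (nrow(sig)) paste0(" (top: ", sig$set_name[1], ")") else ""))
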