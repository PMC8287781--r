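#' Pathway-level DEG summaries
#'
#' For each pathway and time point: the median signed fold change over
#' upregulated DEGs and over downregulated DEGs (medians are computed only
#' over DEGs; a pathway with no DEGs reports counts of 0 and no median),
#' plus DEG counts. A gene annotated to k pathways contributes to all k.
#' When `labels` is supplied (e.g. temporal pattern labels or
#' treatment-effect categories per gene), per-label DEG counts are also
#' tallied per pathway.
#'
#' @param results named list of contrast result data frames by time point
#'   (as from [compare_groups()])
#' @param annotations annotation data frame with a `pathways` list-column
#'   (see [read_gene_annotations()]) or a long data frame with columns
#'   `gene_id`, `pathway`
#' @param labels optional data frame with columns `gene_id`, `label`
#' @return list with `summary` (pathway x timepoint rows: `n_up`, `n_down`,
#'   `median_fc_up`, `median_fc_down`) and `label_counts` (pathway, label,
#'   n; NULL when `labels` is missing)
#' @export
pathway_deg_summary <- function(results, annotations, labels = NULL) {
  long <- if (!is.null(annotations$pathways)) {
    annotation_pathway_long(annotations)
  } else if (all(c("gene_id", "pathway") %in% names(annotations))) {
    annotations
  } else stop("`annotations` must carry gene-to-pathway memberships")
  pathways <- sort(unique(long$pathway))
  rows <- list()
  for (tp in names(results)) {
    r <- results[[tp]]
    de <- r[r$de_flag, c("gene_id", "fc_signed", "direction")]
    for (pw in pathways) {
      members <- long$gene_id[long$pathway == pw]
      d <- de[de$gene_id %in% members, ]
      up <- d$fc_signed[d$direction == "up"]
      dn <- d$fc_signed[d$direction == "down"]
      rows[[length(rows) + 1]] <- data.frame(
        pathway = pw, timepoint = tp,
        n_up = length(up), n_down = length(dn),
        median_fc_up = if (length(up)) stats::median(up) else NA_real_,
        median_fc_down = if (length(dn)) stats::median(dn) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  summary <- do.call(rbind, rows)
  label_counts <- NULL
  if (!is.null(labels)) {
    de_any <- unique(unlist(lapply(results, function(r) r$gene_id[r$de_flag])))
    lab <- stats::setNames(labels$label, labels$gene_id)
    lc <- list()
    for (pw in pathways) {
      members <- intersect(long$gene_id[long$pathway == pw], de_any)
      if (length(members) == 0) next
      tab <- table(lab[members], useNA = "no")
      lc[[pw]] <- data.frame(pathway = pw, label = names(tab),
                             n = as.integer(tab), stringsAsFactors = FALSE)
    }
    label_counts <- if (length(lc)) do.call(rbind, c(lc, make.row.names = FALSE)) else
      data.frame(pathway = character(0), label = character(0), n = integer(0))
  }
  list(summary = summary, label_counts = label_counts)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each gene set against a selected gene
#' list within a universe: with N = |universe|, K = |set within universe|,
#' n = |selected| and k = |overlap|, p = P(X >= k) for X ~
#' Hypergeometric(N, K, n). Sets are intersected with the universe before
#' testing; p-values are BH-adjusted across sets and results sorted by p.
#'
#' @param selected character vector of selected genes (must lie within
#'   `universe`)
#' @param universe character vector defining the background
#' @param gene_sets named list of character vectors (e.g. [read_gmt()])
#' @param alpha significance threshold recorded in the `significant` column
#' @return data frame: `set_name`, `universe_size`, `set_size`,
#'   `n_selected`, `overlap`, `p_value`, `fdr`, `significant`
#' @export
ora_hypergeometric <- function(selected, universe, gene_sets, alpha = 0.05) {
  selected <- unique(selected); universe <- unique(universe)
  outside <- setdiff(selected, universe)
  if (length(outside)) {
    stop("selected gene(s) outside the universe: ", paste(outside, collapse = ", "))
  }
  N <- length(universe); n <- length(selected)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(set, selected))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, universe_size = N, set_size = K,
               n_selected = n, overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$set_name), ]
  out$significant <- out$fdr < alpha
  rownames(out) <- NULL
  out
}

#' Marker-class report of treatment level effects
#'
#' For each marker class (A1, A2, PAN-reactive, DAM, reactive
#' oligodendrocyte, ...): how many marker genes are on the analyzed panel,
#' how many show a reduced level under treatment at any time point, and the
#' gene names. Marker genes absent from the panel are tallied, not errors.
#'
#' @param level_tests data frame of [level_effect_tests()] results (any
#'   number of time points row-bound)
#' @param markers data frame with columns `gene_id`, `marker_class`
#'   (default: the packaged fixture, [marker_classes()])
#' @param panel_genes character vector of genes analyzed
#' @return data frame: `marker_class`, `n_total`, `n_on_panel`,
#'   `n_absent`, `n_reduced`, `reduced_genes`
#' @export
marker_report <- function(level_tests, markers = marker_classes(), panel_genes) {
  reduced <- unique(level_tests$gene_id[level_tests$level_effect == "reduced"])
  out <- lapply(split(markers$gene_id, markers$marker_class), function(g) {
    g <- unique(g)
    on_panel <- intersect(g, panel_genes)
    red <- intersect(on_panel, reduced)
    data.frame(n_total = length(g), n_on_panel = length(on_panel),
               n_absent = length(g) - length(on_panel),
               n_reduced = length(red),
               reduced_genes = paste(sort(red), collapse = "+"),
               stringsAsFactors = FALSE)
  })
  cbind(data.frame(marker_class = names(out), stringsAsFactors = FALSE),
        do.call(rbind, c(out, make.row.names = FALSE)))
}
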