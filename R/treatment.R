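#' Categorize a treatment's effect on a gene's DE trajectory
#'
#' Set algebra over the vehicle-arm (`V`) and treated-arm (`C`) DE
#' time-point sets:
#' \itemize{
#'   \item `unchanged`: C = V (including both empty)
#'   \item `inhibited`: V non-empty, C empty
#'   \item `induced`: V empty, C non-empty
#'   \item `shortened`: C a non-empty proper subset of V
#'   \item `extended`: V a non-empty proper subset of C
#'   \item `shifted`: each arm has time points the other lacks
#' }
#' The six categories are mutually exclusive and cover every (V, C) pair.
#'
#' @param V,C character vectors of time points
#' @return category string
#' @export
pattern_effect_category <- function(V, C) {
  V <- unique(as.character(V)); C <- unique(as.character(C))
  if (setequal(V, C)) return("unchanged")
  if (length(C) == 0) return("inhibited")
  if (length(V) == 0) return("induced")
  only_v <- length(setdiff(V, C)) > 0
  only_c <- length(setdiff(C, V)) > 0
  if (only_v && !only_c) return("shortened")
  if (only_c && !only_v) return("extended")
  "shifted"
}

#' Treated-vs-vehicle level-effect tests at one time point
#'
#' Per-gene contrast of the treated arm against the vehicle arm at a single
#' time point, with conditional FDR by default (a between-injured-group
#' comparison). A gene's level effect is `reduced` when significant with a
#' lower treated mean, `increased` when higher, `none` otherwise.
#'
#' @param norm normalized matrix
#' @param samples sample sheet data frame
#' @param timepoint the time point to test
#' @param group injured group label (default `"TBI"`)
#' @param treated,vehicle treatment labels of the two arms
#' @param fdr_mode,alpha,p_cutoff FDR settings
#' @return data frame `gene_id`, `timepoint`, `level_effect`, `log2fc`,
#'   `p_value`, `fdr`
#' @export
level_effect_tests <- function(norm, samples, timepoint, group = "TBI",
                               treated = "CR2-Crry", vehicle = "vehicle",
                               fdr_mode = "conditional", alpha = 0.05,
                               p_cutoff = 0.05) {
  st <- select_samples(samples, group = group, treatment = treated, timepoint = timepoint)
  sv <- select_samples(samples, group = group, treatment = vehicle, timepoint = timepoint)
  if (length(st) < 2 || length(sv) < 2) {
    stop(sprintf("need >= 2 treated and >= 2 vehicle samples at %s", timepoint))
  }
  res <- compare_groups(norm, st, sv, fdr_mode = fdr_mode, alpha = alpha,
                        p_cutoff = p_cutoff)
  level_effects_from_contrast(res, timepoint)
}

#' Level effects from an existing treated-vs-vehicle contrast
#'
#' Derives the per-gene level-effect labels from a contrast result computed
#' elsewhere (e.g. ingested via [contrast_results_from_comparison()]),
#' mirroring the labelling rule of [level_effect_tests()].
#'
#' @param res contrast result data frame (treated over vehicle)
#' @param timepoint label attached to the rows
#' @return data frame `gene_id`, `timepoint`, `level_effect`, `log2fc`,
#'   `p_value`, `fdr`
#' @export
level_effects_from_contrast <- function(res, timepoint) {
  data.frame(
    gene_id = res$gene_id,
    timepoint = timepoint,
    level_effect = ifelse(!res$de_flag, "none",
                          ifelse(res$log2fc < 0, "reduced", "increased")),
    log2fc = res$log2fc,
    p_value = res$p_value,
    fdr = res$fdr,
    stringsAsFactors = FALSE
  )
}

#' Per-gene treatment-effect records and marginal tallies
#'
#' Combines the vehicle-arm and treated-arm temporal profiles (from
#' [de_timepoint_sets()]) with per-timepoint level tests into one record
#' per gene: the pattern-effect category, per-timepoint level effects, and
#' whether the gene remained differentially upregulated under treatment.
#' The count of genes with reduced level among those remaining upregulated
#' is reported per time point; `remained_rule` selects whether "remaining
#' upregulated" requires the gene to be up in both arms (default) or in the
#' vehicle arm only.
#'
#' @param vehicle_profiles,treated_profiles `profiles` data frames sharing
#'   one gene universe
#' @param level_tests data frame row-binding [level_effect_tests()] results
#'   over time points (or NULL to skip level effects)
#' @param remained_rule `"both"` or `"vehicle"`
#' @return list with `records` (per-gene data frame), `category_counts`,
#'   `reduced_among_up` (per-timepoint counts), and `unaffected_genes`
#'   (unchanged pattern and no level effect at any time point)
#' @export
summarize_treatment_effects <- function(vehicle_profiles, treated_profiles,
                                        level_tests = NULL,
                                        remained_rule = c("both", "vehicle")) {
  remained_rule <- match.arg(remained_rule)
  genes <- vehicle_profiles$gene_id
  if (!identical(sort(genes), sort(treated_profiles$gene_id))) {
    stop("gene universes differ between arms")
  }
  tidx <- match(genes, treated_profiles$gene_id)
  V_up <- vehicle_profiles$de_up; V_down <- vehicle_profiles$de_down
  C_up <- treated_profiles$de_up[tidx]; C_down <- treated_profiles$de_down[tidx]
  V <- mapply(function(u, d) union(u, d), V_up, V_down, SIMPLIFY = FALSE)
  C <- mapply(function(u, d) union(u, d), C_up, C_down, SIMPLIFY = FALSE)
  records <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  records$vehicle_de <- V
  records$treated_de <- C
  records$pattern_effect <- mapply(pattern_effect_category, V, C)

  any_level <- rep(FALSE, length(genes))
  reduced_among_up <- NULL
  if (!is.null(level_tests)) {
    for (tp in unique(level_tests$timepoint)) {
      lt <- level_tests[level_tests$timepoint == tp, ]
      eff <- stats::setNames(lt$level_effect, lt$gene_id)[genes]
      eff[is.na(eff)] <- "none"
      records[[paste0("level_", tp)]] <- unname(eff)
      any_level <- any_level | eff != "none"
      up_v <- vapply(V_up, function(s) tp %in% s, logical(1))
      up_c <- vapply(C_up, function(s) tp %in% s, logical(1))
      remained <- if (remained_rule == "both") up_v & up_c else up_v
      records[[paste0("remained_up_", tp)]] <- remained
      reduced_among_up <- rbind(reduced_among_up, data.frame(
        timepoint = tp,
        n_remained_up = sum(remained),
        n_reduced_among_up = sum(remained & eff == "reduced"),
        stringsAsFactors = FALSE
      ))
    }
  }
  records$any_level_effect <- any_level
  records$affected <- records$pattern_effect != "unchanged" | any_level
  category_counts <- as.data.frame(table(pattern_effect = records$pattern_effect),
                                   stringsAsFactors = FALSE)
  names(category_counts)[2] <- "n"
  list(
    records = records,
    category_counts = category_counts,
    reduced_among_up = reduced_among_up,
    unaffected_genes = genes[!records$affected]
  )
}

#' PCA embedding of samples
#'
#' Principal components of the gene-centered log2 normalized matrix with
#' samples as observations (no unit-variance scaling: panel genes share a
#' scale after normalization). Component signs are fixed canonically by
#' flipping each loading vector so its largest-magnitude loading is
#' positive.
#'
#' @param norm normalized matrix (genes x samples), strictly positive
#' @param n_components number of components to return (default 2)
#' @return list with `coordinates` (data frame: `sample_id`, `PC1`, ...)
#'   and `explained_variance` (fractions, non-increasing)
#' @export
pca_embedding <- function(norm, n_components = 2) {
  if (ncol(norm) < 2) stop("PCA needs >= 2 samples")
  if (n_components > ncol(norm)) stop("more components than samples requested")
  x <- log2(norm)
  x <- x - rowMeans(x)            # center genes
  pc <- stats::prcomp(t(x), center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) {
      pc$rotation[, j] <- -load
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- data.frame(sample_id = colnames(norm), pc$x[, seq_len(k), drop = FALSE],
                       row.names = NULL, stringsAsFactors = FALSE)
  list(coordinates = coords, explained_variance = ev[seq_len(k)])
}
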