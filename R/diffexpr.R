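#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value, with explicit conventions for degenerate inputs: when
#' both groups have zero variance, identical means give p = 1 (t = 0) and
#' different means give p = 0 (t = +/-Inf, flagged with a warning).
#'
#' @param x,y numeric vectors (length >= 2 each) of log2 expression values
#' @return list with `t`, `df`, `p`
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  dm <- mean(x) - mean(y)
  if (se2 == 0) {
    if (dm == 0) return(list(t = 0, df = NA_real_, p = 1))
    warning("zero variance in both groups with unequal means; p = 0 limit")
    return(list(t = sign(dm) * Inf, df = NA_real_, p = 0))
  }
  tt <- dm / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Signed fold change from mean log2 values
#'
#' With r = 2^(mean_test - mean_ref), returns r when r >= 1 and -1/r
#' otherwise, so up- and down-regulation are symmetric around +/-1. A zero
#' difference returns +1.
#'
#' @param mean_log2_test,mean_log2_ref mean log2 expression per group
#'   (vectorized)
#' @return signed fold change(s) with absolute value >= 1
#' @export
signed_fold_change <- function(mean_log2_test, mean_log2_ref) {
  r <- 2^(mean_log2_test - mean_log2_ref)
  ifelse(r >= 1, r, -1 / r)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up BH across the whole input vector.
#'
#' @param p numeric vector of p-values in [0,1]
#' @return adjusted values in original order
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Conditional Benjamini-Hochberg adjustment
#'
#' Sensitivity-boosting FDR variant in which BH is applied only to the
#' genes with raw p below `p_cutoff`, with the family size equal to that
#' subset; everything outside the subset is assigned an adjusted value of 1
#' and can never be called differentially expressed. Used for the
#' complement-panel injury contrasts and for all between-injured-group
#' comparisons, where within-group variability after injury would otherwise
#' swamp the standard adjustment.
#'
#' @param p numeric vector of p-values in [0,1]
#' @param p_cutoff raw-p inclusion threshold (default 0.05)
#' @return adjusted values in original order
#' @export
conditional_bh_fdr <- function(p, p_cutoff = 0.05) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  out <- rep(1, length(p))
  idx <- which(p < p_cutoff)
  if (length(idx)) out[idx] <- stats::p.adjust(p[idx], method = "BH")
  out
}

#' Two-group differential expression on log2 normalized counts
#'
#' Per-gene Welch t-test on log2 normalized counts, signed fold change, and
#' FDR adjustment across all genes of the contrast (one family per
#' contrast). A gene is flagged differentially expressed when its adjusted
#' value is below `alpha`; no fold-change cutoff is applied.
#'
#' @param norm normalized count matrix (genes x samples), strictly positive
#' @param test_samples,ref_samples character vectors of sample ids (>= 2
#'   each); fold changes are test over reference
#' @param fdr_mode `"standard"` (BH across all genes) or `"conditional"`
#'   (see [conditional_bh_fdr()])
#' @param alpha DE call threshold on the adjusted value (default 0.05)
#' @param p_cutoff subset cutoff for the conditional mode
#' @param genes optional gene subset (default: all rows)
#' @return data frame with one row per gene: `gene_id`, `mean_log2_test`,
#'   `mean_log2_ref`, `log2fc`, `fc_signed`, `p_value`, `fdr`, `de_flag`,
#'   `direction`, `n_test`, `n_ref`
#' @export
compare_groups <- function(norm, test_samples, ref_samples,
                           fdr_mode = c("standard", "conditional"),
                           alpha = 0.05, p_cutoff = 0.05, genes = NULL) {
  fdr_mode <- match.arg(fdr_mode)
  if (length(test_samples) < 2 || length(ref_samples) < 2) {
    stop("each group needs >= 2 samples")
  }
  miss <- setdiff(c(test_samples, ref_samples), colnames(norm))
  if (length(miss)) stop("sample id(s) not in matrix: ", paste(miss, collapse = ", "))
  if (is.null(genes)) genes <- rownames(norm)
  lx <- log2(norm[genes, test_samples, drop = FALSE])
  ly <- log2(norm[genes, ref_samples, drop = FALSE])
  mt <- rowMeans(lx); mr <- rowMeans(ly)
  p <- vapply(seq_along(genes), function(i) {
    suppressWarnings(welch_t_test(lx[i, ], ly[i, ])$p)
  }, numeric(1))
  fdr <- if (fdr_mode == "standard") bh_fdr(p) else conditional_bh_fdr(p, p_cutoff)
  log2fc <- mt - mr
  de <- fdr < alpha
  data.frame(
    gene_id = genes,
    mean_log2_test = unname(mt),
    mean_log2_ref = unname(mr),
    log2fc = unname(log2fc),
    fc_signed = signed_fold_change(mt, mr),
    p_value = p,
    fdr = fdr,
    de_flag = de,
    direction = ifelse(!de, "none", ifelse(log2fc > 0, "up", "down")),
    n_test = length(test_samples),
    n_ref = length(ref_samples),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Contrast results from a precomputed comparison table
#'
#' Converts an ingested fold-change / p-value table (see
#' [read_comparison_table()]) into the same per-gene contrast-result layout
#' that [compare_groups()] produces, recomputing the FDR column with the
#' requested procedure (precomputed FDR values, when present, are ignored
#' in favour of a reproducible adjustment). This is the path for
#' re-deriving published DEG counts from shipped comparison tables without
#' access to the raw counts.
#'
#' @param comp data frame from [read_comparison_table()] (a single
#'   contrast)
#' @param fdr_mode,alpha,p_cutoff as in [compare_groups()]
#' @return data frame with `gene_id`, `log2fc`, `fc_signed`, `p_value`,
#'   `fdr`, `de_flag`, `direction`
#' @export
contrast_results_from_comparison <- function(comp, fdr_mode = c("standard", "conditional"),
                                             alpha = 0.05, p_cutoff = 0.05) {
  fdr_mode <- match.arg(fdr_mode)
  if (anyDuplicated(comp$gene_id)) {
    stop("comparison table contains duplicated gene ids; split by contrast first")
  }
  fdr <- if (fdr_mode == "standard") bh_fdr(comp$p_value) else
    conditional_bh_fdr(comp$p_value, p_cutoff)
  de <- fdr < alpha
  data.frame(
    gene_id = comp$gene_id,
    log2fc = comp$log2fc,
    fc_signed = comp$fc_signed,
    p_value = comp$p_value,
    fdr = fdr,
    de_flag = de,
    direction = ifelse(!de, "none", ifelse(comp$log2fc > 0, "up", "down")),
    stringsAsFactors = FALSE
  )
}

#' Rank genes by baseline expression
#'
#' Mean normalized count per gene over a set of baseline samples, sorted in
#' decreasing order; annotation columns (e.g. complement class/pathway) are
#' carried through when supplied. Ties are broken by gene id for a stable
#' order.
#'
#' @param norm normalized matrix
#' @param sample_ids baseline samples (>= 1)
#' @param genes gene subset (default: all rows); genes absent from the
#'   matrix raise an error
#' @param annotations optional data frame keyed by `gene_id` to merge in
#' @return data frame `gene_id`, `mean_count`, `rank`, plus annotation
#'   columns
#' @export
baseline_expression_ranking <- function(norm, sample_ids, genes = NULL,
                                        annotations = NULL) {
  if (length(sample_ids) < 1) stop("need at least one baseline sample")
  if (is.null(genes)) genes <- rownames(norm)
  if (length(genes) == 0) {
    return(data.frame(gene_id = character(0), mean_count = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  miss <- setdiff(genes, rownames(norm))
  if (length(miss)) stop("gene(s) not in matrix: ", paste(miss, collapse = ", "))
  mu <- rowMeans(norm[genes, sample_ids, drop = FALSE])
  ord <- order(-mu, genes)
  out <- data.frame(gene_id = genes[ord], mean_count = unname(mu[ord]),
                    rank = seq_along(genes), stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    out <- merge(out, annotations, by = "gene_id", all.x = TRUE, sort = FALSE)
    out <- out[order(out$rank), ]
    rownames(out) <- NULL
  }
  out
}

#' Relative expression by the 2^-dCT method
#'
#' @param ct_target,ct_reference threshold-cycle values (vectorized)
#' @return 2^-(ct_target - ct_reference)
#' @export
qpcr_relative_expression <- function(ct_target, ct_reference) {
  2^(-(ct_target - ct_reference))
}
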