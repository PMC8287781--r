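#' Canonical temporal pattern label
#'
#' Deterministic string describing the time points at which a gene is
#' differentially expressed: `"consistent_up"` / `"consistent_down"` when
#' every analyzed time point is DE in one direction, `"up:d3+d7"` style for
#' single-direction partial patterns, `"mixed:up@d3|down@d28"` for genes
#' changing direction across time points, and `"none"` for no DE.
#'
#' @param de_up,de_down character vectors of time points
#' @param timepoints all analyzed time points, in canonical order
#' @return label string
#' @export
pattern_label <- function(de_up, de_down, timepoints) {
  de_up <- intersect(timepoints, de_up)
  de_down <- intersect(timepoints, de_down)
  if (length(de_up) == 0 && length(de_down) == 0) return("none")
  if (length(de_down) == 0) {
    if (setequal(de_up, timepoints)) return("consistent_up")
    return(paste0("up:", paste(de_up, collapse = "+")))
  }
  if (length(de_up) == 0) {
    if (setequal(de_down, timepoints)) return("consistent_down")
    return(paste0("down:", paste(de_down, collapse = "+")))
  }
  parts <- character(0)
  for (tp in timepoints) {
    if (tp %in% de_up) parts <- c(parts, paste0("up@", tp))
    else if (tp %in% de_down) parts <- c(parts, paste0("down@", tp))
  }
  paste0("mixed:", paste(parts, collapse = "|"))
}

#' Per-gene DE time-point sets and per-timepoint counts
#'
#' Collates a set of per-timepoint contrast results (one
#' [compare_groups()] data frame per time point, against a common
#' reference) into per-gene up/down time-point sets with a canonical
#' pattern label, plus marginal up/down counts per time point.
#'
#' @param results named list of contrast result data frames; names are the
#'   time points, all sharing one gene universe
#' @return list with `profiles` (data frame: `gene_id`, list-columns
#'   `de_up` / `de_down`, `pattern_label`) and `counts` (data frame:
#'   `timepoint`, `n_up`, `n_down`)
#' @export
de_timepoint_sets <- function(results) {
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    stop("`results` must be a named list (names = time points)")
  }
  timepoints <- names(results)
  genes <- results[[1]]$gene_id
  for (tp in timepoints) {
    if (!identical(sort(results[[tp]]$gene_id), sort(genes))) {
      stop("gene universes differ between time points")
    }
  }
  up <- sapply(timepoints, function(tp) {
    r <- results[[tp]]
    stats::setNames(r$direction == "up", r$gene_id)[genes]
  })
  down <- sapply(timepoints, function(tp) {
    r <- results[[tp]]
    stats::setNames(r$direction == "down", r$gene_id)[genes]
  })
  up <- matrix(up, nrow = length(genes), dimnames = list(genes, timepoints))
  down <- matrix(down, nrow = length(genes), dimnames = list(genes, timepoints))
  profiles <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  profiles$de_up <- lapply(genes, function(g) timepoints[up[g, ]])
  profiles$de_down <- lapply(genes, function(g) timepoints[down[g, ]])
  profiles$pattern_label <- mapply(pattern_label, profiles$de_up, profiles$de_down,
                                   MoreArgs = list(timepoints = timepoints))
  counts <- data.frame(timepoint = timepoints,
                       n_up = colSums(up), n_down = colSums(down),
                       row.names = NULL, stringsAsFactors = FALSE)
  list(profiles = profiles, counts = counts)
}

#' Time points of peak change per gene
#'
#' For each gene differentially expressed in one direction at two or more
#' of the analyzed time points, tests every unordered pair of its DE time
#' points with a direct injured-vs-injured contrast on log2 normalized
#' counts (the reference group being shared, the difference between injured
#' groups equals the difference of the per-timepoint fold changes). FDR is
#' adjusted across genes within each pair (conditional mode by default, as
#' for all between-injured comparisons). A DE time point belongs to the
#' peak set unless some other DE time point significantly exceeds it in the
#' gene's direction (larger mean for upregulated genes, smaller for
#' downregulated). Genes with no significant pair keep all their DE time
#' points (`peak_basis = "no_difference_all"`); single-timepoint genes get
#' that singleton with no tests consulted; mixed-direction genes are
#' excluded (`peak_basis = NA`).
#'
#' @param norm normalized matrix
#' @param samples sample sheet data frame
#' @param profiles `profiles` element of [de_timepoint_sets()]
#' @param timepoints time points eligible for peak analysis (default
#'   `c("d3","d7","d28")`)
#' @param group,treatment design factors selecting the injured arm tested
#'   (default vehicle-treated TBI)
#' @param fdr_mode,alpha,p_cutoff FDR settings for the pairwise contrasts
#' @return data frame `gene_id`, list-column `peak_set`, `peak_basis`;
#'   attribute `"n_pair_tests"` records how many pairwise contrasts were
#'   run
#' @export
peak_change_analysis <- function(norm, samples, profiles,
                                 timepoints = c("d3", "d7", "d28"),
                                 group = "TBI", treatment = "vehicle",
                                 fdr_mode = "conditional",
                                 alpha = 0.05, p_cutoff = 0.05) {
  de_up <- lapply(profiles$de_up, intersect, x = timepoints)
  de_down <- lapply(profiles$de_down, intersect, x = timepoints)
  n_up <- lengths(de_up); n_down <- lengths(de_down)
  mixed <- n_up > 0 & n_down > 0
  de_set <- vector("list", nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    de_set[[i]] <- if (mixed[i]) character(0) else if (n_up[i] > 0) de_up[[i]] else de_down[[i]]
  }
  dir_up <- n_up > 0 & !mixed

  # pairwise contrasts only for pairs some eligible gene actually needs
  need_pairs <- unique(unlist(lapply(de_set[lengths(de_set) >= 2], function(s) {
    cmb <- utils::combn(sort(match(s, timepoints)), 2)
    apply(cmb, 2, function(ij) paste(timepoints[ij], collapse = "|"))
  })))
  pair_res <- list()
  for (pair in need_pairs) {
    tp <- strsplit(pair, "|", fixed = TRUE)[[1]]
    s1 <- select_samples(samples, group = group, treatment = treatment, timepoint = tp[1])
    s2 <- select_samples(samples, group = group, treatment = treatment, timepoint = tp[2])
    if (length(s1) < 2 || length(s2) < 2) {
      stop(sprintf("need >= 2 %s/%s samples at %s and %s for peak analysis",
                   group, treatment, tp[1], tp[2]))
    }
    pair_res[[pair]] <- compare_groups(norm, s1, s2, fdr_mode = fdr_mode,
                                       alpha = alpha, p_cutoff = p_cutoff)
  }
  lookup <- lapply(pair_res, function(r) {
    list(fdr = stats::setNames(r$fdr, r$gene_id),
         log2fc = stats::setNames(r$log2fc, r$gene_id))
  })

  peak <- vector("list", nrow(profiles))
  basis <- rep(NA_character_, nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    s <- de_set[[i]]
    if (mixed[i] || length(s) == 0) { peak[[i]] <- character(0); next }
    if (length(s) == 1) { peak[[i]] <- s; basis[i] <- "no_difference_all"; next }
    g <- profiles$gene_id[i]
    s <- timepoints[sort(match(s, timepoints))]
    exceeded <- stats::setNames(rep(FALSE, length(s)), s)
    any_sig <- FALSE
    for (a in seq_len(length(s) - 1)) for (b in seq(a + 1, length(s))) {
      pair <- paste(s[c(a, b)], collapse = "|")
      fdr_g <- lookup[[pair]]$fdr[[g]]
      lfc_g <- lookup[[pair]]$log2fc[[g]]
      if (is.na(fdr_g) || fdr_g >= alpha) next
      any_sig <- TRUE
      # contrast is s[a] (test) vs s[b] (ref): log2fc > 0 means s[a] higher
      higher <- if (lfc_g > 0) s[a] else s[b]
      lower <- setdiff(s[c(a, b)], higher)
      if (dir_up[i]) exceeded[lower] <- TRUE else exceeded[higher] <- TRUE
    }
    peak[[i]] <- s[!exceeded]
    basis[i] <- if (any_sig) "pairwise_significant" else "no_difference_all"
  }
  out <- data.frame(gene_id = profiles$gene_id, stringsAsFactors = FALSE)
  out$peak_set <- peak
  out$peak_basis <- basis
  attr(out, "n_pair_tests") <- length(pair_res)
  out
}
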