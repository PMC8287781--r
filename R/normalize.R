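#' Geometric mean
#'
#' @param x positive numeric vector
#' @return exp(mean(log(x)))
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0) stop("geometric mean of an empty vector")
  if (any(!is.finite(x)) || any(x <= 0)) stop("geometric mean requires positive values")
  exp(mean(log(x)))
}

#' Percent coefficient of variation
#'
#' 100 * sample standard deviation / mean, with the n-1 denominator.
#'
#' @param x numeric vector of length >= 2 with non-zero mean
#' @return %CV as a non-negative number
#' @export
percent_cv <- function(x) {
  if (length(x) < 2) stop("%CV requires at least 2 values")
  m <- mean(x)
  if (m == 0) stop("%CV undefined for zero mean")
  100 * stats::sd(x) / m
}

#' Background thresholding from negative-control probes
#'
#' Estimates a per-sample background level from the negative-control counts
#' and floors every endogenous and housekeeping count below it. The default
#' rule is mean + 2 standard deviations of the sample's negative controls
#' (the platform's conventional default); `"mean"` uses the mean alone,
#' `"fixed"` a user constant, `"off"` disables flooring (thresholds 0).
#' Thresholds below `floor` are raised to `floor` so that downstream
#' logarithms are defined even for degenerate negatives.
#'
#' @param x a [count_table()], or a numeric matrix (already-thresholded
#'   values are accepted) together with `code_class`
#' @param method `"mean2sd"`, `"mean"`, `"fixed"`, or `"off"`
#' @param fixed_value threshold for `method = "fixed"`
#' @param floor minimum threshold (default 1)
#' @param code_class named code-class vector, required when `x` is a matrix
#' @return list with `thresholds` (named per sample), `counts` (matrix with
#'   endogenous + housekeeping rows floored), and `method`
#' @export
background_threshold <- function(x, method = c("mean2sd", "mean", "fixed", "off"),
                                 fixed_value = NULL, floor = 1,
                                 code_class = NULL) {
  if (!inherits(x, "count_table")) {
    if (!is.matrix(x) || is.null(code_class)) {
      stop("`x` must be a count_table, or a matrix with `code_class` supplied")
    }
    x <- list(counts = x, code_class = code_class[rownames(x)])
  }
  method <- match.arg(method)
  neg <- x$counts[x$code_class == "Negative", , drop = FALSE]
  if (method %in% c("mean2sd", "mean") && nrow(neg) < 2) {
    stop("fewer than 2 negative-control probes; pass method = 'off' (or 'fixed') to disable negative-control thresholding explicitly")
  }
  theta <- switch(method,
    mean2sd = apply(neg, 2, function(v) mean(v) + 2 * stats::sd(v)),
    mean    = colMeans(neg),
    fixed   = {
      if (is.null(fixed_value) || fixed_value <= 0) stop("method 'fixed' needs a positive `fixed_value`")
      stats::setNames(rep(fixed_value, ncol(x$counts)), colnames(x$counts))
    },
    off     = stats::setNames(rep(0, ncol(x$counts)), colnames(x$counts))
  )
  theta <- pmax(theta, floor)
  names(theta) <- colnames(x$counts)
  counts <- x$counts
  rows <- x$code_class %in% c("Endogenous", "Housekeeping")
  counts[rows, ] <- pmax(counts[rows, , drop = FALSE],
                         matrix(theta, nrow = sum(rows), ncol = length(theta), byrow = TRUE))
  list(thresholds = theta, counts = counts, method = method)
}

#' Select housekeeping genes by %CV
#'
#' Keeps housekeeping candidates whose %CV across samples (on thresholded
#' raw counts) is strictly below `cv_threshold`. The expression range of
#' the selected set (max/min of per-gene means) is reported as a
#' diagnostic: a broad range (>= 10-fold) is expected for a well-behaved
#' reference set, and a warning is raised when the set is small or narrow.
#'
#' @param counts thresholded count matrix (genes x samples)
#' @param code_class named code-class vector (as in a [count_table()])
#' @param cv_threshold percent, default 15
#' @param sample_ids optional subset of samples over which to compute %CV
#'   (default: all)
#' @return list with `selected` (gene ids), `cv_table` (gene, mean, cv,
#'   selected), and `expression_range` (fold spread of selected means)
#' @export
select_housekeeping <- function(counts, code_class, cv_threshold = 15,
                                sample_ids = NULL) {
  cand <- names(code_class)[code_class == "Housekeeping"]
  if (length(cand) == 0) stop("no housekeeping-class genes present")
  if (is.null(sample_ids)) sample_ids <- colnames(counts)
  sub <- counts[cand, sample_ids, drop = FALSE]
  cv <- apply(sub, 1, percent_cv)
  mu <- rowMeans(sub)
  sel <- cand[cv < cv_threshold]
  if (length(sel) == 0) {
    stop(sprintf("no housekeeping candidate has %%CV < %s; consider relaxing cv_threshold", cv_threshold))
  }
  rng <- max(mu[sel]) / min(mu[sel])
  if (length(sel) < 3) warning("fewer than 3 housekeeping genes selected")
  if (rng < 10) warning(sprintf("selected housekeeping genes span only %.1f-fold in mean expression (>= 10-fold expected)", rng))
  list(
    selected = sel,
    cv_table = data.frame(gene_id = cand, mean = unname(mu), cv = unname(cv),
                          selected = cand %in% sel, stringsAsFactors = FALSE),
    expression_range = rng
  )
}

#' Housekeeping geometric-mean normalization factors
#'
#' Per sample s, g_s is the geometric mean of the housekeeping counts; the
#' reference is the arithmetic mean of the g_s across samples; the
#' normalization factor is f_s = reference / g_s, and normalized counts are
#' raw * f_s.
#'
#' @param counts thresholded (strictly positive) count matrix
#' @param housekeeping character vector of selected housekeeping gene ids
#' @return list with `g_sample`, `reference_mean`, `factors`
#' @export
normalization_factors <- function(counts, housekeeping) {
  if (length(housekeeping) == 0) stop("empty housekeeping set")
  hk <- counts[housekeeping, , drop = FALSE]
  if (any(hk <= 0)) stop("housekeeping counts must be strictly positive (threshold first)")
  g <- apply(hk, 2, geometric_mean)
  ref <- mean(g)
  list(g_sample = g, reference_mean = ref, factors = ref / g)
}

#' Full nSolver-style normalization
#'
#' Composition of [background_threshold()], [select_housekeeping()] and
#' [normalization_factors()], returning the scaled matrix together with the
#' fitted model (thresholds, %CV table, selected genes, factors).
#'
#' @param x a [count_table()] containing housekeeping and (unless
#'   thresholding is off) negative-control probes
#' @param cv_threshold %CV selection threshold (default 15)
#' @param background thresholding rule, see [background_threshold()]
#' @param fixed_value,floor passed to [background_threshold()]
#' @param cv_samples optional sample subset for the %CV computation
#' @return list with `normalized` (matrix, endogenous + housekeeping rows,
#'   strictly positive when thresholding is active) and `model`
#' @export
normalize_counts <- function(x, cv_threshold = 15,
                             background = c("mean2sd", "mean", "fixed", "off"),
                             fixed_value = NULL, floor = 1, cv_samples = NULL) {
  stopifnot(inherits(x, "count_table"))
  background <- match.arg(background)
  if (!any(x$code_class == "Housekeeping")) stop("count table has no housekeeping genes")
  thr <- background_threshold(x, method = background, fixed_value = fixed_value,
                              floor = floor)
  hk <- select_housekeeping(thr$counts, x$code_class, cv_threshold = cv_threshold,
                            sample_ids = cv_samples)
  nf <- normalization_factors(thr$counts, hk$selected)
  keep <- x$code_class %in% c("Endogenous", "Housekeeping")
  normalized <- sweep(thr$counts[keep, , drop = FALSE], 2, nf$factors, `*`)
  model <- list(
    background_method = background,
    background_threshold = thr$thresholds,
    housekeeping_set = hk$selected,
    cv_table = hk$cv_table,
    expression_range = hk$expression_range,
    g_sample = nf$g_sample,
    reference_mean = nf$reference_mean,
    normalization_factor = nf$factors
  )
  list(normalized = normalized, model = model)
}
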