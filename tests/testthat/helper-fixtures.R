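# small in-code fixtures and independent oracles shared across test files

# toy count table: 4 endogenous, 2 housekeeping, 2 positive, 3 negative
toy_count_table <- function() {
  counts <- rbind(
    GeneA = c(120, 240, 60),
    GeneB = c(30, 28, 33),
    GeneC = c(3, 5, 2),
    GeneD = c(1000, 980, 1020),
    HK1 = c(200, 202, 198),
    HK2 = c(400, 404, 396),
    POS1 = c(5000, 5100, 4900),
    POS2 = c(100, 110, 90),
    NEG1 = c(4, 5, 3),
    NEG2 = c(6, 7, 5),
    NEG3 = c(8, 6, 4)
  )
  colnames(counts) <- c("s1", "s2", "s3")
  count_table(counts, c(rep("Endogenous", 4), rep("Housekeeping", 2),
                        rep("Positive", 2), rep("Negative", 3)))
}

# brute-force Benjamini-Hochberg directly from the step-up definition:
# q_i = min_{j: p_j ranked >= rank(i)} m * p_(j) / j, capped at 1
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
    q_sorted[i] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# exact hypergeometric upper tail by enumeration of the pmf
hyper_tail_brute_force <- function(k, N, K, n) {
  js <- max(k, 0):min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# normalized matrix with groups separated by construction: genes x samples,
# log2 means given per sample, tight gaussian noise
build_norm_matrix <- function(gene_means, noise_sd = 0.01, seed = 1) {
  # gene_means: list of named numeric vectors (one per gene), names = samples
  set.seed(seed)
  samples <- names(gene_means[[1]])
  m <- t(vapply(gene_means, function(mu) {
    2^(mu + stats::rnorm(length(mu), 0, noise_sd))
  }, numeric(length(samples))))
  colnames(m) <- samples
  rownames(m) <- names(gene_means)
  m
}

# minimal sample sheet for a vehicle/treated two-arm design
toy_design <- function(timepoints = c("d3", "d7", "d28"), n = 3) {
  rows <- list(data.frame(
    sample_id = sprintf("sham_%d", seq_len(n)), group = "sham",
    treatment = "none", timepoint = "baseline", age_class = "12wk",
    stringsAsFactors = FALSE))
  for (tp in timepoints) {
    rows <- c(rows, list(
      data.frame(sample_id = sprintf("veh_%s_%d", tp, seq_len(n)),
                 group = "TBI", treatment = "vehicle", timepoint = tp,
                 age_class = "12wk", stringsAsFactors = FALSE),
      data.frame(sample_id = sprintf("crry_%s_%d", tp, seq_len(n)),
                 group = "TBI", treatment = "CR2-Crry", timepoint = tp,
                 age_class = "12wk", stringsAsFactors = FALSE)))
  }
  do.call(rbind, rows)
}
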