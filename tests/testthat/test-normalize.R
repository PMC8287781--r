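test_that("geometric mean matches its definition and rejects non-positive input", {
  expect_equal(geometric_mean(c(4, 4, 4)), 4)
  expect_equal(geometric_mean(c(2, 8)), 4)
  expect_equal(geometric_mean(c(1, 10, 100)), 10)
  expect_equal(geometric_mean(c(8, 2)), geometric_mean(c(2, 8)))
  expect_error(geometric_mean(c(1, 0)), "positive")
  expect_error(geometric_mean(numeric(0)), "empty")
})

test_that("percent CV uses the n-1 standard deviation over the mean", {
  expect_equal(percent_cv(c(10, 10, 10)), 0)
  expect_equal(percent_cv(c(8, 12)), 100 * sqrt(8) / 10)   # 28.2843
  expect_equal(percent_cv(c(100, 110, 90)), 10)
  expect_error(percent_cv(5), "at least 2")
})

test_that("geometric mean and %CV agree with brute-force definitions on random vectors", {
  set.seed(101)
  for (i in 1:1000) {
    v <- stats::runif(sample(2:10, 1), 0.5, 1000)
    expect_equal(geometric_mean(v), prod(v)^(1 / length(v)), tolerance = 1e-12)
    expect_equal(percent_cv(v),
                 100 * sqrt(sum((v - mean(v))^2) / (length(v) - 1)) / mean(v),
                 tolerance = 1e-12)
  }
})

test_that("background thresholding floors counts at mean + 2 sd of negatives", {
  counts <- rbind(g1 = c(3, 3, 3), g2 = c(10, 10, 10), g3 = c(50, 50, 50),
                  hk = c(100, 100, 100),
                  n1 = c(4, 4, 4), n2 = c(6, 6, 6), n3 = c(8, 8, 8))
  colnames(counts) <- c("s1", "s2", "s3")
  ct <- count_table(counts, c("Endogenous", "Endogenous", "Endogenous",
                              "Housekeeping", "Negative", "Negative", "Negative"))
  thr <- background_threshold(ct)
  expect_equal(unname(thr$thresholds), rep(10, 3))  # mean 6 + 2*sd 2
  expect_equal(unname(thr$counts[c("g1", "g2", "g3"), "s1"]), c(10, 10, 50))
  # negatives themselves are untouched
  expect_equal(unname(thr$counts["n1", ]), c(4, 4, 4))
})

test_that("degenerate negatives fall back to the floor and thresholding is idempotent", {
  counts <- rbind(g1 = c(0, 5), g2 = c(20, 30),
                  n1 = c(0, 0), n2 = c(0, 0))
  colnames(counts) <- c("s1", "s2")
  ct <- count_table(counts, c("Endogenous", "Endogenous", "Negative", "Negative"))
  thr <- background_threshold(ct)
  expect_equal(unname(thr$thresholds), c(1, 1))
  expect_true(all(thr$counts[c("g1", "g2"), ] >= 1))

  ct2 <- count_table(thr$counts, ct$code_class)
  expect_equal(background_threshold(ct2)$counts, thr$counts)

  # all counts above the threshold: identity
  big <- toy_count_table()
  thr1 <- background_threshold(big)
  above <- big$counts >= matrix(thr1$thresholds, nrow = nrow(big$counts),
                                ncol = 3, byrow = TRUE)
  expect_equal(thr1$counts[above], big$counts[above])

  expect_error(
    background_threshold(count_table(counts[1:3, ],
                                     c("Endogenous", "Endogenous", "Negative"))),
    "disable"
  )
})

test_that("housekeeping selection keeps candidates strictly below the %CV threshold", {
  counts <- rbind(hkA = c(100, 100, 100),   # CV 0 -> in
                  hkB = c(50, 100, 75),     # CV 33 -> out
                  hkC = c(1000, 1010, 990), # CV 1 -> in
                  n1 = c(0, 0, 0), n2 = c(0, 0, 0))
  colnames(counts) <- c("s1", "s2", "s3")
  code <- c("Housekeeping", "Housekeeping", "Housekeeping", "Negative", "Negative")
  sel <- suppressWarnings(
    select_housekeeping(counts, stats::setNames(code, rownames(counts))))
  expect_setequal(sel$selected, c("hkA", "hkC"))
  expect_equal(sel$expression_range, 1000 / 100)
  expect_error(
    select_housekeeping(counts, stats::setNames(code, rownames(counts)),
                        cv_threshold = 0),
    "relaxing"
  )
  # two-sample candidate at CV 47 excluded at the default threshold
  expect_gt(percent_cv(c(50, 100)), 15)
})

test_that("normalization factors scale samples to the housekeeping reference", {
  # per-sample housekeeping geometric means 100, 200, 400
  counts <- rbind(hk1 = c(50, 100, 200), hk2 = c(200, 400, 800))
  colnames(counts) <- c("s1", "s2", "s3")
  nf <- normalization_factors(counts, c("hk1", "hk2"))
  expect_equal(unname(nf$g_sample), c(100, 200, 400))
  expect_equal(nf$reference_mean, 700 / 3)
  expect_equal(unname(nf$factors), (700 / 3) / c(100, 200, 400))
  # self-consistency: mean over samples of reference/f equals the reference
  expect_equal(mean(nf$reference_mean / nf$factors) , nf$reference_mean * 3 / 3,
               tolerance = 1e-9)

  same <- rbind(hk1 = c(100, 100), hk2 = c(400, 400))
  colnames(same) <- c("a", "b")
  expect_equal(unname(normalization_factors(same, c("hk1", "hk2"))$factors),
               c(1, 1))
})

test_that("normalization equalizes housekeeping geometric means across samples", {
  sim <- simulate_panel(sim_config(), seed = 5)
  res <- normalize_counts(sim$counts)
  hk <- res$normalized[res$model$housekeeping_set, ]
  gm <- apply(hk, 2, geometric_mean)
  expect_equal(unname(gm), rep(res$model$reference_mean, ncol(hk)),
               tolerance = 1e-9)
  expect_true(all(res$normalized > 0))
})

test_that("scaling one sample's raw counts rescales its factor relative to the others", {
  ct <- toy_count_table()
  hk <- c("HK1", "HK2")
  f0 <- normalization_factors(ct$counts, hk)$factors
  scaled_counts <- ct$counts
  scaled_counts[, "s2"] <- scaled_counts[, "s2"] * 4
  f1 <- normalization_factors(scaled_counts, hk)$factors
  # relative factors: scaled sample drops 4-fold against every other sample
  expect_equal((f1[["s2"]] / f1[["s1"]]), (f0[["s2"]] / f0[["s1"]]) / 4,
               tolerance = 1e-12)
  expect_equal((f1[["s2"]] / f1[["s3"]]), (f0[["s2"]] / f0[["s3"]]) / 4,
               tolerance = 1e-12)
})

test_that("simulated equal library sizes leave normalization factors near 1", {
  # per-sample factors inherit the housekeeping sampling noise (a few
  # percent at these expression levels); the mean over samples is unbiased
  cfg <- sim_config(sigma_lib = 0)
  sim <- simulate_panel(cfg, seed = 11)
  res <- normalize_counts(sim$counts)
  f <- res$model$normalization_factor
  expect_lt(abs(mean(f) - 1), 0.01)
  expect_true(all(abs(f - 1) < 0.10))
})
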