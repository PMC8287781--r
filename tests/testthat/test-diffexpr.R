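test_that("Welch test matches the reference implementation and is symmetric", {
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(7)
  for (i in 1:50) {
    x <- stats::rnorm(sample(2:6, 1), sd = stats::runif(1, 0.5, 2))
    y <- stats::rnorm(sample(2:6, 1), mean = stats::runif(1, -1, 1))
    mine <- welch_t_test(x, y)
    ref <- stats::t.test(x, y)  # Welch by default
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
    swapped <- welch_t_test(y, x)
    expect_equal(swapped$t, -mine$t)
    expect_equal(swapped$p, mine$p)
  }

  p_ref <- welch_t_test(c(10, 11, 12), c(13, 14, 15))
  expect_equal(p_ref$p, stats::t.test(c(10, 11, 12), c(13, 14, 15))$p.value,
               tolerance = 1e-9)
})

test_that("Welch test degenerate conventions: constant groups", {
  expect_warning(res <- welch_t_test(c(2, 2), c(5, 5)), "zero variance")
  expect_equal(res$p, 0)
  expect_equal(welch_t_test(c(3, 3, 3), c(3, 3, 3))$p, 1)
  expect_error(welch_t_test(1, c(1, 2)), ">= 2")
})

test_that("signed fold change is symmetric around +/-1", {
  expect_equal(signed_fold_change(1, 0), 2)
  expect_equal(signed_fold_change(0, 1), -2)
  expect_equal(signed_fold_change(5, 5), 1)
  set.seed(3)
  d <- stats::rnorm(100, 0, 3)
  fc <- signed_fold_change(d, 0)
  expect_true(all(abs(fc) >= 1))
  expect_equal(sign(fc[d != 0]), sign(d[d != 0]))
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  set.seed(42)
  for (i in 1:1000) {
    p <- stats::runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_brute_force(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  }
})

test_that("conditional BH restricts the family to p < 0.05 and never exceeds 1", {
  expect_equal(conditional_bh_fdr(c(0.01, 0.2, 0.03, 0.6)), c(0.02, 1, 0.03, 1))
  expect_equal(conditional_bh_fdr(c(0.9, 0.06, 0.05)), c(1, 1, 1))
  set.seed(43)
  for (i in 1:200) {
    p <- stats::runif(sample(1:50, 1))
    qc <- conditional_bh_fdr(p)
    qf <- bh_fdr(p)
    sub <- p < 0.05
    # smaller family, same leading ranks: conditional is never more conservative
    expect_true(all(qc[sub] <= qf[sub] + 1e-12))
    expect_true(all(qc[!sub] == 1))
  }
})

test_that("compare_groups flags a strong planted effect and is order-invariant", {
  set.seed(9)
  samples <- c(paste0("t", 1:3), paste0("r", 1:3))
  norm <- 2^matrix(stats::rnorm(50 * 6, 8, 0.2), nrow = 50,
                   dimnames = list(sprintf("g%02d", 1:50), samples))
  norm["g01", 1:3] <- norm["g01", 1:3] * 2^3   # planted log2FC = 3
  res <- compare_groups(norm, paste0("t", 1:3), paste0("r", 1:3))
  expect_true(res$de_flag[res$gene_id == "g01"])
  expect_identical(res$direction[res$gene_id == "g01"], "up")
  expect_gt(res$fc_signed[res$gene_id == "g01"], 1)

  perm_s <- norm[, sample(samples)]
  perm_g <- norm[sample(rownames(norm)), ]
  res_s <- compare_groups(perm_s, paste0("t", 1:3), paste0("r", 1:3))
  expect_equal(res_s$p_value, res$p_value)
  res_g <- compare_groups(perm_g, paste0("t", 1:3), paste0("r", 1:3))
  res_g <- res_g[match(res$gene_id, res_g$gene_id), ]
  expect_equal(res_g$p_value, res$p_value)

  expect_error(compare_groups(norm, "t1", paste0("r", 1:3)), ">= 2 samples")
})

test_that("a group contrasted against a split of itself yields no DE genes", {
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    norm <- 2^matrix(stats::rnorm(200 * 6, 8, 0.3), nrow = 200,
                     dimnames = list(sprintf("g%03d", 1:200),
                                     c(paste0("a", 1:3), paste0("b", 1:3))))
    res <- compare_groups(norm, paste0("a", 1:3), paste0("b", 1:3))
    if (any(res$de_flag)) hits <- hits + 1L
  }
  expect_lte(hits, 2L)  # BH controls family error under the global null
})

test_that("baseline ranking sorts by mean with stable ties and carries annotations", {
  norm <- rbind(low = c(10, 10), high = c(1000, 1000),
                tieB = c(50, 50), tieA = c(50, 50))
  colnames(norm) <- c("s1", "s2")
  ann <- data.frame(gene_id = c("high", "low"),
                    complement_class = c("effector", "regulator"))
  r <- baseline_expression_ranking(norm, c("s1", "s2"), annotations = ann)
  expect_identical(r$gene_id, c("high", "tieA", "tieB", "low"))
  expect_equal(r$mean_count[1] / r$mean_count[4], 100)
  expect_identical(r$complement_class[1], "effector")
  expect_identical(nrow(baseline_expression_ranking(norm, "s1", genes = character(0))), 0L)
})

test_that("2^-dCT relative expression", {
  expect_equal(qpcr_relative_expression(20, 20), 1)
  expect_equal(qpcr_relative_expression(21, 20), 0.5)
  expect_equal(qpcr_relative_expression(18, 20), 4)
})

test_that("ingested comparison tables reproduce compare_groups DE calls", {
  set.seed(12)
  samples <- c(paste0("t", 1:3), paste0("r", 1:3))
  norm <- 2^matrix(stats::rnorm(120 * 6, 8, 0.3), nrow = 120,
                   dimnames = list(sprintf("g%03d", 1:120), samples))
  norm[1:10, 1:3] <- norm[1:10, 1:3] * 2^3
  for (mode in c("standard", "conditional")) {
    res <- compare_groups(norm, paste0("t", 1:3), paste0("r", 1:3), fdr_mode = mode)
    path <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(data.frame(gene_id = res$gene_id,
                                fold_change = res$fc_signed,
                                p_value = res$p_value), path, row.names = FALSE)
    back <- contrast_results_from_comparison(read_comparison_table(path),
                                             fdr_mode = mode)
    expect_equal(back$fdr, res$fdr, tolerance = 1e-12)
    expect_identical(back$de_flag, res$de_flag)
    expect_identical(back$direction, res$direction)
  }
})
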