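tps <- c("d3", "d7", "d28")

test_that("pattern-effect categorization is total, exclusive, and matches its set algebra", {
  subsets <- unlist(lapply(0:3, function(k) {
    if (k == 0) return(list(character(0)))
    apply(utils::combn(tps, k), 2, identity, simplify = FALSE)
  }), recursive = FALSE)
  expect_length(subsets, 8)
  n_by_cat <- c(unchanged = 0, inhibited = 0, induced = 0, shortened = 0,
                extended = 0, shifted = 0)
  for (V in subsets) for (C in subsets) {
    cat <- pattern_effect_category(V, C)
    expect_true(cat %in% names(n_by_cat))
    n_by_cat[cat] <- n_by_cat[cat] + 1
    # each category's defining predicate holds, and only that category's
    expect_identical(cat == "unchanged", setequal(V, C))
    if (!setequal(V, C)) {
      expect_identical(cat == "inhibited", length(V) > 0 && length(C) == 0)
      expect_identical(cat == "induced", length(V) == 0 && length(C) > 0)
      expect_identical(cat == "shortened",
                       length(C) > 0 && all(C %in% V) && !all(V %in% C))
      expect_identical(cat == "extended",
                       length(V) > 0 && all(V %in% C) && !all(C %in% V))
      expect_identical(cat == "shifted",
                       length(setdiff(V, C)) > 0 && length(setdiff(C, V)) > 0)
    }
  }
  expect_equal(sum(n_by_cat), 64)  # all (V, C) pairs covered exactly once
  expect_identical(pattern_effect_category(c("d3", "d7"), "d3"), "shortened")
  expect_identical(pattern_effect_category(character(0), "d7"), "induced")
  expect_identical(pattern_effect_category("d3", c("d3", "d28")), "extended")
})

test_that("level tests call reduced/increased only on significant differences", {
  design <- toy_design()
  means <- list(
    same  = c(8, 10, 10, 10),
    down  = c(8, 12, 12, 12),
    up    = c(8, 10, 10, 10),
    padding = c(8, 8, 8, 8)
  )
  gene_means <- lapply(names(means), function(g) {
    m <- means[[g]]
    mu <- stats::setNames(rep(m[1], nrow(design)), design$sample_id)
    for (i in seq_along(tps)) {
      veh <- design$sample_id[design$treatment == "vehicle" & design$timepoint == tps[i]]
      crry <- design$sample_id[design$treatment == "CR2-Crry" & design$timepoint == tps[i]]
      mu[veh] <- m[i + 1]
      shift <- if (g == "down") -1.5 else if (g == "up") 1.5 else 0
      mu[crry] <- m[i + 1] + shift
    }
    mu
  })
  names(gene_means) <- names(means)
  norm <- build_norm_matrix(gene_means, noise_sd = 0.05, seed = 4)
  lt <- level_effect_tests(norm, design, "d7")
  eff <- stats::setNames(lt$level_effect, lt$gene_id)
  expect_identical(unname(eff["same"]), "none")
  expect_identical(unname(eff["down"]), "reduced")
  expect_identical(unname(eff["up"]), "increased")
})

test_that("identical arms yield no level effects at all", {
  design <- toy_design()
  set.seed(6)
  base <- 2^matrix(stats::rnorm(30 * 3, 8, 0.3), nrow = 30)
  norm <- matrix(0, nrow = 30, ncol = nrow(design),
                 dimnames = list(sprintf("g%02d", 1:30), design$sample_id))
  for (tp in tps) {
    veh <- design$sample_id[design$treatment == "vehicle" & design$timepoint == tp]
    crry <- design$sample_id[design$treatment == "CR2-Crry" & design$timepoint == tp]
    norm[, veh] <- base
    norm[, crry] <- base   # exactly identical treated arm
  }
  norm[, design$sample_id[design$group == "sham"]] <- base
  lt <- level_effect_tests(norm, design, "d3")
  expect_true(all(lt$level_effect == "none"))
})

test_that("treatment summaries partition the gene universe and count reductions among remaining up", {
  mk_profiles <- function(up_sets) {
    genes <- names(up_sets)
    data.frame(gene_id = genes,
               de_up = I(unname(up_sets)),
               de_down = I(rep(list(character(0)), length(genes))),
               pattern_label = NA_character_,
               stringsAsFactors = FALSE)
  }
  veh <- mk_profiles(list(g1 = c("d3", "d7"), g2 = c("d3", "d7"), g3 = character(0),
                          g4 = c("d7"), g5 = c("d3", "d7", "d28")))
  trt <- mk_profiles(list(g1 = c("d3"), g2 = c("d3", "d7"), g3 = c("d7"),
                          g4 = character(0), g5 = c("d3", "d7", "d28")))
  lt <- data.frame(gene_id = c("g2", "g5", "g1"), timepoint = "d7",
                   level_effect = c("reduced", "reduced", "reduced"),
                   stringsAsFactors = FALSE)
  s <- summarize_treatment_effects(veh, trt, lt)
  rec <- s$records
  expect_identical(rec$pattern_effect[rec$gene_id == "g1"], "shortened")
  expect_identical(rec$pattern_effect[rec$gene_id == "g3"], "induced")
  expect_identical(rec$pattern_effect[rec$gene_id == "g4"], "inhibited")
  expect_identical(rec$pattern_effect[rec$gene_id == "g5"], "unchanged")
  expect_equal(sum(s$category_counts$n), 5)
  # g1 lost d7 under treatment, so only g2 and g5 "remained up" at d7
  r7 <- s$reduced_among_up[s$reduced_among_up$timepoint == "d7", ]
  expect_equal(r7$n_remained_up, 2)
  expect_equal(r7$n_reduced_among_up, 2)
  # vehicle-only rule also counts g1 and g4, which lost d7 under treatment
  s2 <- summarize_treatment_effects(veh, trt, lt, remained_rule = "vehicle")
  r7b <- s2$reduced_among_up[s2$reduced_among_up$timepoint == "d7", ]
  expect_equal(r7b$n_remained_up, 4)
  expect_equal(r7b$n_reduced_among_up, 3)
  # unaffected = unchanged pattern and no level effect anywhere
  expect_identical(s$unaffected_genes, character(0))
  lt_none <- lt[0, ]
  s3 <- summarize_treatment_effects(veh, trt, lt_none)
  expect_setequal(s3$unaffected_genes, c("g2", "g5"))

  expect_error(summarize_treatment_effects(veh, trt[1:3, ], lt), "universes differ")
})

test_that("PCA embedding is deterministic, sign-canonical and cluster-separating", {
  set.seed(8)
  norm <- 2^matrix(stats::rnorm(100 * 8, 8, 0.2), nrow = 100,
                   dimnames = list(sprintf("g%03d", 1:100),
                                   c(paste0("a", 1:4), paste0("b", 1:4))))
  norm[1:30, paste0("b", 1:4)] <- norm[1:30, paste0("b", 1:4)] * 2^2

  pca <- pca_embedding(norm)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  # clusters split on PC1
  a <- pca$coordinates$PC1[1:4]; b <- pca$coordinates$PC1[5:8]
  expect_gt(min(abs(outer(a, b, `-`))), max(dist(a)))

  # duplicated sample columns get identical coordinates
  dup <- cbind(norm, a1_copy = norm[, "a1"])
  colnames(dup)[9] <- "a9"
  pd <- pca_embedding(dup)
  expect_equal(unlist(pd$coordinates[pd$coordinates$sample_id == "a9", -1]),
               unlist(pd$coordinates[pd$coordinates$sample_id == "a1", -1]),
               tolerance = 1e-9)

  # gene-order invariance (signs are canonical, so exact up to tolerance)
  perm <- norm[sample(rownames(norm)), ]
  pp <- pca_embedding(perm)
  expect_equal(pp$coordinates$PC1, pca$coordinates$PC1, tolerance = 1e-9)

  # gene-centering leaves n_samples - 1 informative components, which hold
  # the whole variance budget
  full <- pca_embedding(norm, n_components = 7)
  expect_equal(sum(full$explained_variance), 1, tolerance = 1e-9)

  expect_error(pca_embedding(norm[, 1, drop = FALSE]), ">= 2 samples")
  expect_error(pca_embedding(norm, n_components = 9), "more components")
})
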