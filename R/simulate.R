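#' Neuroinflammation panel pathway vocabulary used by the simulator
#' @keywords internal
.panel_pathways <- c(
  "Activated Microglia", "Adaptive Immune Response", "Angiogenesis",
  "Apoptosis", "Astrocyte Function", "Autophagy", "Carbohydrate Metabolism",
  "Cell Cycle", "Cellular Stress", "Cytokine Signaling", "DNA Damage",
  "Epigenetic Regulation", "Growth Factor Signaling", "Inflammatory Signaling",
  "Innate Immune Response", "Insulin Signaling", "Lipid Metabolism",
  "Matrix Remodeling", "NF-kB", "Neurons and Neurotransmission", "Notch",
  "Oligodendrocyte Function", "Oxidative Stress"
)

# named genes planted per archetype block so marker and complement reports
# are exercised end to end on simulated data
.block_named_genes <- list(
  lr_persistent = c("C3", "Fbln5", "H2-T23", "Serping1", "Srgn", "Emp1",
                    "Ptx3", "Tm4sf1", "Serpina3n", "Steap4", "Timp1", "Vim",
                    "C1qa", "C1qb", "C1qc"),
  lr_early_peak = character(0),
  lr_late_peak = "Clec7a",
  unaffected_persistent = c("Gbp2", "Psmb8", "S100a10", "Cd109", "Clcf1",
                            "Tgm1", "Apoe", "Axl", "Tyrobp", "Trem2", "C4a",
                            "Lcn2", "Gfap", "Cxcl10"),
  consistent_down = c("C6", "Rbfox3", "Bdnf", "Homer1", "Grin2b", "Dlg4",
                      "Nrgn", "Cx3cl1", "Pacsin1"),
  inhibited_acute = c("St3gal6", "Lrrc3", "Hmox1", "Msr1", "Fcgr2b", "Cd36",
                      "Cd68", "Cd84", "Ccr5"),
  shortened_acute = c("C3ar1", "C5ar1", "Itgam"),
  extended_acute = character(0),
  induced_d7 = c("Cxcl9", "Traf1", "Ccr2", "Nfkb2", "Nfkbie", "Mmp14",
                 "Ngfr", "Cldn5", "Hdc"),
  acute_unchanged = character(0),
  d3_only = "Pla2g4a",
  chronic_peak = "Itgax",
  null = c("Cfp", "Lair1", "Cd93")
)

#' Simulation configuration
#'
#' Defaults emulate the study design the package targets: a 757-gene
#' endogenous panel with 15 housekeeping candidates (11 stable, 4 noisy), 6
#' positive and 8 negative control probes; one pooled sham group plus
#' vehicle- and inhibitor-treated injured arms at d3/d7/d28, n = 3 per
#' group; negative-binomial counts (variance mu + phi mu^2) around
#' log-normal baselines with per-sample scale factors. Planted temporal
#' archetypes and treatment modifiers are allocated in blocks whose sizes
#' mirror the reported result structure (e.g. 18 consistently downregulated
#' genes, 27 induced, 34 extended, 87 level-reduced-while-upregulated at
#' d7, 60 consistently upregulated genes unaffected by treatment, 29 genes
#' peaking acutely and 1 gene peaking subacutely-chronically).
#'
#' @param n_endogenous endogenous panel size (default 757)
#' @param n_per_group samples per experimental group (default 3)
#' @param baseline_meanlog2,baseline_sdlog2 log2-scale parameters of the
#'   baseline mean distribution (default Normal(8, 2), exponentiated)
#' @param dispersion NB dispersion phi of endogenous genes (default 0.05)
#' @param sigma_lib standard deviation (log scale) of per-sample library
#'   scale factors (default 0.05)
#' @param effect_size generic planted |log2FC| (default 3)
#' @param peak_high,peak_low planted |log2FC| at peak and non-peak time
#'   points of peak-contrast archetypes (defaults 5 and 3, so both the DE
#'   calls and the pairwise peak tests are well powered at n = 3 even for
#'   genes in the low tail of the baseline distribution)
#' @param level_reduction log2 reduction planted in the treated arm at d7
#'   for level-effect genes (default 1.5)
#' @param lambda_bg Poisson mean of negative-control probes (default 4)
#' @param pos_ladder positive-control geometric ladder of spike means
#' @param hk_dispersion_stable,hk_dispersion_noisy NB dispersions of the 11
#'   stable and 4 noisy housekeeping candidates
#' @param blocks named integer vector of genes per archetype block; the
#'   block `null` absorbs the remainder and the total must not exceed
#'   `n_endogenous`
#' @param include_aging add the uninjured/injured 1-year and 2-year arms
#'   with planted aging and chronic-injury effects (default FALSE)
#' @param aging_step planted per-age-step |log2FC| for aging genes
#' @param injury_chronic planted |log2FC| of chronic injury effects (y1/y2)
#' @return a `sim_config` list
#' @export
sim_config <- function(n_endogenous = 757,
                       n_per_group = 3,
                       baseline_meanlog2 = 8,
                       baseline_sdlog2 = 2,
                       dispersion = 0.05,
                       sigma_lib = 0.05,
                       effect_size = 3,
                       peak_high = 5,
                       peak_low = 3,
                       level_reduction = 1.5,
                       lambda_bg = 4,
                       pos_ladder = c(8192, 2048, 512, 128, 32, 8),
                       hk_dispersion_stable = 0.002,
                       hk_dispersion_noisy = 0.3,
                       blocks = c(lr_persistent = 57, lr_early_peak = 29,
                                  lr_late_peak = 1, unaffected_persistent = 30,
                                  consistent_down = 18, inhibited_acute = 60,
                                  shortened_acute = 40, extended_acute = 34,
                                  induced_d7 = 27, acute_unchanged = 80,
                                  d3_only = 40, chronic_peak = 30),
                       include_aging = FALSE,
                       aging_step = 1.5,
                       injury_chronic = 2) {
  cfg <- as.list(environment())
  known <- c("lr_persistent", "lr_early_peak", "lr_late_peak",
             "unaffected_persistent", "consistent_down", "inhibited_acute",
             "shortened_acute", "extended_acute", "induced_d7",
             "acute_unchanged", "d3_only", "chronic_peak")
  bad <- setdiff(names(blocks), known)
  if (length(bad)) {
    stop("unknown archetype block(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(known, collapse = ", "))
  }
  if (any(blocks < 0)) stop("block allocations must be non-negative")
  if (sum(blocks) > n_endogenous) {
    stop(sprintf("archetype allocation (%d) exceeds n_endogenous (%d)",
                 sum(blocks), n_endogenous))
  }
  if (dispersion <= 0) stop("dispersion must be positive")
  if (sigma_lib < 0) stop("sigma_lib must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

# per-block planted log2 effects, (vehicle d3,d7,d28 | treated d3,d7,d28)
.block_betas <- function(cfg) {
  e <- cfg$effect_size; ph <- cfg$peak_high; pl <- cfg$peak_low
  lr <- cfg$level_reduction
  list(
    lr_persistent        = list(veh = c(ph, ph, ph), trt = c(ph, ph - lr, ph)),
    lr_early_peak        = list(veh = c(ph, ph, pl), trt = c(ph, ph - lr, pl)),
    lr_late_peak         = list(veh = c(pl, ph, ph), trt = c(pl, ph - lr, ph)),
    unaffected_persistent = list(veh = c(e, e, e), trt = c(e, e, e)),
    consistent_down      = list(veh = c(-e, -e, -e), trt = c(-e, -e, -e)),
    inhibited_acute      = list(veh = c(e, e, 0), trt = c(0, 0, 0)),
    shortened_acute      = list(veh = c(e, e, 0), trt = c(e, 0, 0)),
    extended_acute       = list(veh = c(e, e, 0), trt = c(e, e, e)),
    induced_d7           = list(veh = c(0, 0, 0), trt = c(0, e, 0)),
    acute_unchanged      = list(veh = c(e, e, 0), trt = c(e, e, 0)),
    d3_only              = list(veh = c(e, 0, 0), trt = c(e, 0, 0)),
    chronic_peak         = list(veh = c(pl, pl, ph), trt = c(pl, pl, ph)),
    null                 = list(veh = c(0, 0, 0), trt = c(0, 0, 0))
  )
}

.block_modifier <- c(
  lr_persistent = "level_reduced", lr_early_peak = "level_reduced",
  lr_late_peak = "level_reduced", unaffected_persistent = "none",
  consistent_down = "none", inhibited_acute = "inhibited",
  shortened_acute = "shortened", extended_acute = "extended",
  induced_d7 = "induced", acute_unchanged = "none", d3_only = "none",
  chronic_peak = "none", null = "none"
)

.block_peak <- c(
  lr_persistent = "d3+d7+d28", lr_early_peak = "d3+d7", lr_late_peak = "d7+d28",
  unaffected_persistent = "d3+d7+d28", consistent_down = "d3+d7+d28",
  inhibited_acute = "d3+d7", shortened_acute = "d3+d7", extended_acute = "d3+d7",
  induced_d7 = "", acute_unchanged = "d3+d7", d3_only = "d3",
  chronic_peak = "d28", null = ""
)

.run_seeded <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a panel-count study with known ground truth
#'
#' Draws a full study dataset under `config` (see [sim_config()]):
#' negative-binomial endogenous and housekeeping counts with per-sample
#' log-normal scale factors, Poisson negative controls, and a
#' positive-control spike ladder. Planted log2 effects follow the block
#' design, and the returned truth table carries, per endogenous gene, the
#' archetype, treatment modifier, planted effects and the pattern /
#' peak-set / treatment-category labels the pipeline is expected to
#' recover (derived from the planted effects by the pipeline's own
#' definitions). Output is bit-reproducible under `seed`; the caller's RNG
#' state is left untouched.
#'
#' @param config a [sim_config()]
#' @param seed integer seed fixing the whole draw
#' @return list with `counts` (a [count_table()]), `samples` (sample
#'   sheet), `truth` (per-endogenous-gene data frame),
#'   `annotations` (gene-to-pathway table with list-columns), and
#'   `housekeeping_truth` (ids of the 11 planted stable candidates)
#' @export
simulate_panel <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  .run_seeded(seed, .simulate_panel_impl(config))
}

.simulate_panel_impl <- function(cfg) {
  timepoints <- c("d3", "d7", "d28")
  blocks <- cfg$blocks
  blocks <- c(blocks, null = cfg$n_endogenous - sum(blocks))
  betas <- .block_betas(cfg)

  ## gene naming: planted marker/complement genes first within each block
  gene_ids <- character(0)
  archetype <- character(0)
  auto_i <- 0
  for (b in names(blocks)) {
    nb <- blocks[[b]]
    named <- .block_named_genes[[b]]
    if (length(named) > nb) named <- named[seq_len(nb)]
    n_auto <- nb - length(named)
    auto <- if (n_auto > 0) sprintf("G%04d", auto_i + seq_len(n_auto)) else character(0)
    auto_i <- auto_i + n_auto
    gene_ids <- c(gene_ids, named, auto)
    archetype <- c(archetype, rep(b, nb))
  }

  ## sample sheet: pooled sham + two injured arms per time point
  n <- cfg$n_per_group
  mk <- function(prefix, group, treatment, timepoint, age) {
    data.frame(sample_id = sprintf("%s_%d", prefix, seq_len(n)),
               group = group, treatment = treatment, timepoint = timepoint,
               age_class = age, stringsAsFactors = FALSE)
  }
  sheets <- list(mk("sham", "sham", "none", "baseline", "12wk"))
  for (tp in timepoints) {
    sheets <- c(sheets,
                list(mk(paste0("veh_", tp), "TBI", "vehicle", tp, "12wk")),
                list(mk(paste0("crry_", tp), "TBI", "CR2-Crry", tp, "12wk")))
  }
  if (cfg$include_aging) {
    sheets <- c(sheets,
                list(mk("sham_y1", "sham", "none", "baseline", "1y")),
                list(mk("tbi_y1", "TBI", "none", "y1", "1y")),
                list(mk("sham_y2", "sham", "none", "baseline", "2y")),
                list(mk("tbi_y2", "TBI", "none", "y2", "2y")))
  }
  samples <- validate_sample_sheet(do.call(rbind, sheets))
  ns <- nrow(samples)

  ## planted per-gene, per-sample log2 effects
  beta <- matrix(0, nrow = cfg$n_endogenous, ncol = ns,
                 dimnames = list(gene_ids, samples$sample_id))
  for (j in seq_len(ns)) {
    tp <- samples$timepoint[j]
    if (!tp %in% timepoints) next
    arm <- if (samples$treatment[j] == "vehicle") "veh" else
      if (samples$treatment[j] == "CR2-Crry") "trt" else NA
    if (is.na(arm)) next
    k <- match(tp, timepoints)
    beta[, j] <- vapply(archetype, function(b) betas[[b]][[arm]][k], numeric(1))
  }
  if (cfg$include_aging) {
    age_step <- match(samples$age_class, c("12wk", "1y", "2y")) - 1L
    for (g in c("C4a", "Lair1")) if (g %in% gene_ids) {
      beta[g, ] <- beta[g, ] + cfg$aging_step * age_step
    }
    if ("Cfp" %in% gene_ids) beta["Cfp", ] <- beta["Cfp", ] - cfg$aging_step * age_step
    chronic <- samples$timepoint %in% c("y1", "y2")
    for (g in c("C3", "C4a")) if (g %in% gene_ids) {
      beta[g, chronic] <- beta[g, chronic] + cfg$injury_chronic
    }
  }

  ## baselines, scale factors, counts; genes planted as downregulated get
  ## well-expressed baselines (they emulate abundant neuronal/synaptic
  ## transcripts) so the planted loss is not hidden below background
  mu_g <- 2^stats::rnorm(cfg$n_endogenous, cfg$baseline_meanlog2, cfg$baseline_sdlog2)
  down_genes <- archetype == "consistent_down"
  if (any(down_genes)) {
    mu_g[down_genes] <- 2^stats::rnorm(sum(down_genes),
                                       cfg$baseline_meanlog2 + 2,
                                       cfg$baseline_sdlog2 / 2)
  }
  s_j <- exp(stats::rnorm(ns, 0, cfg$sigma_lib))
  mu_mat <- (mu_g * 2^beta) * rep(s_j, each = cfg$n_endogenous)
  endo <- matrix(
    stats::rnbinom(length(mu_mat), mu = mu_mat, size = 1 / cfg$dispersion),
    nrow = cfg$n_endogenous, dimnames = dimnames(beta)
  )

  n_hk <- 15
  hk_ids <- sprintf("HK%02d", seq_len(n_hk))
  # housekeeping candidates are well-expressed (platform practice), so the
  # planted-stable ones sit comfortably below the 15 %CV threshold; the 4
  # noisy candidates are interleaved so the stable set keeps a broad
  # (>= 10-fold) expression range
  hk_mu <- 2^seq(8, 12, length.out = n_hk)
  hk_noisy <- c(4, 8, 11, 14)
  hk_phi <- ifelse(seq_len(n_hk) %in% hk_noisy,
                   cfg$hk_dispersion_noisy, cfg$hk_dispersion_stable)
  hk <- matrix(0, nrow = n_hk, ncol = ns, dimnames = list(hk_ids, samples$sample_id))
  for (i in seq_len(n_hk)) {
    hk[i, ] <- stats::rnbinom(ns, mu = hk_mu[i] * s_j, size = 1 / hk_phi[i])
  }

  pos_ids <- sprintf("POS%02d", seq_along(cfg$pos_ladder))
  pos <- matrix(stats::rpois(length(cfg$pos_ladder) * ns,
                             lambda = rep(s_j, each = length(cfg$pos_ladder)) * cfg$pos_ladder),
                nrow = length(cfg$pos_ladder),
                dimnames = list(pos_ids, samples$sample_id))
  neg_ids <- sprintf("NEG%02d", seq_len(8))
  neg <- matrix(stats::rpois(8 * ns, lambda = cfg$lambda_bg), nrow = 8,
                dimnames = list(neg_ids, samples$sample_id))

  counts <- count_table(
    rbind(endo, hk, pos, neg),
    c(rep("Endogenous", cfg$n_endogenous), rep("Housekeeping", n_hk),
      rep("Positive", length(pos_ids)), rep("Negative", length(neg_ids)))
  )

  ## ground truth with expected labels under the pipeline's own definitions
  veh_beta <- t(vapply(archetype, function(b) betas[[b]]$veh, numeric(3)))
  trt_beta <- t(vapply(archetype, function(b) betas[[b]]$trt, numeric(3)))
  colnames(veh_beta) <- paste0("beta_veh_", timepoints)
  colnames(trt_beta) <- paste0("beta_trt_", timepoints)
  expected_sets <- function(bm) {
    apply(bm, 1, function(v) {
      list(up = timepoints[v > 0], down = timepoints[v < 0])
    })
  }
  vsets <- expected_sets(veh_beta); tsets <- expected_sets(trt_beta)
  truth <- data.frame(gene_id = gene_ids, archetype = archetype,
                      modifier = unname(.block_modifier[archetype]),
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, veh_beta, trt_beta)
  truth$expected_pattern <- vapply(vsets, function(s) {
    pattern_label(s$up, s$down, timepoints)
  }, character(1))
  truth$expected_treated_pattern <- vapply(tsets, function(s) {
    pattern_label(s$up, s$down, timepoints)
  }, character(1))
  truth$expected_effect <- mapply(function(v, t) {
    pattern_effect_category(union(v$up, v$down), union(t$up, t$down))
  }, vsets, tsets)
  truth$expected_peak <- unname(.block_peak[archetype])
  truth$expected_level_reduced_d7 <- truth$modifier == "level_reduced"
  rownames(truth) <- NULL

  ## pathway annotations: 1-2 random panel pathways per gene, plus the
  ## complement-system annotation for the named complement genes
  comp <- complement_annotations()
  npw <- sample(1:2, cfg$n_endogenous, replace = TRUE)
  pw <- lapply(seq_len(cfg$n_endogenous), function(i) {
    sample(.panel_pathways, npw[i])
  })
  names(pw) <- gene_ids
  for (g in intersect(comp$gene_id, gene_ids)) {
    pw[[g]] <- unique(c("Complement System", pw[[g]]))
  }
  markers <- marker_classes()
  annotations <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  annotations$pathways <- unname(pw)
  annotations$marker_classes <- lapply(gene_ids, function(g) {
    unique(markers$marker_class[markers$gene_id == g])
  })
  annotations$complement_class <-
    comp$complement_class[match(gene_ids, comp$gene_id)]
  annotations$complement_pathway <-
    comp$complement_pathway[match(gene_ids, comp$gene_id)]

  list(counts = counts, samples = samples, truth = truth,
       annotations = annotations,
       housekeeping_truth = hk_ids[!seq_along(hk_ids) %in% hk_noisy])
}

#' Recovery metrics against planted ground truth
#'
#' Compares observed pipeline output with the planted labels: overall DE
#' detection recall and realized false-discovery proportion, per-archetype
#' pattern-label and peak-set recall, per-modifier treatment-category
#' recall, and level-effect recall for the planted level-reduced genes.
#'
#' @param truth truth table from [simulate_panel()]
#' @param vehicle_profiles `profiles` from [de_timepoint_sets()] on the
#'   vehicle arm
#' @param records optional `records` from [summarize_treatment_effects()]
#' @param peaks optional result of [peak_change_analysis()]
#' @return data frame: `metric`, `group`, `value`, `n`
#' @export
recovery_metrics <- function(truth, vehicle_profiles, records = NULL,
                             peaks = NULL) {
  if (!setequal(truth$gene_id, vehicle_profiles$gene_id)) {
    stop("gene universes differ between truth and profiles")
  }
  idx <- match(truth$gene_id, vehicle_profiles$gene_id)
  observed <- vehicle_profiles$pattern_label[idx]
  out <- list()
  add <- function(metric, group, value, n) {
    out[[length(out) + 1]] <<- data.frame(metric = metric, group = group,
                                          value = value, n = n,
                                          stringsAsFactors = FALSE)
  }
  planted <- truth$expected_pattern != "none"
  add("de_recall", "overall", mean(observed[planted] != "none"), sum(planted))
  called <- observed != "none"
  add("fdp", "overall",
      if (any(called)) mean(!planted[called]) else 0, sum(called))
  for (a in unique(truth$archetype)) {
    i <- truth$archetype == a
    add("pattern_recall", a, mean(observed[i] == truth$expected_pattern[i]), sum(i))
  }
  if (!is.null(peaks)) {
    pk <- vapply(peaks$peak_set[match(truth$gene_id, peaks$gene_id)],
                 paste, character(1), collapse = "+")
    has_peak <- truth$expected_peak != ""
    for (a in unique(truth$archetype[has_peak])) {
      i <- truth$archetype == a & has_peak
      add("peak_recall", a, mean(pk[i] == truth$expected_peak[i]), sum(i))
    }
  }
  if (!is.null(records)) {
    eff <- records$pattern_effect[match(truth$gene_id, records$gene_id)]
    for (m in unique(truth$modifier)) {
      i <- truth$modifier == m
      add("category_recall", m, mean(eff[i] == truth$expected_effect[i]), sum(i))
    }
    if ("level_d7" %in% names(records)) {
      lvl <- records$level_d7[match(truth$gene_id, records$gene_id)]
      i <- truth$expected_level_reduced_d7
      if (any(i)) add("level_reduced_recall", "d7", mean(lvl[i] == "reduced"), sum(i))
    }
  }
  do.call(rbind, out)
}
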