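test_that("Spearman rho handles perfect anti-monotone data and ties", {
  expect_equal(spearman_rho(1:3, c(6, 5, 4)), -1)
  set.seed(19)
  for (i in 1:100) {
    x <- sample(1:4, 8, replace = TRUE)  # heavy ties
    y <- sample(1:4, 8, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_rho(x, y), spearman_brute(x, y),
                 tolerance = 1e-12)
    expect_equal(spearman_rho(x, y),
                 suppressWarnings(cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
  }
})

test_that("pair correlations are computed over platform-matched samples", {
  cfg <- test_config(seed = 20, target_slope = -1, noise_sd = 0.3)
  e <- simulate_expression(cfg)
  targets <- simulate_targets(cfg, e$truth)
  pairs <- pair_correlations(e$mirna, e$mrna, targets)
  expect_true(all(pairs$rho >= -1 & pairs$rho <= 1))
  expect_true(all(pairs$n_samples == 24))
  truth_key <- paste(e$truth$targets$mirna_id, e$truth$targets$gene_id)
  is_true <- paste(pairs$mirna_id, pairs$gene_id) %in% truth_key
  expect_lt(median(pairs$rho[is_true & pairs$source ==
                               "predicted_conserved"]), -0.8)
  ## null pairs center near zero
  expect_lt(abs(median(pairs$rho[!is_true])), 0.25)
})

test_that("the three-requirement filter enforces each requirement strictly", {
  pairs <- tibble::tibble(
    mirna_id = c("m1", "m1", "m2", "m3", "m4"),
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    source = c("validated", "predicted_conserved", "predicted_all",
               "predicted_conserved", "predicted_conserved"),
    context_score = c(NA, -0.4, -0.05, -0.3, -0.3),
    rho = c(-0.9, -0.5, -0.9, -0.51, -0.9),
    n_samples = 24)
  mirna_de <- list(age = c("m1", "m2", "m3"), layer = c("m1", "m4"))
  gene_de <- list(age = c("g1", "g2", "g3", "g4"), layer = "g5")
  out <- three_requirement_filter(pairs, mirna_de, gene_de)
  ## g1: validated, both age-DE... m1 age & g1 age -> in
  ## g2: rho exactly -0.5 -> out (strict); g3: not conserved -> out
  ## g4: passes all three; g5: m4 layer-DE but g5 layer-DE -> in
  expect_setequal(out$gene_id, c("g1", "g4", "g5"))
  ## removing any one requirement never shrinks the output
  relaxed_rho <- three_requirement_filter(pairs, mirna_de, gene_de,
                                          rho_max = 1.01)
  all_de <- list(age = unique(pairs$mirna_id), layer = unique(pairs$mirna_id))
  all_gde <- list(age = unique(pairs$gene_id), layer = unique(pairs$gene_id))
  relaxed_de <- three_requirement_filter(pairs, all_de, all_gde)
  expect_true(all(out$gene_id %in% relaxed_rho$gene_id))
  expect_true(all(out$gene_id %in% relaxed_de$gene_id))
  expect_gte(nrow(relaxed_rho), nrow(out))
  expect_gte(nrow(relaxed_de), nrow(out))
})

test_that("candidate ranking applies the expression floor and orders by
           context score then rho", {
  cand <- tibble::tibble(
    mirna_id = "m1", gene_id = c("gLow", "gB", "gA", "gTie"),
    source = "predicted_conserved",
    context_score = c(-0.5, -0.2, -0.4, -0.2),
    rho = c(-0.9, -0.7, -0.6, -0.8),
    mirna_age = TRUE, mirna_layer = TRUE,
    gene_age = TRUE, gene_layer = TRUE)
  med <- c(gLow = 4.9, gB = 8, gA = 7, gTie = 6)
  ranked <- rank_candidates(cand, med)
  expect_false("gLow" %in% ranked$gene_id)     # 4.9 < 5
  expect_equal(ranked$gene_id, c("gA", "gTie", "gB"))
  ## requiring both contrasts drops genes DE in only one
  cand2 <- dplyr::mutate(cand, gene_layer = c(TRUE, FALSE, TRUE, TRUE))
  expect_false("gB" %in% rank_candidates(cand2, med)$gene_id)
  expect_true("gB" %in% rank_candidates(cand2, med,
                                        require_both_contrasts = FALSE)$gene_id)
})

test_that("the expression quartile filter keeps boundary ties", {
  v <- matrix(rep(c(1, 2, 3, 4), 3), 4, 3,
              dimnames = list(paste0("m", 1:4), NULL))
  x <- make_eset(v, samples = make_samples(3))
  expect_setequal(expression_quartile_filter(x, q = 1), paste0("m", 1:4))
  expect_equal(expression_quartile_filter(x, q = 0.25), "m4")
  vt <- matrix(rep(c(1, 4, 4, 2), 3), 4, 3,
               dimnames = list(paste0("m", 1:4), NULL))
  xt <- make_eset(vt, samples = make_samples(3))
  expect_setequal(expression_quartile_filter(xt, q = 0.25), c("m2", "m3"))
  expect_error(expression_quartile_filter(x, q = 0), "\\(0, 1\\]")
})

test_that("same-module site fractions match a direct count", {
  targets <- tibble::tibble(
    mirna_id = c("m1", "m2", "m3", "m1", "m2", "m4", "m5"),
    gene_id = c("g1", "g1", "g1", "g2", "g2", "g2", "g2"),
    source = "predicted_all", context_score = -0.05)
  asg <- tibble::tibble(feature_id = paste0("m", 1:5),
                        module = c(2L, 2L, 2L, 1L, 0L))
  sf <- same_module_site_fraction(targets, asg)
  expect_equal(sf$same_module_fraction[sf$gene_id == "g1"], 1)
  ## g2: labelled sites m1(2), m2(2), m4(1); m5 is an outlier -> 2/3
  expect_equal(sf$same_module_fraction[sf$gene_id == "g2"], 2 / 3)
  expect_equal(sf$modal_module[sf$gene_id == "g2"], 2L)
  ## a brute count over a random table agrees
  set.seed(21)
  big <- tibble::tibble(mirna_id = sample(paste0("m", 1:5), 50, TRUE),
                        gene_id = sample(paste0("g", 1:8), 50, TRUE),
                        source = "predicted_all", context_score = -0.05)
  sf2 <- same_module_site_fraction(big, asg)
  for (g in sf2$gene_id) {
    mir <- unique(big$mirna_id[big$gene_id == g])
    mods <- asg$module[match(mir, asg$feature_id)]
    mods <- mods[mods > 0]
    expect_equal(sf2$same_module_fraction[sf2$gene_id == g],
                 max(table(mods)) / length(mods))
  }
})

test_that("Mann-Whitney U: exact enumeration, symmetry, and wilcox agreement", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$p, 1 / 6)
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p, 0.4)
  set.seed(22)
  for (i in 1:50) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    mine <- mann_whitney_u(x, y)
    ref <- wilcox.test(x, y, alternative = "less", exact = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    brute <- mw_exact_brute(x, y)
    expect_equal(mine$U, brute$U)
    expect_equal(mine$p, brute$p_less, tolerance = 1e-12)
  }
  ## tied data against the brute oracle
  for (i in 1:25) {
    x <- sample(1:4, 6, TRUE); y <- sample(1:4, 6, TRUE)
    expect_equal(mann_whitney_u(x, y)$p, mw_exact_brute(x, y)$p_less,
                 tolerance = 1e-12)
  }
})

test_that("skew filters commute and enrich the true-pair fraction", {
  cfg <- test_config(seed = 23)
  e <- simulate_expression(cfg)
  targets <- simulate_targets(cfg, e$truth)
  mirna <- quantile_normalize(e$mirna)
  pairs <- pair_correlations(mirna, e$mrna, targets)
  truth_mod <- e$truth$module[e$truth$module$module > 0, ]
  sf <- same_module_site_fraction(targets, truth_mod)
  top <- expression_quartile_filter(mirna, 0.25)
  args_full <- list(pairs = pairs, context_max = -0.3, top_mirnas = top,
                    min_same_module_fraction = 0.5, site_fractions = sf)
  full <- do.call(correlation_skew_test, args_full)
  ## applying the same filters in any order gives the same conserved side
  perm <- correlation_skew_test(pairs, top_mirnas = top,
                                min_same_module_fraction = 0.5,
                                site_fractions = sf, context_max = -0.3)
  expect_equal(full$n_conserved, perm$n_conserved)
  expect_equal(full$U, perm$U)
  ## an empty conserved side errors
  expect_error(correlation_skew_test(pairs, context_max = -5), "empty")
})
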