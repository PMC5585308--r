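make_two_group <- function(n_feat = 50, n_per = 4, delta = 0, sd = 1,
                           seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n_feat * 2 * n_per, sd = sd), n_feat)
  v[, seq_len(n_per)] <- v[, seq_len(n_per)] + delta
  samples <- make_samples(2 * n_per)
  X <- cbind(g1 = rep(1:0, each = n_per), g2 = rep(0:1, each = n_per))
  list(x = make_eset(v, samples = samples), X = X, contrast = c(1, -1))
}

test_that("forcing the prior reproduces the limit identities", {
  d <- make_two_group(seed = 2)
  ## d0 = 0: ordinary t
  f0 <- fit_and_moderate(d$x, d$X, d$contrast, prior = list(d0 = 0, s0_sq = 1))
  ordinary_t <- apply(d$x$values, 1, function(y) {
    unname(t.test(y[1:4], y[5:8], var.equal = TRUE)$statistic)
  })
  expect_lt(max(abs(f0$table$t_mod - ordinary_t)), 1e-10)
  expect_equal(unique(f0$table$df_total), 6)

  ## d0 = Inf: every feature shares the prior variance
  fI <- fit_and_moderate(d$x, d$X, d$contrast,
                         prior = list(d0 = Inf, s0_sq = 2))
  xtxi <- solve(t(d$X) %*% d$X)
  su <- sqrt(drop(t(d$contrast) %*% xtxi %*% d$contrast))
  expect_equal(fI$table$t_mod, f0$table$lfc / (su * sqrt(2)),
               tolerance = 1e-12)
})

test_that("moderated statistics match the brute-force moment estimators", {
  set.seed(5)
  v <- matrix(rnorm(200 * 10), 200) * rep(rgamma(200, 2, 2), 10)
  x <- make_eset(v, samples = make_samples(10))
  X <- cbind(a = rep(1:0, each = 5), b = rep(0:1, each = 5))
  fit <- fit_and_moderate(x, X, c(1, -1))
  oracle <- moderated_brute(v, X, c(1, -1))
  expect_true(is.finite(fit$ebayes$d0))
  expect_lt(abs(fit$ebayes$d0 - oracle$d0), 1e-6)
  expect_lt(abs(fit$ebayes$s0_sq - oracle$s0_sq), 1e-8)
  expect_lt(max(abs(fit$table$t_mod - oracle$t_mod)), 1e-8)
  expect_lt(max(abs(fit$table$p_raw - oracle$p)), 1e-8)
})

test_that("moderated fit agrees with limma as an independent cross-check", {
  skip_if_not_installed("limma")
  set.seed(6)
  v <- matrix(rnorm(300 * 12), 300) * rep(rgamma(300, 3, 3), 12)
  x <- make_eset(v, samples = make_samples(12))
  X <- cbind(a = rep(1:0, each = 6), b = rep(0:1, each = 6))
  fit <- fit_and_moderate(x, X, c(1, -1))
  eb <- limma::eBayes(limma::contrasts.fit(limma::lmFit(v, X), c(1, -1)))
  expect_equal(fit$ebayes$d0, eb$df.prior, tolerance = 1e-8)
  expect_equal(fit$ebayes$s0_sq, eb$s2.prior, tolerance = 1e-8)
  expect_lt(max(abs(fit$table$t_mod - eb$t[, 1])), 1e-10)
})

test_that("BH adjustment matches brute force and handles the hand cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_identical(bh_adjust(p), bh_brute(p))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
  }
})

test_that("DE calling respects thresholds and adjusted p is monotone in |t|", {
  d <- make_two_group(n_feat = 100, delta = 1.5, seed = 8)
  fit <- fit_and_moderate(d$x, d$X, d$contrast)
  expect_equal(nrow(call_de(fit, alpha = 0)), 0)
  tab <- fit$table
  o <- order(abs(tab$t_mod), decreasing = TRUE)
  expect_true(all(diff(tab$p_raw[o]) >= -1e-12))
  expect_true(all(tab$p_adj >= tab$p_raw))
  called <- call_de(fit, alpha = 0.05, lfc_min = 1)
  expect_true(all(abs(called$lfc) > 1))
  expect_true(all(called$direction[called$lfc > 0] == "up"))
})

test_that("animal blocking costs df but gains power when animal effects exist", {
  set.seed(9)
  n_an <- 6
  samples <- make_paired_samples(n_an)
  animal_eff <- rnorm(n_an, sd = 2)[rep(seq_len(n_an), each = 2)]
  layer_eff <- ifelse(samples$layer == "LII", 0.6, 0)
  v <- matrix(rnorm(80 * nrow(samples), sd = 0.5), 80, byrow = FALSE)
  v <- sweep(v, 2, animal_eff + layer_eff, "+")
  x <- make_eset(v, samples = samples)
  Xb <- design_cells(samples, blocking = TRUE)
  Xu <- design_cells(samples, blocking = FALSE)
  expect_gt(ncol(Xb), ncol(Xu))  # blocking never increases residual df
  fb <- fit_and_moderate(x, Xb, contrast_layer(Xb))
  fu <- fit_and_moderate(x, Xu, contrast_layer(Xu))
  expect_gt(sum(fb$table$p_adj < 0.05), sum(fu$table$p_adj < 0.05))
})

test_that("run_all_contrasts reports coherent DE sets and overlap counts", {
  cfg <- test_config(seed = 10)
  e <- simulate_expression(cfg)
  res <- run_all_contrasts(quantile_normalize(e$mirna))
  expect_named(res$fits, c("age", "layer", paste0("layer_", c("P2", "P9",
                                                              "P23", "P45"))))
  v <- setNames(res$venn$n, res$venn$set)
  expect_equal(v[["either"]], v[["age_only"]] + v[["layer_only"]] +
                 v[["both"]])
  ## planted truth is recovered with high power
  expect_gt(mean(e$truth$de_age_mirna %in% res$de_sets$age), 0.95)
  expect_gt(mean(e$truth$de_layer_mirna %in% res$de_sets$layer_any), 0.95)
  ## rank-deficient designs are refused
  X <- design_cells(e$mirna$samples)
  expect_error(fit_and_moderate(e$mirna, cbind(X, X[, 1]),
                                c(contrast_age(X), 0)), "rank deficient")
})
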