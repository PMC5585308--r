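test_that("presence filter keeps a feature detectable in any one group", {
  samples <- dplyr::bind_rows(make_paired_samples(2, "P2"),
                              make_paired_samples(2, "P9"))
  v <- matrix(rnorm(3 * 8), 3, 8)
  detected <- rbind(rep(TRUE, 8),                       # everywhere
                    rep(FALSE, 8),                      # nowhere
                    samples$age == "P9" & samples$layer == "LII")
  x <- make_eset(v, samples = samples)
  kept <- rownames(filter_features(x, detected = detected)$values)
  expect_setequal(kept, c("f1", "f3"))  # one full group suffices
})

test_that("quantile normalization matches the hand oracle and its invariants", {
  x <- make_eset(matrix(c(2, 6, 4, 8), 2, 2))
  out <- quantile_normalize(x)$values
  expect_equal(unname(out), matrix(c(3, 7, 3, 7), 2, 2))

  ## identical columns and single columns are unchanged; idempotent
  same <- make_eset(matrix(c(1, 5, 9, 1, 5, 9), 3, 2))
  expect_equal(quantile_normalize(same)$values, same$values)
  single <- make_eset(matrix(c(4, 2, 7), 3, 1))
  expect_equal(quantile_normalize(single)$values, single$values)
  set.seed(1)
  r <- make_eset(matrix(rnorm(40), 8, 5))
  once <- quantile_normalize(r)
  expect_equal(quantile_normalize(once)$values, once$values,
               tolerance = 1e-12)

  ## columns become exact permutations of one another
  expect_equal(apply(once$values, 2, sort),
               matrix(sort(once$values[, 1]), 8, 5,
                      dimnames = list(NULL, colnames(once$values))))

  ## ties within a column get the mean of their quantile values
  tied <- make_eset(matrix(c(1, 1, 5, 2, 4, 9), 3, 2))
  tv <- quantile_normalize(tied)$values
  expect_equal(tv[1, 1], tv[2, 1])
  expect_error(quantile_normalize(make_eset(matrix(c(1, NA), 1, 2))),
               "complete")
})

test_that("TMM factors satisfy the scaling identities and match edgeR", {
  set.seed(2)
  base <- matrix(rnbinom(300 * 4, mu = 50, size = 3) + 1L, 300, 4)
  x <- make_eset(base, scale = "counts")

  ## identical columns -> unit factors; doubling depth only -> unit factors
  two <- make_eset(cbind(base[, 1], base[, 1]), scale = "counts",
                   samples = make_samples(2))
  expect_equal(as.numeric(tmm_factors(two)), c(1, 1), tolerance = 1e-12)
  dbl <- make_eset(cbind(base[, 1], 2L * base[, 1]), scale = "counts",
                   samples = make_samples(2))
  expect_equal(as.numeric(tmm_factors(dbl)), c(1, 1), tolerance = 1e-12)

  f <- as.numeric(tmm_factors(x))
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)

  ## permuting samples permutes factors
  perm <- c(3, 1, 4, 2)
  xp <- make_eset(base[, perm], scale = "counts")
  expect_equal(as.numeric(tmm_factors(xp)), f[perm], tolerance = 1e-12)

  skip_if_not_installed("edgeR")
  ref <- edgeR::calcNormFactors(edgeR::DGEList(x$values))$samples$norm.factors
  expect_equal(f, ref, tolerance = 1e-10)

  expect_error(tmm_factors(make_eset(matrix(c(0L, 5L), 1, 2),
                                     scale = "counts")), "zero total")
})

test_that("log-CPM follows its closed form and is depth-invariant", {
  x <- make_eset(matrix(c(500L, 999500L), 2, 1), scale = "counts",
                 samples = make_samples(1))
  lc <- log_cpm(x)$values
  expect_equal(lc[1, 1], log2(500.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)

  zero <- make_eset(matrix(c(0L, 100L), 2, 1), scale = "counts",
                    samples = make_samples(1))
  expect_true(all(is.finite(log_cpm(zero)$values)))

  set.seed(3)
  c1 <- matrix(rpois(200, 500), 100, 2)
  a <- log_cpm(make_eset(c1, scale = "counts"))$values
  b <- log_cpm(make_eset(2L * c1, scale = "counts"))$values
  expect_lt(max(abs(a - b)), 0.01)
})

test_that("precision weights track the planted mean-variance trend", {
  set.seed(4)
  n <- 600
  samples <- make_samples(8)
  design <- matrix(1, 8, 1)
  mu <- sort(runif(n, 2, 12))

  ## homoskedastic: weights approximately constant
  v <- matrix(mu + rnorm(n * 8, sd = 0.5), n, 8)
  w <- precision_weights(make_eset(v, samples = samples), design)
  expect_lt(sd(w[, 1]) / mean(w[, 1]), 0.2)

  ## decreasing variance with mean -> weights increase along the trend
  sds <- seq(1.5, 0.2, length.out = n)
  v2 <- matrix(mu + rnorm(n * 8) * sds, n, 8)
  w2 <- precision_weights(make_eset(v2, samples = samples), design)
  expect_gt(cor(mu, w2[, 1], method = "spearman"), 0.8)

  ## single feature: unit weights, with a message
  one <- make_eset(matrix(rnorm(8), 1, 8), samples = samples)
  expect_message(w1 <- precision_weights(one, design), "unit")
  expect_true(all(w1 == 1))
})

test_that("delta-Ct normalization centers per sample and is shift invariant", {
  samples <- make_samples(3, platform = "qpcr", layer = NA)
  v <- matrix(c(20, 22, 24,
                21, 23, 25,
                19, 21, 23), 3, 3)
  x <- make_eset(v, scale = "ct", samples = samples)
  out <- delta_ct_normalize(x)$values
  expect_equal(unname(out[, 1]), c(2, 0, -2))
  expect_equal(unname(colMeans(out)), c(0, 0, 0), tolerance = 1e-12)

  ## adding a constant to one sample's Cts leaves its output unchanged
  v2 <- v; v2[, 2] <- v2[, 2] + 7
  out2 <- delta_ct_normalize(make_eset(v2, scale = "ct",
                                       samples = samples))$values
  expect_equal(out2, out, tolerance = 1e-12)

  ## a feature masked anywhere is absent from the output
  mask <- matrix(FALSE, 3, 3); mask[2, 3] <- TRUE
  xm <- make_eset(v, scale = "ct", samples = samples, mask = mask)
  outm <- delta_ct_normalize(xm)$values
  expect_setequal(rownames(outm), c("f1", "f3"))
  expect_equal(unname(colMeans(outm)), c(0, 0, 0), tolerance = 1e-12)
})
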