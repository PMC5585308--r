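test_that("correlation dendrogram honours the distance definition", {
  samples <- make_samples(6)
  base <- c(1, 3, 2, 5, 4, 6)
  v <- rbind(a = base, b = base * 2 + 1,      # identical up to affine: r = 1
             c = -base)                        # negation: r = -1
  hc <- correlation_dendrogram(make_eset(v, samples = samples))
  cd <- cophenetic(hc)
  m <- as.matrix(cd)
  expect_equal(m["a", "b"], 0, tolerance = 1e-12)
  expect_equal(m["a", "c"], 2, tolerance = 1e-12)
  flat <- matrix(c(base, rep(1, 6)), 2, 6, byrow = TRUE)
  expect_error(correlation_dendrogram(make_eset(flat, samples = samples)),
               "zero-variance")
})

test_that("average linkage matches a naive O(n^3) agglomeration oracle", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:9, 1)
    v <- matrix(rnorm(n * 6), n)
    x <- make_eset(v, samples = make_samples(6))
    hc <- correlation_dendrogram(x)
    D <- 1 - cor(t(v))
    expect_equal(unname(as.matrix(cophenetic(hc))),
                 unname(average_linkage_brute(D)), tolerance = 1e-8)
  }
})

test_that("PART recovers two well-separated groups exactly", {
  set.seed(12)
  samples <- make_samples(12)
  p1 <- rnorm(12); p2 <- -p1
  v <- rbind(matrix(rep(p1, 10), 10, byrow = TRUE),
             matrix(rep(p2, 10), 10, byrow = TRUE)) +
    matrix(rnorm(240, sd = 0.1 * sd(p1)), 20)
  x <- make_eset(v, samples = samples)
  mod <- part_partition(x, seed = 1)
  truth <- rep(1:2, each = 10)
  expect_equal(length(setdiff(unique(mod$module), 0)), 2)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(mod$module, truth), 1)
})

test_that("PART declares one module on unstructured data (majority of seeds)", {
  set.seed(13)
  k1 <- vapply(1:6, function(s) {
    profile <- rnorm(12)
    v <- matrix(rep(profile, 30), 30, byrow = TRUE) +
      matrix(rnorm(360, sd = 0.3 * sd(profile)), 30)
    mod <- part_partition(make_eset(v, samples = make_samples(12)), seed = s)
    length(setdiff(unique(mod$module), 0))
  }, 1L)
  expect_gt(mean(k1 == 1), 0.5)
})

test_that("PART is deterministic, label-invariant under permutation, and
           respects the minimum module size", {
  cfg <- test_config(seed = 14)
  e <- simulate_expression(cfg)
  x <- quantile_normalize(e$mirna)
  feats <- e$truth$module$feature_id[e$truth$module$module > 0]
  m1 <- part_partition(x, feats, seed = 5)
  m2 <- part_partition(x, feats, seed = 5)
  expect_identical(m1, m2)
  expect_true(all(table(m1$module[m1$module > 0]) >= 5))
  skip_if_not_installed("mclust")
  perm <- sample(feats)
  m3 <- part_partition(x, perm, seed = 5)
  joined <- dplyr::inner_join(m1, m3, by = "feature_id")
  expect_equal(mclust::adjustedRandIndex(joined$module.x, joined$module.y), 1)
})

test_that("module profiles are means of standardized members", {
  samples <- make_samples(8)
  base <- c(1, 2, 3, 4, 5, 6, 7, 8)
  v <- rbind(a = base, b = base * 3 - 2, c = -base, d = -2 * base)
  x <- make_eset(v, samples = samples)
  asg <- tibble::tibble(feature_id = c("a", "b", "c", "d"),
                        module = c(1L, 1L, 2L, 0L))
  prof <- module_profiles(x, asg)
  z <- as.numeric(scale(base))
  p1 <- prof$representative[prof$module == 1]
  expect_equal(p1, z, tolerance = 1e-12)
  expect_true(all(prof$n_members[prof$module == 1] == 2))
  expect_false(2 %in% prof$module && any(prof$module == 0))

  ## a module of two anti-correlated profiles cancels to ~0
  asg2 <- tibble::tibble(feature_id = c("a", "c"), module = c(1L, 1L))
  prof2 <- module_profiles(x, asg2)
  expect_equal(prof2$representative, rep(0, 8), tolerance = 1e-12)
})

test_that("planted module shapes are recovered with high cosine similarity", {
  cfg <- test_config(seed = 15)
  e <- simulate_expression(cfg)
  x <- quantile_normalize(e$mirna)
  truth_mod <- e$truth$module[e$truth$module$module > 0, ]
  prof <- module_profiles(x, truth_mod)
  shapes <- default_module_shapes()
  cell <- paste(x$samples$age, x$samples$layer, sep = ".")
  cos <- vapply(sort(unique(prof$module)), function(m) {
    rep_ <- prof$representative[prof$module == m]
    planted <- shapes[m, cell]
    sum(rep_ * planted) / sqrt(sum(rep_^2) * sum(planted^2))
  }, 1.0)
  expect_true(all(cos >= 0.95))
})
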