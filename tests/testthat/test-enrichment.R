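test_that("query selection uses a strict LFC threshold and direction", {
  tab <- tibble::tibble(feature_id = c("a", "b", "c", "d"),
                        lfc = c(0.5, 0.51, -2, 0.7),
                        p_adj = c(0.01, 0.01, 0.01, 0.2))
  expect_setequal(select_query_genes(tab, 0.5, "up"), c("b", "d"))
  expect_setequal(select_query_genes(tab, 0.5, "down"), "c")
  expect_setequal(select_query_genes(tab, 0.5, "up", alpha = 0.05), "b")
})

test_that("Fisher enrichment matches the closed form and the tail oracle", {
  ## the 2x2 [[10,2],[3,15]]: query of 12, term of 13, universe of 30
  universe <- paste0("g", 1:30)
  term_genes <- paste0("g", 1:13)
  query <- paste0("g", c(1:10, 14, 15))
  terms <- tibble::tibble(term_id = "T1", term_name = "t",
                          genes = list(term_genes))
  rec <- fisher_enrichment(query, universe, terms)
  expect_equal(rec$overlap, 10L)
  expect_equal(rec$odds_ratio, 25)  # ad/bc = 10*15/(2*3)
  expect_equal(rec$p_raw, fisher_tail_brute(10, 13, 30, 12),
               tolerance = 1e-12)
  expect_equal(rec$p_raw,
               fisher.test(matrix(c(10, 2, 3, 15), 2),
                           alternative = "greater")$p.value,
               tolerance = 1e-10)
})

test_that("hypergeometric p matches brute-force tails on random tables", {
  set.seed(24)
  for (i in 1:500) {
    universe_n <- sample(20:50, 1)
    term_n <- sample(1:(universe_n - 1), 1)
    query_n <- sample(1:(universe_n - 1), 1)
    universe <- paste0("g", seq_len(universe_n))
    terms <- tibble::tibble(term_id = "T", term_name = "t",
                            genes = list(sample(universe, term_n)))
    query <- sample(universe, query_n)
    rec <- fisher_enrichment(query, universe, terms)
    expect_equal(rec$p_raw,
                 fisher_tail_brute(rec$overlap, term_n, universe_n, query_n),
                 tolerance = 1e-10)
  }
})

test_that("enrichment p is monotone decreasing in overlap at fixed margins", {
  p <- vapply(3:10, function(k) {
    phyper(k - 1, 15, 85, 20, lower.tail = FALSE)
  }, 1.0)
  universe <- paste0("g", 1:100)
  term <- paste0("g", 1:15)
  ps <- vapply(3:10, function(k) {
    query <- c(paste0("g", 1:k), paste0("g", 16:(35 - k)))
    fisher_enrichment(query, universe,
                      tibble::tibble(term_id = "T", term_name = "t",
                                     genes = list(term)))$p_raw
  }, 1.0)
  expect_equal(ps, p, tolerance = 1e-12)
  expect_true(all(diff(ps) < 0))
})

test_that("oversized terms are dropped before testing and the OR is corrected", {
  universe <- paste0("g", seq_len(4000))
  terms <- tibble::tibble(
    term_id = c("small", "big"), term_name = c("s", "b"),
    genes = list(paste0("g", 1:20), paste0("g", seq_len(2501))))
  rec <- fisher_enrichment(paste0("g", 1:10), universe, terms,
                           max_term_size = 2500)
  expect_equal(rec$term_id, "small")
  ## zero cell -> Haldane-Anscombe correction keeps the OR finite
  rec0 <- fisher_enrichment(paste0("g", 30:39), universe,
                            terms[1, ])
  expect_true(is.finite(rec0$odds_ratio))
  ## blocklist removes terms before testing
  recb <- fisher_enrichment(paste0("g", 1:10), universe, terms,
                            blocklist = "small")
  expect_false("small" %in% recb$term_id)
})

test_that("dot-matrix export caps display values only", {
  recs <- list(setA = tibble::tibble(
    term_id = c("T1", "T2", "T3"), term_name = c("a", "b", "c"),
    odds_ratio = c(30, 3, 14), p_adj = c(1e-20, 1e-3, 1e-16),
    significant = TRUE))
  dm <- export_dot_matrix(recs)
  expect_equal(dm$or_capped, c(12, 3, 12))
  expect_equal(dm$neg_log_p_capped, c(15, 3, 15))
  expect_equal(dm$odds_ratio, c(30, 3, 14))     # uncapped retained
  expect_equal(dm$neg_log_p, c(20, 3, 16))
})

test_that("a uniform random query is rarely significant (null calibration)", {
  set.seed(25)
  universe <- paste0("g", seq_len(800))
  terms <- tibble::tibble(
    term_id = paste0("T", 1:30), term_name = paste0("t", 1:30),
    genes = lapply(1:30, function(i) sample(universe, 40)))
  n_sig <- vapply(1:10, function(i) {
    sum(fisher_enrichment(sample(universe, 60), universe,
                          terms)$significant)
  }, 1L)
  expect_lt(mean(n_sig), 1)
})
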