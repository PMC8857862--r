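test_that("the Jaccard index matches hand enumeration", {
  expect_equal(jaccard_index(letters[1:4], letters[3:6]), 2 / 6)
  expect_equal(jaccard_index(c("x", "y"), c("x", "y")), 1)
  expect_equal(jaccard_index("a", "b"), 0)
  expect_equal(jaccard_index(c("a", "a", "b"), c("b", "b")), 1 / 2) # dedup
  expect_error(jaccard_index(character(0), character(0)), "undefined")
})

test_that("size-preserving randomization preserves cardinalities", {
  universe <- as.character(1:30)
  sizes <- c(A = 5L, B = 12L, C = 30L)
  set.seed(1)
  for (i in 1:10) {
    draw <- randomize_variant_sets(universe, sizes)
    expect_equal(lengths(draw), sizes)
    expect_true(all(unlist(draw) %in% universe))
  }
  # a set as large as the universe is always the whole universe
  full <- randomize_variant_sets(universe, c(A = 30L, B = 30L))
  expect_setequal(full$A, universe)
  expect_equal(jaccard_index(full$A, full$B), 1)
  # same seed, same draws
  d1 <- with(list(), {set.seed(7); randomize_variant_sets(universe, sizes)})
  d2 <- with(list(), {set.seed(7); randomize_variant_sets(universe, sizes)})
  expect_identical(d1, d2)
  expect_error(randomize_variant_sets(universe, c(A = 31L)), "exceeds")
})

test_that("empirical p-values count ties as exceeding", {
  expect_equal(empirical_pvalue(0.5, c(0.1, 0.2, 0.3), "plus_one")$p_value,
               1 / 4)
  r <- empirical_pvalue(0.3, c(0.1, 0.2, 0.3), "plus_one")
  expect_equal(r$p_value, 2 / 4) # the tie at 0.3 counts
  expect_equal(r$exceed_count, 1L)
  expect_equal(empirical_pvalue(0.05, c(0.1, 0.2, 0.3), "raw")$p_value, 1)
  expect_equal(empirical_pvalue(0.9, c(0.1, 0.2, 0.3), "raw")$p_value, 0)
  expect_error(empirical_pvalue(0.5, numeric(0)), "non-empty")
})

test_that("significance categories reproduce the published star key", {
  expect_equal(significance_category(0L, 100000L), "***")
  expect_equal(significance_category(500L, 100000L), "**")
  expect_equal(significance_category(5000L, 100000L), "*")
  # the boundary p = 0.01 is not significant
  expect_equal(significance_category(1000L, 100000L), "*")
  expect_equal(significance_category(999L, 100000L), "**")
  # p = 1e-6 exactly is the top stratum
  expect_equal(significance_category(1L, 1000000L), "***")
  expect_error(significance_category(11L, 10L), "0..n_randomizations")
})

test_that("maximal overlap of identical small sets reaches the floor p-value", {
  cfg <- permutation_config(400, seed = 11)
  res <- test_pair(c("1", "2", "3", "4", "5"), c("1", "2", "3", "4", "5"),
                   universe = as.character(1:600), config = cfg)
  expect_equal(res$jaccard, 1)
  expect_equal(res$exceed_count, 0L)
  expect_equal(res$p_raw, 0)
  expect_equal(res$p_plus_one, 1 / 401)
})

test_that("p is non-increasing in the shared count at fixed sizes", {
  universe <- as.character(1:40)
  cfg <- permutation_config(1000, seed = 5)
  ps <- vapply(c(2L, 4L, 6L, 8L, 10L), function(k) {
    a <- as.character(1:10)
    b <- as.character(c(seq_len(k), 30L + seq_len(10L - k)))
    test_pair(a, b, universe = universe, config = cfg)$p_raw
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("plus-one p-values are never zero; raw is zero iff nothing exceeds", {
  set.seed(99)
  for (i in 1:20) {
    k <- sample(0:5, 1)
    a <- as.character(1:8)
    b <- as.character(c(seq_len(k), 100L + seq_len(8L - k)))
    res <- test_pair(a, b, universe = as.character(1:120),
                     config = permutation_config(300, seed = i))
    expect_gt(res$p_plus_one, 0)
    expect_equal(res$p_raw == 0, res$exceed_count == 0L)
  }
})

test_that("the permutation p agrees with the closed-form hypergeometric tail", {
  cfg <- permutation_config(20000, seed = 31)
  a <- as.character(1:6)
  b <- as.character(c(1:3, 25:29)) # 3 shared, sizes 6 and 8
  res <- test_pair(a, b, universe = as.character(1:30), config = cfg)
  exact <- hypergeom_overlap_pvalue(6, 8, 3, 30)
  se <- sqrt(exact * (1 - exact) / cfg$n_randomizations)
  expect_lt(abs(res$p_raw - exact), 3 * se)
})

test_that("test_pair is deterministic given a seed and validates inputs", {
  cfg <- permutation_config(500, seed = 123)
  a <- c("73", "489")
  b <- c("73", "11719")
  universe <- as.character(c(73, 489, 11719, 1:47))
  r1 <- test_pair(a, b, universe = universe, config = cfg)
  r2 <- test_pair(a, b, universe = universe, config = cfg)
  expect_identical(r1, r2)
  expect_error(test_pair(a, b, universe = c("73", "489")), "subsets")
  expect_error(test_pair(character(0), b), "non-empty")
})

test_that("the degree-preserving swap null conserves degrees", {
  # all variants have degree one, so no rewiring can ever create an overlap:
  # the null distribution is degenerate at 0 and a zero-overlap observation
  # has p = 1
  sets <- list(A = c("v1", "v2"), B = c("v3", "v4"), C = c("v5", "v6"))
  cfg <- permutation_config(200, seed = 17,
                            null_model = "degree_preserving_swap")
  res <- test_pair(sets$A, sets$B, universe = paste0("v", 1:6),
                   config = cfg, cancer_a = "A", cancer_b = "B",
                   network_sets = sets)
  expect_equal(res$p_raw, 1)
  # swap null without the full network is refused
  expect_error(test_pair(sets$A, sets$B, config = cfg), "network_sets")
  # deterministic under a fixed seed on a non-degenerate network
  sets2 <- list(A = c("v1", "v2", "v3"), B = c("v1", "v4", "v5"),
                C = c("v2", "v4", "v6"), D = c("v3", "v5", "v6"))
  cfg2 <- permutation_config(300, seed = 4,
                             null_model = "degree_preserving_swap")
  s1 <- test_pair(sets2$A, sets2$B, config = cfg2, cancer_a = "A",
                  cancer_b = "B", network_sets = sets2)
  s2 <- test_pair(sets2$A, sets2$B, config = cfg2, cancer_a = "A",
                  cancer_b = "B", network_sets = sets2)
  expect_identical(s1, s2)
  expect_true(s1$p_raw >= 0 && s1$p_raw <= 1)
})

test_that("overlap_scan keeps only sharing pairs, ordered by evidence", {
  sets <- toy_sets() # Z shares nothing with GC
  cfg <- permutation_config(400, seed = 8)
  res <- overlap_scan(sets, "GC", config = cfg)
  expect_equal(nrow(res), 2L)
  expect_setequal(res$cancer_b, c("X", "Y"))
  expect_true(all(diff(res$p_value) >= 0))
  expect_equal(res$p_bonferroni, pmin(1, res$p_value * 2))
  r2 <- overlap_scan(sets, "GC", config = cfg)
  expect_identical(res, r2)
  expect_error(overlap_scan(sets, "missing"), "reference label")
})

test_that("max_shared finds every pair attaining the maximum", {
  tab <- load_table1_fixture()
  ms <- max_shared(tab)
  expect_equal(ms$count, 8L)
  expect_equal(ms$cancers, c("Kidney-RCC", "Liver-HCC", "Prost-AdenoCA"))
  one <- tab[tab$cancer_b == "Uterus-AdenoCA", ]
  expect_equal(max_shared(one)$count, 3L)
  expect_error(max_shared(tab[0, ]), "non-empty")
})

test_that("multi-cancer variant collection respects k and significance", {
  tab <- load_table1_fixture()
  sig2 <- multi_cancer_variants(tab, min_cancers = 2, significant_only = TRUE)
  expect_length(sig2, 11L)
  # the two most recurrent variants appear in five significant pairs each
  expect_length(multi_cancer_variants(tab, 5, TRUE), 2L)
  expect_named(multi_cancer_variants(tab, 5, TRUE), c("11914", "16111"))
  expect_length(multi_cancer_variants(tab, 6, TRUE), 0L)
  all_any <- multi_cancer_variants(tab, 1, FALSE)
  expect_length(all_any, 30L)
  expect_error(multi_cancer_variants(tab, 0), ">= 1")
})
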