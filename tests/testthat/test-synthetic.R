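test_that("planted overlaps are realized exactly when chance overlap is off", {
  cfg <- synthetic_config(
    seed = 3, universe_size = 200,
    cancer_types = data.frame(label = c("X", "Y"), set_size = c(30L, 25L),
                              n_samples = c(5L, 5L)),
    reference_size = 40L,
    planted_overlaps = c(X = 8L, Y = 0L)
  )
  sim <- generate_cohorts(cfg)
  expect_equal(unname(sim$truth$realized_overlaps), c(8L, 0L))
  sets <- cohort_variant_sets(sim$cohort_b)
  ref <- cohort_variant_sets(sim$cohort_a)$GC
  expect_equal(length(intersect(ref, sets$X)), 8L)
  expect_equal(length(intersect(ref, sets$Y)), 0L)
})

test_that("infeasible configurations are rejected before sampling", {
  types <- data.frame(label = "X", set_size = 10L, n_samples = 3L)
  expect_error(
    synthetic_config(seed = 1, universe_size = 100, cancer_types = types,
                     reference_size = 5L, planted_overlaps = c(X = 10L)),
    "planted overlap"
  )
  expect_error(
    synthetic_config(seed = 1, universe_size = 12, cancer_types = types,
                     reference_size = 5L),
    "universe too small"
  )
  expect_error(
    synthetic_config(seed = 1, universe_size = 20000, cancer_types = types,
                     reference_size = 5L),
    "16569"
  )
  expect_error(
    synthetic_config(seed = 1, universe_size = 100, cancer_types = types,
                     reference_size = 5L, planted_overlaps = c(Q = 1L)),
    "unknown cancer type"
  )
})

test_that("generation is deterministic: same seed, byte-identical files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_synthetic_cohorts(
    generate_cohorts(synthetic_preset("table1-like", seed = 5)), d1
  )
  write_synthetic_cohorts(
    generate_cohorts(synthetic_preset("table1-like", seed = 5)), d2
  )
  for (f in c("cohort_a.tsv", "cohort_b.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  write_synthetic_cohorts(
    generate_cohorts(synthetic_preset("table1-like", seed = 6)), d3
  )
  expect_false(identical(readLines(file.path(d1, "cohort_b.tsv")),
                         readLines(file.path(d3, "cohort_b.tsv"))))
})

test_that("generated files pass the variant-table reader unchanged", {
  dir <- withr::local_tempdir()
  sim <- generate_cohorts(synthetic_preset("table1-like", seed = 12))
  write_synthetic_cohorts(sim, dir)
  a <- read_variant_table(file.path(dir, "cohort_a.tsv"))
  b <- read_variant_table(file.path(dir, "cohort_b.tsv"))
  expect_identical(cohort_variant_sets(a), sim$cohort_a$variant_sets)
  expect_identical(cohort_variant_sets(b), sim$cohort_b$variant_sets)
  expect_identical(cohort_carrier_counts(b), sim$cohort_b$carrier_counts)
})

test_that("the carrier model realizes all three frequency classes", {
  sim <- generate_cohorts(synthetic_preset("table1-like", seed = 1))
  m <- intersect_cohorts(sim$cohort_a, sim$cohort_b)
  expect_setequal(unique(m$frequency_class),
                  c("higher_in_a", "higher_in_b", "equal"))
})

test_that("planted pairs earn systematically smaller p than weakly planted ones", {
  ranks <- vapply(1:10, function(r) {
    cfg <- synthetic_config(
      seed = 100 + r, universe_size = 600,
      cancer_types = data.frame(
        label = c("planted8", "planted1"),
        set_size = c(50L, 50L), n_samples = c(5L, 5L)
      ),
      reference_size = 50L,
      planted_overlaps = c(planted8 = 8L, planted1 = 1L)
    )
    sim <- generate_cohorts(cfg)
    sets <- c(list(GC = cohort_variant_sets(sim$cohort_a)$GC),
              cohort_variant_sets(sim$cohort_b))
    res <- overlap_scan(sets, "GC", universe = sim$truth$universe_keys,
                        config = permutation_config(500, seed = r))
    which(res$cancer_b == "planted8")
  }, integer(1))
  expect_true(mean(ranks == 1L) >= 0.9)
})

test_that("presets encode the documented study magnitudes", {
  cfg <- synthetic_preset("table1-like", seed = 1)
  expect_equal(cfg$universe_size, 600L)
  expect_equal(cfg$reference_size, 50L)
  expect_equal(cfg$reference_samples, 13L)
  expect_equal(nrow(cfg$cancer_types), 22L)
  expect_true(all(cfg$cancer_types$set_size >= 30L &
                    cfg$cancer_types$set_size <= 200L))
  expect_true(all(cfg$planted_overlaps >= 1L & cfg$planted_overlaps <= 8L))
  expect_false(cfg$allow_chance_overlap)

  null_cfg <- synthetic_preset("table1-like", seed = 1, planted = "none")
  expect_true(all(null_cfg$planted_overlaps == 0L))
  expect_true(null_cfg$allow_chance_overlap)

  toy <- synthetic_preset("toy", seed = 1)
  expect_equal(toy$universe_size, 8L)
})
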