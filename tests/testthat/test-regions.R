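map <- build_region_map()

test_that("the default map holds the canonical features on the full-length genome", {
  expect_equal(map$genome_length, 16569L)
  expect_equal(nrow(map$features), 38L) # 37 genes + control region
  dloop <- map$features[map$features$category == "control_region", ]
  expect_equal(nrow(dloop), 1L)
  expect_true(dloop$wraps_origin)
  expect_equal(dloop$start, 16024L)
  expect_equal(dloop$end, 576L)
})

test_that("positions annotate to their published regions", {
  expect_equal(annotate_position(map, 11719)$primary, "MT-ND4")
  expect_equal(annotate_position(map, 489)$primary, "D-loop")
  expect_equal(annotate_position(map, 8584)$primary, "MT-ATP6")
  expect_equal(annotate_position(map, 13789)$primary, "MT-ND5")
  expect_error(annotate_position(map, 0), "out of range")
  expect_error(annotate_position(map, 16570), "out of range")
})

test_that("the wrapped control region obeys circular membership", {
  in_dloop <- function(p) {
    "D-loop" %in% annotate_position(map, p)$features$name
  }
  expect_true(all(vapply(c(16024, 16569, 1, 576), in_dloop, logical(1))))
  expect_false(in_dloop(577))
  expect_false(in_dloop(16023))
})

test_that("overlapping genes report all matches with a deterministic primary", {
  hit <- annotate_position(map, 8560) # inside both MT-ATP8 and MT-ATP6
  expect_setequal(hit$features$name, c("MT-ATP8", "MT-ATP6"))
  expect_equal(hit$primary, "MT-ATP8") # tie broken by smaller start
  hit2 <- annotate_position(map, 10762) # MT-ND4L / MT-ND4 overlap
  expect_setequal(hit2$features$name, c("MT-ND4L", "MT-ND4"))
  expect_equal(hit2$primary, "MT-ND4L")
})

test_that("primary labels partition the entire circular genome", {
  ann <- annotate_positions(map, seq_len(16569L))
  expect_equal(nrow(ann), 16569L)
  expect_false(any(is.na(ann$region)))
  # every feature and the intergenic fallback are realized as a primary label
  expect_true(all(c(map$features$name, "intergenic") %in% ann$region))
  # spot-check against the independent per-position path
  set.seed(42)
  for (p in sample.int(16569L, 50L)) {
    expect_equal(ann$region[p], annotate_position(map, p)$primary)
  }
  # region sizes sum to the genome length (totality)
  expect_equal(sum(table(ann$region)), 16569L)
})

test_that("region summaries reproduce the published region counts", {
  sv <- load_shared_variant_fixture()
  s30 <- summarize_regions(map, sv$position)
  expect_equal(s30$n_regions, 11L)
  golden <- annotate_positions(map, sv$position)
  expect_equal(golden$region, sv$region)

  s11 <- summarize_regions(map, sv$position[sv$somatic])
  expect_equal(s11$n_regions, 4L)
  expect_setequal(names(s11$regions),
                  c("D-loop", "MT-ND1", "MT-ND4", "MT-ND5"))
  expect_equal(s11$regions[["D-loop"]],
               c(73L, 489L, 16093L, 16189L, 16360L))

  empty <- summarize_regions(map, integer(0))
  expect_equal(empty$n_regions, 0L)
})

test_that("custom maps are validated", {
  bad_coord <- local_tsv(c(
    "name\tstart\tend\tcategory",
    "FOO\t1\t16570\tprotein_coding"
  ))
  expect_error(build_region_map(bad_coord), "out of range")
  bad_cat <- local_tsv(c(
    "name\tstart\tend\tcategory",
    "FOO\t1\t10\texon"
  ))
  expect_error(build_region_map(bad_cat), "category")
  # two same-category features starting at the same coordinate overlap
  # ambiguously unless a priority column orders them
  ambiguous <- local_tsv(c(
    "name\tstart\tend\tcategory",
    "FOO\t10\t100\tprotein_coding",
    "BAR\t10\t60\tprotein_coding"
  ))
  expect_error(build_region_map(ambiguous), "priority")
  resolved <- local_tsv(c(
    "name\tstart\tend\tcategory\tpriority",
    "FOO\t10\t100\tprotein_coding\t2",
    "BAR\t10\t60\tprotein_coding\t1"
  ))
  custom <- build_region_map(resolved)
  expect_equal(annotate_position(custom, 20)$primary, "BAR")
  expect_equal(annotate_position(custom, 5)$primary, "intergenic")
})
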