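#' Packaged pairwise-overlap summary table
#'
#' Returns the 22 published rows summarizing shared variants between the
#' gastric-cancer (GC) reference cohort and each other cancer type: the
#' Jaccard index, the significance category of its randomization test
#' (`"*"` not significant, p > 0.01; `"**"` p < 0.01; `"***"` p <= 1e-6)
#' and the shared positions. Numeric p-values were not published, so only the
#' category is stored.
#'
#' @return A tibble with columns `cancer_a`, `cancer_b`, `jaccard`,
#'   `n_shared`, `significance` and `shared_variants` (list of integer
#'   positions, in printed order).
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_overlaps.tsv", package = "mitonet",
                      mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged overlap-table fixture is missing", call. = FALSE)
  }
  raw <- readr::read_tsv(path, col_types = "ccdcc", progress = FALSE)
  expected <- c("cancer_a", "cancer_b", "jaccard", "category", "variants")
  if (!identical(names(raw), expected) || nrow(raw) == 0L) {
    stop("packaged overlap-table fixture is corrupt", call. = FALSE)
  }
  shared <- lapply(strsplit(raw$variants, "|", fixed = TRUE), function(x) {
    assert_rcrs_position(x, what = "fixture position")
  })
  if (any(lengths(shared) == 0L) ||
      !all(raw$category %in% c("*", "**", "***")) ||
      any(raw$jaccard < 0 | raw$jaccard > 1)) {
    stop("packaged overlap-table fixture is corrupt", call. = FALSE)
  }
  tibble::tibble(
    cancer_a = raw$cancer_a,
    cancer_b = raw$cancer_b,
    jaccard = raw$jaccard,
    n_shared = lengths(shared),
    significance = raw$category,
    shared_variants = shared
  )
}

#' Packaged shared-variant region list
#'
#' The 30 mitochondrial positions found in both source cohorts, each with its
#' published region label, and the flag marking the 11 positions that were
#' exclusive to tumours (somatic) in the gastric-cancer cohort.
#'
#' @return A tibble with columns `position`, `region`, `somatic` (logical).
#' @export
load_shared_variant_fixture <- function() {
  path <- system.file("extdata", "shared_variant_regions.tsv",
                      package = "mitonet", mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged shared-variant fixture is missing", call. = FALSE)
  }
  raw <- readr::read_tsv(path, col_types = "ici", progress = FALSE)
  if (!identical(names(raw), c("position", "region", "somatic")) ||
      nrow(raw) == 0L || anyDuplicated(raw$position) > 0L) {
    stop("packaged shared-variant fixture is corrupt", call. = FALSE)
  }
  assert_rcrs_position(raw$position, what = "fixture position")
  tibble::tibble(
    position = raw$position,
    region = raw$region,
    somatic = raw$somatic == 1L
  )
}
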