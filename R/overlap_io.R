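# TSV serialization of pairwise overlap results.
#
# Column names follow the published table legend: CT1/CT2 cancer types, JC
# Jaccard index, N number of shared variants; the statistical columns
# (P_value, exceed_count, ...) are written when present so that scan output
# round-trips losslessly.

OVERLAP_EXTRA_COLS <- c(
  "n_a", "n_b", "p_raw", "p_plus_one", "exceed_count",
  "n_randomizations", "p_bonferroni"
)

#' Write a pairwise overlap table
#'
#' Serializes overlap results (from [overlap_scan()], [test_pair()] or the
#' packaged fixture) to TSV with columns `CT1`, `CT2`, `JC`, `N`, `P_value`,
#' `category` and pipe-delimited `variants`, plus any statistical columns
#' present. The file round-trips losslessly through [read_overlap_table()].
#'
#' @param results tibble of overlap results; must be non-empty.
#' @param path output file.
#' @return The input, invisibly.
#' @export
write_overlap_table <- function(results, path) {
  if (is.null(results) || nrow(results) == 0L) {
    stop("results must be non-empty", call. = FALSE)
  }
  out <- tibble::tibble(
    CT1 = results$cancer_a,
    CT2 = results$cancer_b,
    JC = results$jaccard,
    N = if (!is.null(results[["n_shared"]])) results[["n_shared"]]
        else lengths(results$shared_variants),
    P_value = if (!is.null(results[["p_value"]])) results[["p_value"]] else NA_real_,
    category = results$significance,
    variants = vapply(results$shared_variants, paste,
                      character(1), collapse = "|")
  )
  for (col in OVERLAP_EXTRA_COLS) {
    if (!is.null(results[[col]])) out[[col]] <- results[[col]]
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(results)
}

#' Read a pairwise overlap table
#'
#' Inverse of [write_overlap_table()].
#'
#' @param path TSV produced by [write_overlap_table()].
#' @return A tibble with columns `cancer_a`, `cancer_b`, `jaccard`,
#'   `n_shared`, `p_value`, `significance`, `shared_variants` plus any
#'   statistical columns stored in the file.
#' @export
read_overlap_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    CT1 = "c", CT2 = "c", JC = "d", N = "i", P_value = "d",
    category = "c", variants = "c", .default = "d"
  ), progress = FALSE)
  required <- c("CT1", "CT2", "JC", "N", "category", "variants")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing overlap-table column(s): ",
      paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  shared <- strsplit(raw$variants, "|", fixed = TRUE)
  if (all(grepl("^[0-9]+$", unlist(shared)))) {
    shared <- lapply(shared, as.integer)
  }
  out <- tibble::tibble(
    cancer_a = raw$CT1,
    cancer_b = raw$CT2,
    jaccard = raw$JC,
    n_shared = raw$N,
    p_value = if (!is.null(raw[["P_value"]])) raw[["P_value"]] else NA_real_,
    significance = raw$category,
    shared_variants = shared
  )
  for (col in OVERLAP_EXTRA_COLS) {
    if (!is.null(raw[[col]])) out[[col]] <- raw[[col]]
  }
  int_cols <- intersect(c("n_a", "n_b", "exceed_count", "n_randomizations"),
                        names(out))
  for (col in int_cols) out[[col]] <- as.integer(out[[col]])
  out
}
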