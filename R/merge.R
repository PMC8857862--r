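#' Classify the carrier-frequency balance of a shared variant
#'
#' @param carriers_a,carriers_b distinct-sample carrier counts (>= 1) in the
#'   two cohorts.
#' @return Character vector: `"higher_in_a"`, `"higher_in_b"` or `"equal"`,
#'   determined by the sign of `carriers_a - carriers_b`.
#' @export
classify_frequency <- function(carriers_a, carriers_b) {
  if (any(carriers_a < 1L) || any(carriers_b < 1L)) {
    stop("carrier counts of a shared variant must be >= 1", call. = FALSE)
  }
  d <- sign(carriers_a - carriers_b)
  c("higher_in_b", "equal", "higher_in_a")[d + 2L]
}

#' Merge two cohorts on their shared variants
#'
#' Intersects the variant keys of two cohorts and reports, per shared key, the
#' distinct-sample carrier counts on each side, the frequency class, and the
#' cancer types of cohort B carrying it. Variants private to one cohort are
#' excluded from the records and reported as counts in the attributes.
#'
#' The default key mode is `position_and_alt` when both cohorts carry complete
#' alleles, with a (messaged) fallback to `position_only` when either lacks
#' them.
#'
#' @param a,b two [mito_cohort()] objects.
#' @param mode `"auto"`, `"position_and_alt"` or `"position_only"`.
#' @return A tibble, one row per shared key sorted by position, with columns
#'   `key`, `position`, `carriers_a`, `carriers_b`, `frequency_class`,
#'   `cancer_types_b` (list), and attributes `key_mode`, `n_private_a`,
#'   `n_private_b`, `n_union`.
#' @export
intersect_cohorts <- function(a, b, mode = "auto") {
  stopifnot(inherits(a, "mito_cohort"), inherits(b, "mito_cohort"))
  if (identical(mode, "auto")) {
    if (a$key_mode == "position_and_alt" && b$key_mode == "position_and_alt") {
      mode <- "position_and_alt"
    } else {
      mode <- "position_only"
      if (a$key_mode != b$key_mode) {
        message("allele information incomplete; merging on position only")
      }
    }
  } else {
    mode <- match.arg(mode, c("position_and_alt", "position_only"))
    if (mode == "position_and_alt" &&
        (a$key_mode == "position_only" || b$key_mode == "position_only")) {
      stop("position_and_alt merge requires alleles in both cohorts",
        call. = FALSE)
    }
  }
  counts_a <- cohort_carrier_counts(a, mode)
  counts_b <- cohort_carrier_counts(b, mode)
  shared <- sort_keys(intersect(names(counts_a), names(counts_b)))

  sets_b <- cohort_variant_sets(b, mode)
  types_b <- lapply(shared, function(k) {
    sort(names(sets_b)[vapply(sets_b, function(s) k %in% s, logical(1))])
  })
  ca <- unname(counts_a[shared])
  cb <- unname(counts_b[shared])
  out <- tibble::tibble(
    key = shared,
    position = key_position(shared),
    carriers_a = ca,
    carriers_b = cb,
    frequency_class = if (length(shared) > 0L) classify_frequency(ca, cb)
                      else character(0),
    cancer_types_b = types_b
  )
  attr(out, "key_mode") <- mode
  attr(out, "n_private_a") <- length(counts_a) - length(shared)
  attr(out, "n_private_b") <- length(counts_b) - length(shared)
  attr(out, "n_union") <- length(union(names(counts_a), names(counts_b)))
  attr(out, "cohort_a") <- a$name
  attr(out, "cohort_b") <- b$name
  out
}
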