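#' Construct mitochondrial variants
#'
#' A mitochondrial variant is keyed by its 1-based position on the rCRS
#' (1..16569) with optional reference and alternate alleles. Alleles must be
#' given either both or not at all; when present each must match `[ACGTN]+`
#' (single bases for SNVs; unequal lengths represent INDELs).
#'
#' @param position integer vector of 1-based rCRS coordinates.
#' @param ref,alt character vectors of alleles, or `NA` when unknown.
#' @return A tibble with columns `position`, `ref`, `alt` and the canonical
#'   display `label` (`"8584:G>A"` with alleles, `"73"` without).
#' @examples
#' mt_variant(c(8584L, 73L), ref = c("G", NA), alt = c("A", NA))
#' @export
mt_variant <- function(position, ref = NA_character_, alt = NA_character_) {
  position <- assert_rcrs_position(position)
  n <- length(position)
  ref <- toupper(rep_len(as.character(ref), n))
  alt <- toupper(rep_len(as.character(alt), n))
  one_sided <- xor(is.na(ref), is.na(alt))
  if (any(one_sided)) {
    stop("ref and alt alleles must be either both present or both absent",
      call. = FALSE
    )
  }
  ok <- function(x) is.na(x) | grepl("^[ACGTN]+$", x)
  if (!all(ok(ref)) || !all(ok(alt))) {
    stop("alleles must match [ACGTN]+", call. = FALSE)
  }
  tibble::tibble(
    position = position, ref = ref, alt = alt,
    label = variant_label(position, ref, alt)
  )
}

#' Canonical display label of a variant
#'
#' The label is a pure function of (position, ref, alt): `"<pos>:<ref>><alt>"`
#' when alleles are present, otherwise the bare position.
#'
#' @inheritParams mt_variant
#' @return Character vector of labels.
#' @export
variant_label <- function(position, ref = NA_character_, alt = NA_character_) {
  position <- assert_rcrs_position(position)
  ifelse(is.na(ref) | is.na(alt),
    as.character(position),
    paste0(position, ":", ref, ">", alt)
  )
}

#' Merge key of a variant
#'
#' Two cohorts can be merged on position alone (`"position_only"`) or on
#' position plus alternate allele (`"position_and_alt"`); the key is the string
#' identity under the chosen mode and is stable across runs.
#'
#' @inheritParams mt_variant
#' @param mode `"position_only"` or `"position_and_alt"`.
#' @return Character vector of keys (`"73"` or `"8584:G>A"`).
#' @examples
#' variant_key(8584, "G", "A", mode = "position_and_alt")
#' variant_key(73, mode = "position_only")
#' @export
variant_key <- function(position, ref = NA_character_, alt = NA_character_,
                        mode = c("position_and_alt", "position_only")) {
  mode <- match.arg(mode)
  position <- assert_rcrs_position(position)
  if (mode == "position_only") {
    return(as.character(position))
  }
  n <- length(position)
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  if (any(is.na(ref) | is.na(alt))) {
    stop("position_and_alt keys require ref and alt alleles", call. = FALSE)
  }
  paste0(position, ":", toupper(ref), ">", toupper(alt))
}
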