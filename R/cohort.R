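#' Build a cohort from per-sample variant calls
#'
#' A cohort groups variant calls by cancer type and derives, per key mode, the
#' per-cancer variant sets and per-variant carrier counts (distinct samples
#' carrying the variant; a duplicated (sample, variant) pair counts once).
#'
#' @param calls data frame with columns `sample_id`, `cancer_type`, `position`
#'   and optionally `ref`, `alt`, `origin_status` (`somatic`, `germline` or
#'   `unknown`).
#' @param name cohort name used for provenance tags.
#' @return An object of class `mito_cohort` with elements `name`, `calls`
#'   (deduplicated, ordered), `key_mode`, `variant_sets` and `carrier_counts`.
#' @seealso [read_variant_table()], [cohort_variant_sets()],
#'   [cohort_carrier_counts()]
#' @export
mito_cohort <- function(calls, name = "cohort") {
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  required <- c("sample_id", "cancer_type", "position")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(calls) == 0L) {
    stop("cohort has no variant calls", call. = FALSE)
  }
  if (any(!nzchar(calls$sample_id) | is.na(calls$sample_id))) {
    stop("sample_id must be non-empty", call. = FALSE)
  }
  if (any(!nzchar(calls$cancer_type) | is.na(calls$cancer_type))) {
    stop("cancer_type must be non-empty", call. = FALSE)
  }
  if (is.null(calls$ref)) calls$ref <- NA_character_
  if (is.null(calls$alt)) calls$alt <- NA_character_
  if (is.null(calls$origin_status)) calls$origin_status <- "unknown"
  calls$origin_status[is.na(calls$origin_status)] <- "unknown"
  bad_status <- setdiff(unique(calls$origin_status),
                        c("somatic", "germline", "unknown"))
  if (length(bad_status) > 0L) {
    stop("origin_status must be somatic, germline or unknown; got: ",
      paste(bad_status, collapse = ", "), call. = FALSE)
  }
  v <- mt_variant(calls$position, calls$ref, calls$alt)
  calls <- tibble::tibble(
    sample_id = as.character(calls$sample_id),
    cancer_type = as.character(calls$cancer_type),
    position = v$position, ref = v$ref, alt = v$alt,
    origin_status = as.character(calls$origin_status)
  )
  # collapse duplicated (sample, variant) rows and fix a canonical row order
  # so derived fields are invariant under permutation of the input
  dup_key <- paste(calls$sample_id, v$label, sep = "\r")
  calls <- calls[!duplicated(dup_key), , drop = FALSE]
  ord <- order(calls$position, calls$ref, calls$alt,
               calls$cancer_type, calls$sample_id)
  calls <- calls[ord, , drop = FALSE]

  mode <- if (all(!is.na(calls$ref)) && all(!is.na(calls$alt))) {
    "position_and_alt"
  } else {
    "position_only"
  }
  out <- structure(
    list(name = as.character(name), calls = calls, key_mode = mode),
    class = "mito_cohort"
  )
  out$variant_sets <- cohort_variant_sets(out, mode)
  out$carrier_counts <- cohort_carrier_counts(out, mode)
  out
}

resolve_key_mode <- function(cohort, mode) {
  if (identical(mode, "auto")) cohort$key_mode else match.arg(
    mode, c("position_and_alt", "position_only")
  )
}

#' Per-cancer variant sets of a cohort
#'
#' Recomputes the map cancer type -> set of variant keys from the raw calls.
#'
#' @param cohort a `mito_cohort`.
#' @param mode key mode (`"auto"` uses the cohort's resolved mode).
#' @return Named list of sorted character key vectors, one per cancer type.
#' @export
cohort_variant_sets <- function(cohort, mode = "auto") {
  stopifnot(inherits(cohort, "mito_cohort"))
  mode <- resolve_key_mode(cohort, mode)
  keys <- variant_key(cohort$calls$position, cohort$calls$ref,
                      cohort$calls$alt, mode = mode)
  sets <- split(keys, cohort$calls$cancer_type)
  sets <- lapply(sets, sort_keys)
  sets[order(names(sets))]
}

#' Per-variant carrier counts of a cohort
#'
#' Number of distinct samples carrying each variant key (not call counts).
#'
#' @inheritParams cohort_variant_sets
#' @return Named integer vector, keys sorted by position.
#' @export
cohort_carrier_counts <- function(cohort, mode = "auto") {
  stopifnot(inherits(cohort, "mito_cohort"))
  mode <- resolve_key_mode(cohort, mode)
  keys <- variant_key(cohort$calls$position, cohort$calls$ref,
                      cohort$calls$alt, mode = mode)
  pair <- unique(paste(cohort$calls$sample_id, keys, sep = "\r"))
  counts <- table(sub("^.*\r", "", pair))
  out <- setNames(as.integer(counts), names(counts))
  out[sort_keys(names(out))]
}

#' @export
print.mito_cohort <- function(x, ...) {
  cat(sprintf(
    "<mito_cohort '%s'> %d calls, %d samples, %d cancer types, %d variants (%s keys)\n",
    x$name, nrow(x$calls), length(unique(x$calls$sample_id)),
    length(x$variant_sets), length(x$carrier_counts), x$key_mode
  ))
  invisible(x)
}

#' Read a per-sample variant table
#'
#' Reads a cohort from the canonical TSV interchange format (header columns
#' `sample_id`, `cancer_type`, `position`, optionally `ref`, `alt`,
#' `origin_status`) or, as a convenience layer, from a VCF restricted to the
#' mitochondrial contig (`MT`, `chrM` or `NC_012920.1`). VCF ingestion splits
#' multi-allelic records into one call per alternate allele and derives
#' carriers from genotype columns containing that allele; the cancer type is
#' not encoded in VCF and must be supplied.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param name cohort name (defaults to the file name).
#' @param cancer_type cancer type assigned to every VCF sample (ignored for
#'   TSV input).
#' @return A [mito_cohort()].
#' @export
read_variant_table <- function(path, format = c("tsv", "vcf"),
                               name = NULL, cancer_type = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (is.null(name)) name <- sub("\\.(tsv|txt|vcf)$", "", basename(path))
  if (format == "tsv") {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    required <- c("sample_id", "cancer_type", "position")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols) > 0L) {
      stop("missing mandatory column(s): ",
        paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    pos <- suppressWarnings(as.integer(raw$position))
    bad <- which(is.na(pos) | pos < 1L | pos > MT_GENOME_LENGTH)
    if (length(bad) > 0L) {
      # +1 for the header row, so the number matches the physical file line
      stop(sprintf(
        "invalid rCRS position '%s' at line %d of %s",
        raw$position[bad[1]], bad[1] + 1L, path
      ), call. = FALSE)
    }
    raw$position <- pos
    return(mito_cohort(raw, name = name))
  }
  read_variant_vcf(path, name = name, cancer_type = cancer_type)
}

MT_CONTIGS <- c("MT", "chrM", "NC_012920.1")

read_variant_vcf <- function(path, name, cancer_type) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF ingestion requires the 'vcfR' package", call. = FALSE)
  }
  if (is.null(cancer_type) || !nzchar(cancer_type)) {
    stop("cancer_type must be supplied when reading a VCF", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  keep <- fix$CHROM %in% MT_CONTIGS
  if (!any(keep)) {
    stop("VCF contains no records on a mitochondrial contig (",
      paste(MT_CONTIGS, collapse = ", "), ")", call. = FALSE)
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = sum(keep),
                                     dimnames = list(NULL, colnames(vcf@gt)[-1]))
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (j in seq_along(alts)) {
      carried <- vapply(gt[i, ], function(g) {
        if (is.na(g)) return(FALSE)
        any(strsplit(g, "[/|]")[[1]] == as.character(j))
      }, logical(1))
      if (!any(carried)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = names(carried)[carried],
        cancer_type = cancer_type,
        position = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[j],
        origin_status = "unknown"
      )
    }
  }
  if (length(rows) == 0L) {
    stop("no carried mitochondrial variants found in ", path, call. = FALSE)
  }
  mito_cohort(do.call(rbind, rows), name = name)
}
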