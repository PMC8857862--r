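REGION_CATEGORIES <- c(
  protein_coding = 1L, rRNA = 2L, tRNA = 3L,
  control_region = 4L, intergenic = 5L
)

#' Build a region map of the circular mitochondrial genome
#'
#' A region map assigns every rCRS position (1..16569) exactly one primary
#' label. The packaged default holds the 37 canonical mitochondrial genes at
#' their standard rCRS coordinates plus a single control-region feature
#' spanning 16024..576: "D-loop" here covers the whole major noncoding region,
#' wrapping through the origin (encoded as start > end). Positions covered by
#' no feature fall back to the label `"intergenic"`.
#'
#' Overlapping features are allowed (e.g. MT-ATP8/MT-ATP6 share 8527..8572);
#' all matches are reported by [annotate_position()], and the primary label is
#' chosen deterministically by category priority (protein_coding > rRNA > tRNA
#' > control_region), then by an optional numeric `priority` column, then by
#' smaller feature start. Custom maps whose overlapping features cannot be
#' ordered by those rules must carry a `priority` column.
#'
#' @param source `NULL` (or `"default"`) for the packaged map, otherwise a
#'   path to a TSV with columns `name`, `start`, `end`, `category` (1-based
#'   inclusive coordinates, wrap encoded as start > end) and optional
#'   `priority`.
#' @return An object of class `region_map` with elements `genome_length` and
#'   `features` (a tibble).
#' @export
build_region_map <- function(source = NULL) {
  if (is.null(source) || identical(source, "default")) {
    source <- system.file("extdata", "rcrs_regions.tsv", package = "mitonet",
                          mustWork = TRUE)
  }
  if (!file.exists(source)) {
    stop("region map file not found: ", source, call. = FALSE)
  }
  raw <- readr::read_tsv(source, col_types = readr::cols(
    name = "c", start = "i", end = "i", category = "c", .default = "d"
  ), progress = FALSE)
  required <- c("name", "start", "end", "category")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("region map must have column(s): ",
      paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  assert_rcrs_position(raw$start, what = "feature start")
  assert_rcrs_position(raw$end, what = "feature end")
  bad_cat <- setdiff(unique(raw$category), names(REGION_CATEGORIES))
  if (length(bad_cat) > 0L) {
    stop("unknown feature category: ", paste(bad_cat, collapse = ", "),
      call. = FALSE)
  }
  features <- tibble::tibble(
    name = raw$name,
    start = raw$start,
    end = raw$end,
    category = raw$category,
    wraps_origin = raw$start > raw$end,
    priority = if ("priority" %in% names(raw)) raw$priority else NA_real_
  )
  map <- structure(
    list(genome_length = MT_GENOME_LENGTH, features = features),
    class = "region_map"
  )
  validate_region_map(map)
  map
}

# Features whose overlap cannot be resolved by (category rank, priority,
# start) make the primary label ambiguous; reject such maps.
validate_region_map <- function(map) {
  f <- map$features
  n <- nrow(f)
  if (n < 2L) return(invisible(map))
  rank <- REGION_CATEGORIES[f$category]
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (!features_overlap(f[i, ], f[j, ])) next
      tied <- rank[i] == rank[j] && f$start[i] == f$start[j] &&
        (is.na(f$priority[i]) || is.na(f$priority[j]) ||
           f$priority[i] == f$priority[j])
      if (tied) {
        stop(sprintf(
          paste0("overlapping features '%s' and '%s' cannot be ordered; ",
                 "add a priority column"),
          f$name[i], f$name[j]
        ), call. = FALSE)
      }
    }
  }
  invisible(map)
}

# Circular membership of one position in one feature.
position_in_feature <- function(position, start, end, wraps) {
  if (wraps) position >= start | position <= end
  else position >= start & position <= end
}

features_overlap <- function(a, b) {
  # expand each (possibly wrapped) feature to linear segments and test
  segs <- function(x) {
    if (x$wraps_origin) {
      list(c(x$start, MT_GENOME_LENGTH), c(1L, x$end))
    } else {
      list(c(x$start, x$end))
    }
  }
  for (sa in segs(a)) {
    for (sb in segs(b)) {
      if (sa[1] <= sb[2] && sb[1] <= sa[2]) return(TRUE)
    }
  }
  FALSE
}

#' Annotate a single rCRS position
#'
#' Returns every feature containing the position (circular membership, so the
#' wrapped control region contains 16024..16569 and 1..576) and the single
#' deterministic primary label.
#'
#' @param map a [build_region_map()] object.
#' @param position one rCRS position.
#' @return List with `position`, `primary` (label) and `features` (tibble of
#'   all matching features; zero rows means intergenic).
#' @export
annotate_position <- function(map, position) {
  stopifnot(inherits(map, "region_map"), length(position) == 1L)
  position <- assert_rcrs_position(position)
  f <- map$features
  hit <- mapply(position_in_feature, f$start, f$end, f$wraps_origin,
                MoreArgs = list(position = position))
  matches <- f[hit, , drop = FALSE]
  if (nrow(matches) == 0L) {
    primary <- "intergenic"
  } else {
    ord <- order(REGION_CATEGORIES[matches$category],
                 ifelse(is.na(matches$priority), Inf, matches$priority),
                 matches$start)
    primary <- matches$name[ord[1]]
  }
  list(position = position, primary = primary, features = matches)
}

#' Annotate many rCRS positions with their primary region label
#'
#' @param map a [build_region_map()] object.
#' @param positions integer vector of rCRS positions.
#' @return A tibble with columns `position` and `region` (primary label), in
#'   input order.
#' @export
annotate_positions <- function(map, positions) {
  stopifnot(inherits(map, "region_map"))
  positions <- assert_rcrs_position(positions)
  f <- map$features
  # sweep features in primary-preference order; first claim wins
  pref <- order(REGION_CATEGORIES[f$category],
                ifelse(is.na(f$priority), Inf, f$priority),
                f$start)
  region <- rep("intergenic", length(positions))
  open <- rep(TRUE, length(positions))
  for (i in pref) {
    hit <- open & position_in_feature(positions, f$start[i], f$end[i],
                                      f$wraps_origin[i])
    region[hit] <- f$name[i]
    open[hit] <- FALSE
  }
  tibble::tibble(position = positions, region = region)
}

#' Group positions by primary region
#'
#' Every input position is counted under exactly one primary label; the
#' distinct-region count is the number of non-empty labels.
#'
#' @inheritParams annotate_positions
#' @return List with `regions` (named list region -> sorted unique positions,
#'   ordered by first genomic position) and `n_regions`.
#' @export
summarize_regions <- function(map, positions) {
  if (length(positions) == 0L) {
    return(list(regions = setNames(list(), character(0)), n_regions = 0L))
  }
  ann <- annotate_positions(map, positions)
  regions <- lapply(split(ann$position, ann$region), function(p) sort(unique(p)))
  regions <- regions[order(vapply(regions, min, numeric(1)))]
  list(regions = regions, n_regions = length(regions))
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf(
    "<region_map> %d features on a %d-bp circular genome (%d wrapping the origin)\n",
    nrow(x$features), x$genome_length, sum(x$features$wraps_origin)
  ))
  invisible(x)
}
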