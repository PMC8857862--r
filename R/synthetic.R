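#' Configure a synthetic two-cohort simulation
#'
#' Describes two cohorts with known ground truth: a global variant pool drawn
#' from distinct rCRS positions, a reference cancer (cohort A), a panel of
#' other cancer types (cohort B) with per-type variant-set sizes and sample
#' counts, and a planted number of variants forced to be shared between each
#' type and the reference. With `allow_chance_overlap = FALSE` (default) the
#' non-planted variants of every type are drawn from the stratum of the pool
#' disjoint from the reference set, so the realized overlap equals the
#' planted count exactly; with `TRUE` sets are drawn independently from the
#' whole pool and chance collisions may add to it.
#'
#' Per-variant carrier counts are `1 + Poisson(carrier_mean)`, truncated at
#' the type's sample count, so all three carrier-frequency classes occur.
#'
#' @param seed integer seed; generation is fully deterministic given the
#'   config.
#' @param universe_size number of distinct variant positions in the pool
#'   (<= 16569).
#' @param cancer_types data frame with columns `label`, `set_size`,
#'   `n_samples`.
#' @param reference_label,reference_size,reference_samples the reference
#'   cancer of cohort A.
#' @param planted_overlaps named integer vector, number of variants forced
#'   shared with the reference per cancer type (default 0; each must be
#'   <= min(reference_size, that type's set_size)).
#' @param carrier_mean mean of the Poisson excess-carrier distribution.
#' @param allow_chance_overlap allow by-chance collisions with the reference
#'   set?
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed, universe_size = 600L,
                             cancer_types,
                             reference_label = "GC", reference_size = 50L,
                             reference_samples = 13L,
                             planted_overlaps = NULL,
                             carrier_mean = 0.6,
                             allow_chance_overlap = FALSE) {
  cancer_types <- as.data.frame(cancer_types, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "set_size", "n_samples") %in% names(cancer_types)))
  universe_size <- as.integer(universe_size)
  if (universe_size < 1L || universe_size > MT_GENOME_LENGTH) {
    stop("universe_size must lie in 1..16569", call. = FALSE)
  }
  planted <- setNames(rep(0L, nrow(cancer_types)), cancer_types$label)
  if (!is.null(planted_overlaps)) {
    unknown <- setdiff(names(planted_overlaps), names(planted))
    if (length(unknown) > 0L) {
      stop("planted overlap for unknown cancer type(s): ",
        paste(unknown, collapse = ", "), call. = FALSE)
    }
    planted[names(planted_overlaps)] <- as.integer(planted_overlaps)
  }
  feasible_max <- pmin(reference_size, cancer_types$set_size)
  if (any(planted > feasible_max) || any(planted < 0L)) {
    stop("planted overlap must lie in 0..min(reference size, set size)",
      call. = FALSE)
  }
  if (reference_size > universe_size ||
      any(cancer_types$set_size > universe_size)) {
    stop("set sizes cannot exceed universe_size", call. = FALSE)
  }
  if (!allow_chance_overlap &&
      any(cancer_types$set_size - planted > universe_size - reference_size)) {
    stop(paste0("universe too small to keep non-planted variants disjoint ",
                "from the reference set"), call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed), universe_size = universe_size,
      cancer_types = tibble::tibble(
        label = as.character(cancer_types$label),
        set_size = as.integer(cancer_types$set_size),
        n_samples = as.integer(cancer_types$n_samples)
      ),
      reference_label = reference_label,
      reference_size = as.integer(reference_size),
      reference_samples = as.integer(reference_samples),
      planted_overlaps = planted,
      carrier_mean = carrier_mean,
      allow_chance_overlap = isTRUE(allow_chance_overlap)
    ),
    class = "synthetic_config"
  )
}

#' Named simulation presets
#'
#' `"table1-like"` emulates the magnitudes of the published pairwise-overlap
#' table: a pool of 600 variants, a 13-sample reference set of 50 variants,
#' the 22 published cancer-type labels with their printed sample counts
#' (2 is used for the one type whose count was not printed), per-type set
#' sizes spanning 30..200, and planted overlaps equal to each pair's
#' published shared-variant count (1..8). `"toy"` is a pool of 8 variants
#' with two 3-variant cancer types, small enough for exhaustive-enumeration
#' oracles.
#'
#' @param preset `"table1-like"` or `"toy"`.
#' @param seed integer seed.
#' @param planted `"table1"` (preset defaults) or `"none"`, which zeroes all
#'   planted overlaps and draws sets independently from the whole pool
#'   (`allow_chance_overlap = TRUE`) — the null regime used for calibration.
#' @return A [synthetic_config()].
#' @export
synthetic_preset <- function(preset = c("table1-like", "toy"), seed,
                             planted = c("table1", "none")) {
  preset <- match.arg(preset)
  planted <- match.arg(planted)
  if (preset == "toy") {
    cfg <- synthetic_config(
      seed = seed, universe_size = 8L,
      cancer_types = data.frame(
        label = c("X", "Y"), set_size = c(3L, 3L), n_samples = c(3L, 3L)
      ),
      reference_size = 3L, reference_samples = 3L,
      planted_overlaps = if (planted == "table1") c(X = 2L) else NULL,
      allow_chance_overlap = planted == "none"
    )
    return(cfg)
  }
  tab <- load_table1_fixture()
  n_samples <- c(
    "Breast-AdenoCA" = 7L, "Breast-LobularCA" = 1L, "Cervix-SCC" = 1L,
    "CNS-Medullo" = 3L, "CNS-Oligo" = 1L, "ColoRect-AdenoCA" = 2L,
    "Eso-AdenoCA" = 7L, "Head-SCC" = 3L, "Kidney-ChRCC" = 4L,
    "Kidney-RCC" = 9L, "Liver-HCC" = 14L, "Lung-SCC" = 1L,
    "Lymph-BNHL" = 4L, "Lymph-CLL" = 2L, "Ovary-AdenoCA" = 5L,
    "Panc-AdenoCA" = 6L, "Panc-Endocrine" = 2L, "Prost-AdenoCA" = 10L,
    "SoftTissue-Leiomyo" = 1L, "Stomach-AdenoCA" = 1L, "Thy-AdenoCA" = 3L,
    "Uterus-AdenoCA" = 2L
  )
  labels <- sort(tab$cancer_b)
  sizes <- round(seq(30L, 200L, length.out = length(labels)))
  synthetic_config(
    seed = seed, universe_size = 600L,
    cancer_types = data.frame(
      label = labels, set_size = sizes,
      n_samples = unname(n_samples[labels])
    ),
    reference_label = "GC", reference_size = 50L, reference_samples = 13L,
    planted_overlaps = if (planted == "table1") {
      setNames(tab$n_shared, tab$cancer_b)
    } else {
      NULL
    },
    allow_chance_overlap = planted == "none"
  )
}

#' Generate a synthetic cohort pair with known ground truth
#'
#' @param config a [synthetic_config()].
#' @return List with `cohort_a` (the reference cohort), `cohort_b` (the
#'   multi-cancer cohort) — both [mito_cohort()] objects — and `truth`: the
#'   pool (`universe` positions and alleles), the per-cancer position sets,
#'   the planted and realized per-type overlaps with the reference, and the
#'   config.
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    nt <- c("A", "C", "G", "T")
    universe <- sort(sample.int(MT_GENOME_LENGTH, config$universe_size))
    ref_allele <- sample(nt, config$universe_size, replace = TRUE)
    alt_allele <- vapply(ref_allele, function(r) sample(setdiff(nt, r), 1L),
                         character(1))
    pool <- tibble::tibble(position = universe, ref = ref_allele,
                           alt = unname(alt_allele))

    ref_idx <- sort(sample.int(config$universe_size, config$reference_size))
    non_ref_idx <- setdiff(seq_len(config$universe_size), ref_idx)

    draw_calls <- function(idx, label, n_samples, origin) {
      samples <- sprintf("%s_s%02d", label, seq_len(n_samples))
      rows <- lapply(idx, function(i) {
        n_car <- min(n_samples, 1L + rpois(1L, config$carrier_mean))
        tibble::tibble(
          sample_id = sort(sample(samples, n_car)),
          cancer_type = label,
          position = pool$position[i], ref = pool$ref[i], alt = pool$alt[i],
          origin_status = origin
        )
      })
      do.call(rbind, rows)
    }

    sets <- list()
    calls_b <- list()
    for (i in seq_len(nrow(config$cancer_types))) {
      ct <- config$cancer_types[i, ]
      k <- config$planted_overlaps[[ct$label]]
      planted_idx <- if (k > 0L) sort(sample(ref_idx, k)) else integer(0)
      rest_pool <- if (config$allow_chance_overlap) {
        setdiff(seq_len(config$universe_size), planted_idx)
      } else {
        non_ref_idx
      }
      rest_idx <- sort(sample(rest_pool, ct$set_size - k))
      idx <- sort(c(planted_idx, rest_idx))
      sets[[ct$label]] <- pool$position[idx]
      calls_b[[ct$label]] <- draw_calls(idx, ct$label, ct$n_samples, "somatic")
    }

    cohort_a <- mito_cohort(
      draw_calls(ref_idx, config$reference_label,
                 config$reference_samples, "unknown"),
      name = "cohort_a"
    )
    cohort_b <- mito_cohort(do.call(rbind, calls_b), name = "cohort_b")

    ref_positions <- pool$position[ref_idx]
    realized <- vapply(sets, function(s) length(intersect(s, ref_positions)),
                       integer(1))
    list(
      cohort_a = cohort_a,
      cohort_b = cohort_b,
      truth = list(
        pool = pool,
        universe = pool$position,
        universe_keys = variant_key(pool$position, pool$ref, pool$alt),
        reference_label = config$reference_label,
        reference_set = ref_positions,
        sets = sets,
        planted_overlaps = config$planted_overlaps,
        realized_overlaps = realized,
        config = config
      )
    )
  })
}

#' Write a synthetic cohort pair to disk
#'
#' Emits `cohort_a.tsv` and `cohort_b.tsv` in the canonical variant-table
#' schema (so they pass [read_variant_table()] unchanged) and `truth.json`
#' with the planted ground truth. Output is byte-identical across runs for a
#' fixed config.
#'
#' @param sim result of [generate_cohorts()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_cohorts <- function(sim, dir) {
  stopifnot(is.list(sim), !is.null(sim$truth))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(sim$cohort_a$calls, file.path(dir, "cohort_a.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$cohort_b$calls, file.path(dir, "cohort_b.tsv"),
                   progress = FALSE)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  truth$config$cancer_types <- as.data.frame(truth$config$cancer_types)
  truth$pool <- as.data.frame(truth$pool)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
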