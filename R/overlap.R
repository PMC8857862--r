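#' Jaccard index of two variant sets
#'
#' `|A intersect B| / |A union B|`, the pairwise overlap statistic used
#' throughout the package.
#'
#' @param set_a,set_b vectors of variant keys (coerced to character,
#'   de-duplicated). At least one must be non-empty.
#' @return A number in \[0, 1\].
#' @export
jaccard_index <- function(set_a, set_b) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  if (length(a) == 0L && length(b) == 0L) {
    stop("Jaccard index is undefined for two empty sets", call. = FALSE)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Configuration of the randomization test
#'
#' @param n_randomizations number of randomization rounds R (default 100000,
#'   the number used for the published table).
#' @param seed integer seed; a fixed seed makes every result, including scan
#'   ordering and exported files, fully reproducible. `NULL` uses the session
#'   RNG.
#' @param null_model `"size_preserving_resample"` (default): each cancer's
#'   variant set is redrawn uniformly from the variant universe at its
#'   observed cardinality, independently per cancer per round — the direct
#'   randomization of cancer-variant associations conditional on set sizes.
#'   `"degree_preserving_swap"`: double-edge swaps on the full bipartite
#'   network, preserving every variant's and cancer's degree (requires the
#'   full per-cancer set list, see [test_pair()]).
#' @param p_convention `"raw"` (`count / R`; can reach 0 and is the scale on
#'   which the three significance categories are defined) or `"plus_one"`
#'   (`(count + 1) / (R + 1)`; never 0, preferred for calibration work).
#' @return An object of class `permutation_config`.
#' @export
permutation_config <- function(n_randomizations = 100000L, seed = NULL,
                               null_model = c("size_preserving_resample",
                                              "degree_preserving_swap"),
                               p_convention = c("raw", "plus_one")) {
  n_randomizations <- as.integer(n_randomizations)
  if (is.na(n_randomizations) || n_randomizations < 1L) {
    stop("n_randomizations must be >= 1", call. = FALSE)
  }
  structure(
    list(
      n_randomizations = n_randomizations,
      seed = if (is.null(seed)) NULL else as.integer(seed),
      null_model = match.arg(null_model),
      p_convention = match.arg(p_convention)
    ),
    class = "permutation_config"
  )
}

#' Draw one size-preserving randomization of per-cancer variant sets
#'
#' Each cancer receives a uniformly drawn subset of the universe at its
#' original cardinality, drawn independently per cancer.
#'
#' @param universe vector of variant keys forming the sampling frame.
#' @param sizes named integer vector of set sizes, one per cancer.
#' @return Named list of randomized key sets.
#' @export
randomize_variant_sets <- function(universe, sizes) {
  universe <- unique(as.character(universe))
  if (any(sizes > length(universe))) {
    stop("set size exceeds the size of the variant universe", call. = FALSE)
  }
  if (any(sizes < 0L)) stop("set sizes must be non-negative", call. = FALSE)
  lapply(setNames(as.integer(sizes), names(sizes)), function(s) {
    universe[sample.int(length(universe), s)]
  })
}

#' Empirical p-value of an observed Jaccard index
#'
#' Upper-tail probability against a randomization-generated null: ties count
#' as exceeding.
#'
#' @param observed_jc observed Jaccard index.
#' @param null_jcs numeric vector of null-round Jaccard indices (non-empty).
#' @param convention `"raw"` or `"plus_one"` (see [permutation_config()]).
#' @return List with `p_value` and `exceed_count` (number of null values
#'   `>= observed_jc`).
#' @export
empirical_pvalue <- function(observed_jc, null_jcs,
                             convention = c("raw", "plus_one")) {
  convention <- match.arg(convention)
  if (length(null_jcs) == 0L) {
    stop("null distribution must be non-empty", call. = FALSE)
  }
  count <- sum(null_jcs >= observed_jc)
  r <- length(null_jcs)
  p <- if (convention == "raw") count / r else (count + 1) / (r + 1)
  list(p_value = p, exceed_count = count)
}

#' Significance category of an empirical p-value
#'
#' The three published strata: `"***"` for p <= 1e-6 (attainable at
#' R = 100000 only with an exceed count of 0 under the raw convention),
#' `"**"` for p < 0.01, and `"*"` (not significant) for p >= 0.01 — the
#' boundary p = 0.01 itself is not significant.
#'
#' @param exceed_count number of null rounds with a Jaccard index at or above
#'   the observed one.
#' @param n_randomizations number of rounds R.
#' @param convention p convention; categories are defined on the `"raw"`
#'   scale.
#' @return Character vector of categories.
#' @export
significance_category <- function(exceed_count, n_randomizations,
                                  convention = c("raw", "plus_one")) {
  convention <- match.arg(convention)
  if (any(exceed_count < 0L) || any(exceed_count > n_randomizations)) {
    stop("exceed_count must lie in 0..n_randomizations", call. = FALSE)
  }
  p <- if (convention == "raw") {
    exceed_count / n_randomizations
  } else {
    (exceed_count + 1) / (n_randomizations + 1)
  }
  ifelse(p <= 1e-6, "***", ifelse(p < 0.01, "**", "*"))
}

# Null distribution of the Jaccard index under size-preserving resampling:
# both sets are redrawn uniformly from a universe of size u at their observed
# cardinalities, independently each round. Works on integer indices for speed.
null_jaccard_resample <- function(u, n_a, n_b, r) {
  vapply(seq_len(r), function(i) {
    a <- sample.int(u, n_a)
    b <- sample.int(u, n_b)
    k <- sum(match(b, a, nomatch = 0L) > 0L)
    k / (n_a + n_b - k)
  }, numeric(1))
}

# Null distribution under degree-preserving double-edge swaps on the full
# bipartite cancer-variant incidence structure. A Markov chain is run over the
# 0/1 incidence matrix: after a burn-in of 5|E| accepted-or-rejected proposals,
# one Jaccard value for the focal pair is recorded every |E| proposals.
null_jaccard_swap <- function(sets, label_a, label_b, r) {
  universe <- sort_keys(unique(unlist(sets, use.names = FALSE)))
  inc <- matrix(FALSE, nrow = length(sets), ncol = length(universe),
                dimnames = list(names(sets), universe))
  for (i in seq_along(sets)) inc[i, match(sets[[i]], universe)] <- TRUE
  edge_c <- rep(seq_along(sets), lengths(sets))
  edge_v <- match(unlist(sets, use.names = FALSE), universe)
  n_edges <- length(edge_c)
  if (n_edges < 2L) stop("too few edges for edge swapping", call. = FALSE)
  ia <- match(label_a, names(sets))
  ib <- match(label_b, names(sets))
  n_a <- sum(inc[ia, ])
  n_b <- sum(inc[ib, ])

  propose <- function(n) {
    for (s in seq_len(n)) {
      e <- sample.int(n_edges, 2L)
      c1 <- edge_c[e[1]]; v1 <- edge_v[e[1]]
      c2 <- edge_c[e[2]]; v2 <- edge_v[e[2]]
      if (c1 == c2 || v1 == v2) next
      if (inc[c1, v2] || inc[c2, v1]) next
      inc[c1, v1] <<- FALSE; inc[c2, v2] <<- FALSE
      inc[c1, v2] <<- TRUE;  inc[c2, v1] <<- TRUE
      edge_v[e[1]] <<- v2;   edge_v[e[2]] <<- v1
    }
  }
  propose(5L * n_edges)
  vapply(seq_len(r), function(i) {
    propose(n_edges)
    k <- sum(inc[ia, ] & inc[ib, ])
    k / (n_a + n_b - k)
  }, numeric(1))
}

#' Randomization test of the variant-set overlap of one cancer pair
#'
#' Computes the observed Jaccard index of the two sets and its empirical
#' p-value over `config$n_randomizations` randomization rounds. Under the
#' default null model both sets are redrawn from the universe at their
#' observed sizes each round; under the degree-preserving swap null the full
#' per-cancer set list must be supplied via `network_sets` and the bipartite
#' incidence structure is rewired by double-edge swaps.
#'
#' @param set_a,set_b variant-key sets of the two cancers (subsets of
#'   `universe`).
#' @param universe the sampling frame; defaults to the union of all supplied
#'   sets. A user-supplied superset (e.g. the full merged variant universe) is
#'   accepted.
#' @param config a [permutation_config()].
#' @param cancer_a,cancer_b labels for the output row.
#' @param network_sets named list of all per-cancer sets (must include both
#'   labels); required for the swap null.
#' @return One-row tibble with columns `cancer_a`, `cancer_b`, `n_a`, `n_b`,
#'   `n_shared`, `jaccard`, `p_value` (under `config$p_convention`), `p_raw`,
#'   `p_plus_one`, `exceed_count`, `n_randomizations`, `significance` (stars,
#'   from the raw convention) and `shared_variants` (list column, sorted by
#'   position).
#' @export
test_pair <- function(set_a, set_b, universe = NULL,
                      config = permutation_config(),
                      cancer_a = "A", cancer_b = "B", network_sets = NULL) {
  stopifnot(inherits(config, "permutation_config"))
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  if (length(a) == 0L || length(b) == 0L) {
    stop("both variant sets must be non-empty", call. = FALSE)
  }
  if (is.null(universe)) {
    universe <- if (!is.null(network_sets)) {
      unique(unlist(network_sets, use.names = FALSE))
    } else {
      union(a, b)
    }
  }
  universe <- unique(as.character(universe))
  if (!all(a %in% universe) || !all(b %in% universe)) {
    stop("variant sets must be subsets of the universe", call. = FALSE)
  }
  shared <- sort_keys(intersect(a, b))
  observed <- jaccard_index(a, b)
  r <- config$n_randomizations

  null_jcs <- with_seed(config$seed, {
    if (config$null_model == "size_preserving_resample") {
      null_jaccard_resample(length(universe), length(a), length(b), r)
    } else {
      if (is.null(network_sets) ||
          !all(c(cancer_a, cancer_b) %in% names(network_sets))) {
        stop(paste0("the degree-preserving swap null requires network_sets ",
                    "containing both cancer labels"), call. = FALSE)
      }
      null_jaccard_swap(network_sets, cancer_a, cancer_b, r)
    }
  })
  raw <- empirical_pvalue(observed, null_jcs, "raw")
  plus <- empirical_pvalue(observed, null_jcs, "plus_one")
  tibble::tibble(
    cancer_a = cancer_a, cancer_b = cancer_b,
    n_a = length(a), n_b = length(b), n_shared = length(shared),
    jaccard = observed,
    p_value = if (config$p_convention == "raw") raw$p_value else plus$p_value,
    p_raw = raw$p_value, p_plus_one = plus$p_value,
    exceed_count = raw$exceed_count, n_randomizations = r,
    significance = significance_category(raw$exceed_count, r, "raw"),
    shared_variants = list(shared)
  )
}

#' Overlap scan of a reference cancer against all others
#'
#' Tests the reference variant set against every other cancer type that
#' shares at least one variant with it, one published-table-style row per
#' pair. Rows are ordered by p-value ascending, then Jaccard index
#' descending, then label; a Bonferroni-adjusted column over the tested pairs
#' is appended as supplementary output (the headline p-values are
#' uncorrected).
#'
#' @param sets named list of per-cancer variant-key sets, including the
#'   reference.
#' @param reference label of the reference cancer (e.g. `"GC"`).
#' @param universe sampling frame; defaults to the union of all sets.
#' @param config a [permutation_config()].
#' @return Tibble of [test_pair()] rows plus `p_bonferroni`.
#' @export
overlap_scan <- function(sets, reference, universe = NULL,
                         config = permutation_config()) {
  stopifnot(inherits(config, "permutation_config"))
  if (!reference %in% names(sets)) {
    stop("reference label not found among the variant sets", call. = FALSE)
  }
  ref_set <- unique(as.character(sets[[reference]]))
  if (length(ref_set) == 0L) {
    stop("reference variant set must be non-empty", call. = FALSE)
  }
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  others <- sort(setdiff(names(sets), reference))
  pair_config <- config
  pair_config$seed <- NULL
  rows <- with_seed(config$seed, {
    out <- list()
    for (lab in others) {
      s <- unique(as.character(sets[[lab]]))
      if (length(intersect(ref_set, s)) == 0L) next
      out[[lab]] <- test_pair(ref_set, s, universe = universe,
                              config = pair_config,
                              cancer_a = reference, cancer_b = lab,
                              network_sets = sets)
    }
    out
  })
  if (length(rows) == 0L) {
    return(tibble::tibble())
  }
  res <- do.call(rbind, rows)
  res$p_bonferroni <- pmin(1, res$p_value * nrow(res))
  ord <- order(res$p_value, -res$jaccard, res$cancer_b)
  res[ord, , drop = FALSE]
}

#' Largest number of shared variants over a set of pairs
#'
#' @param results overlap results ([overlap_scan()] output or the packaged
#'   fixture): any tibble with `cancer_b`, `n_shared` and/or
#'   `shared_variants`.
#' @return List with `count` (the maximum) and `cancers` (all cancer types
#'   attaining it, sorted).
#' @export
max_shared <- function(results) {
  if (is.null(results) || nrow(results) == 0L) {
    stop("results must be non-empty", call. = FALSE)
  }
  n <- if (!is.null(results$n_shared)) results$n_shared
       else lengths(results$shared_variants)
  m <- max(n)
  list(count = m, cancers = sort(results$cancer_b[n == m]))
}

#' Variants shared with multiple cancer types
#'
#' Collects the variants appearing in the shared lists of at least
#' `min_cancers` pairs, optionally restricted to statistically significant
#' pairs (categories `"**"` and `"***"`).
#'
#' @param results overlap results or fixture rows with `cancer_b`,
#'   `significance` and `shared_variants`.
#' @param min_cancers minimum number of cancer types (k >= 1).
#' @param significant_only restrict to significant pairs?
#' @return Named list variant -> sorted cancer types, ordered by position;
#'   empty when no variant reaches the threshold.
#' @export
multi_cancer_variants <- function(results, min_cancers = 2L,
                                  significant_only = TRUE) {
  if (min_cancers < 1L) stop("min_cancers must be >= 1", call. = FALSE)
  if (is.null(results) || nrow(results) == 0L) {
    return(setNames(list(), character(0)))
  }
  if (significant_only) {
    results <- results[results$significance %in% c("**", "***"), ,
                       drop = FALSE]
  }
  if (nrow(results) == 0L) {
    return(setNames(list(), character(0)))
  }
  long_variant <- as.character(unlist(results$shared_variants))
  long_cancer <- rep(results$cancer_b, lengths(results$shared_variants))
  by_variant <- lapply(split(long_cancer, long_variant),
                       function(x) sort(unique(x)))
  by_variant <- by_variant[lengths(by_variant) >= min_cancers]
  by_variant[order(key_position(names(by_variant)), names(by_variant))]
}

#' Exact hypergeometric tail of a set overlap
#'
#' Closed-form diagnostic cross-check of the randomization test: under
#' size-preserving uniform resampling from a universe of `universe_size`
#' variants, the shared count of two sets of sizes `n_a` and `n_b` is
#' hypergeometric, so `P(shared >= n_shared)` is available exactly. The
#' headline statistic of the package is the empirical randomization p-value;
#' this is provided for comparison only.
#'
#' @param n_a,n_b set sizes.
#' @param n_shared observed shared count.
#' @param universe_size size of the sampling frame.
#' @return Upper-tail probability.
#' @export
hypergeom_overlap_pvalue <- function(n_a, n_b, n_shared, universe_size) {
  stopifnot(n_a <= universe_size, n_b <= universe_size,
            n_shared <= min(n_a, n_b))
  phyper(n_shared - 1, n_a, universe_size - n_a, n_b, lower.tail = FALSE)
}
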