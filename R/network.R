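#' Build the bipartite mutation-cancer network
#'
#' The network is a graph G(V, E) whose two node classes are mitochondrial
#' variant keys (u) and cancer-type labels (v); an edge records that the
#' variant was reported in that cancer type. Duplicate associations are
#' collapsed (their provenance tags are merged), node sets are derived from
#' the surviving edges, and all outputs use a deterministic lexicographic node
#' ordering.
#'
#' @param associations data frame with columns `variant`, `cancer` and
#'   optionally `source` (provenance tag).
#' @return An object of class `mutation_cancer_network` with elements `edges`
#'   (tibble `variant`, `cancer`, `source`), `variants` and `cancers`.
#' @export
build_network <- function(associations) {
  associations <- as.data.frame(associations, stringsAsFactors = FALSE)
  if (nrow(associations) == 0L) {
    warning("empty association list; returning an empty network")
    edges <- tibble::tibble(variant = character(0), cancer = character(0),
                            source = character(0))
    return(structure(
      list(edges = edges, variants = character(0), cancers = character(0)),
      class = "mutation_cancer_network"
    ))
  }
  missing_cols <- setdiff(c("variant", "cancer"), names(associations))
  if (length(missing_cols) > 0L) {
    stop("associations must have column(s): ",
      paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  variant <- as.character(associations$variant)
  cancer <- as.character(associations$cancer)
  src <- if (!is.null(associations$source)) {
    as.character(associations$source)
  } else {
    rep(NA_character_, length(variant))
  }
  edge_id <- paste(variant, cancer, sep = "\r")
  src_by_edge <- vapply(split(src, edge_id), function(s) {
    s <- sort(unique(s[!is.na(s)]))
    if (length(s) == 0L) NA_character_ else paste(s, collapse = ";")
  }, character(1))
  keep <- !duplicated(edge_id)
  edges <- tibble::tibble(
    variant = variant[keep], cancer = cancer[keep],
    source = unname(src_by_edge[edge_id[keep]])
  )
  edges <- edges[order(edges$variant, edges$cancer), , drop = FALSE]
  net <- structure(
    list(
      edges = edges,
      variants = sort(unique(edges$variant)),
      cancers = sort(unique(edges$cancer))
    ),
    class = "mutation_cancer_network"
  )
  assert_bipartite(net)
  net
}

# A label used on both sides would collapse the two node classes.
assert_bipartite <- function(net) {
  clash <- intersect(net$variants, net$cancers)
  if (length(clash) > 0L) {
    stop("network is not bipartite; label(s) used as both variant and cancer: ",
      paste(utils::head(clash, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(net)
}

#' Derive the mutation-cancer network of a merged cohort pair
#'
#' Convenience constructor: one association per (variant key, cancer type)
#' observed in either cohort, tagged with the cohort name as provenance. The
#' reference cohort enters as one cancer node alongside the other cohort's
#' types.
#'
#' @param a,b two [mito_cohort()] objects.
#' @param mode key mode passed to [cohort_variant_sets()].
#' @return A [build_network()] object.
#' @export
network_from_cohorts <- function(a, b, mode = "auto") {
  stopifnot(inherits(a, "mito_cohort"), inherits(b, "mito_cohort"))
  assoc_of <- function(cohort) {
    sets <- cohort_variant_sets(cohort, mode)
    tibble::tibble(
      variant = unlist(sets, use.names = FALSE),
      cancer = rep(names(sets), lengths(sets)),
      source = cohort$name
    )
  }
  build_network(rbind(assoc_of(a), assoc_of(b)))
}

#' Summarize a mutation-cancer network
#'
#' @param net a [build_network()] object.
#' @return List with `n_variants`, `n_cancers`, `n_edges`, `variant_degree`
#'   and `cancer_degree` (named integer vectors; both sum to `n_edges`).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "mutation_cancer_network"))
  degree_of <- function(labels, col) {
    d <- setNames(integer(length(labels)), labels)
    if (nrow(net$edges) > 0L) {
      tab <- table(net$edges[[col]])
      d[names(tab)] <- as.integer(tab)
    }
    d
  }
  list(
    n_variants = length(net$variants),
    n_cancers = length(net$cancers),
    n_edges = nrow(net$edges),
    variant_degree = degree_of(net$variants, "variant"),
    cancer_degree = degree_of(net$cancers, "cancer")
  )
}

#' Per-cancer variant sets of a network
#'
#' @param net a [build_network()] object.
#' @return Named list cancer type -> sorted variant keys.
#' @export
network_variant_sets <- function(net) {
  stopifnot(inherits(net, "mutation_cancer_network"))
  sets <- lapply(split(net$edges$variant, net$edges$cancer), sort_keys)
  sets[order(names(sets))]
}

#' Export a mutation-cancer network
#'
#' `json_graph` writes node-link JSON consumable by force-directed viewers
#' (top-level `nodes` array with `id` and `kind` in variant/cancer, and
#' `links` array with `source`, `target`, `dataset`); `graphml` writes
#' GraphML; `edge_tsv` writes a three-column edge list that round-trips
#' through [read_network_tsv()] (as does `json_graph` through
#' [read_network_json()]).
#'
#' @param net a [build_network()] object.
#' @param format `"json_graph"`, `"graphml"` or `"edge_tsv"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, format = c("json_graph", "graphml", "edge_tsv"),
                           path) {
  stopifnot(inherits(net, "mutation_cancer_network"))
  format <- match.arg(format)
  if (format != "edge_tsv" && nrow(net$edges) == 0L) {
    stop("cannot export an empty network as ", format, call. = FALSE)
  }
  if (format == "edge_tsv") {
    readr::write_tsv(net$edges, path, progress = FALSE)
  } else if (format == "json_graph") {
    nodes <- tibble::tibble(
      id = c(net$variants, net$cancers),
      kind = rep(c("variant", "cancer"),
                 c(length(net$variants), length(net$cancers)))
    )
    links <- tibble::tibble(
      source = net$edges$variant,
      target = net$edges$cancer,
      dataset = net$edges$source
    )
    jsonlite::write_json(list(nodes = nodes, links = links), path,
                         dataframe = "rows", na = "null", pretty = TRUE)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a mutation-cancer network to an igraph bipartite graph
#'
#' @param net a [build_network()] object.
#' @return An undirected igraph with vertex attributes `kind` and `type`
#'   (logical bipartite class, TRUE for cancer nodes).
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "mutation_cancer_network"))
  vertices <- data.frame(
    name = c(net$variants, net$cancers),
    kind = rep(c("variant", "cancer"),
               c(length(net$variants), length(net$cancers))),
    type = rep(c(FALSE, TRUE),
               c(length(net$variants), length(net$cancers))),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    from = net$edges$variant, to = net$edges$cancer,
    source = net$edges$source, stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Re-import an edge-list TSV as a network
#'
#' @param path file written by [export_network()] with `format = "edge_tsv"`.
#' @return A [build_network()] object.
#' @export
read_network_tsv <- function(path) {
  edges <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  build_network(edges)
}

#' Re-import node-link JSON as a network
#'
#' @param path file written by [export_network()] with `format = "json_graph"`.
#' @return A [build_network()] object.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$links)) {
    stop("not a node-link JSON graph: ", path, call. = FALSE)
  }
  build_network(tibble::tibble(
    variant = obj$links$source,
    cancer = obj$links$target,
    source = if (!is.null(obj$links$dataset)) obj$links$dataset
             else NA_character_
  ))
}

#' @export
print.mutation_cancer_network <- function(x, ...) {
  cat(sprintf(
    "<mutation_cancer_network> %d variant nodes, %d cancer nodes, %d edges\n",
    length(x$variants), length(x$cancers), nrow(x$edges)
  ))
  invisible(x)
}
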