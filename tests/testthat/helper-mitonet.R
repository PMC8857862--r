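# Shared fixture builders. Everything is generated in code at test time.

local_tsv <- function(lines, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  writeLines(lines, path)
  path
}

# Three samples of one cancer type, positions with alleles.
toy_calls <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s1", "s3"),
    cancer_type = c("GC", "GC", "GC", "GC"),
    position = c(73L, 73L, 11719L, 8584L),
    ref = c("A", "A", "G", "G"),
    alt = c("G", "G", "A", "A"),
    origin_status = c("germline", "germline", "somatic", "somatic")
  )
}

toy_cohort <- function(name = "toy") {
  mito_cohort(toy_calls(), name = name)
}

# A cohort from bare (sample, cancer, position) triplets, no alleles.
cohort_from_triplets <- function(samples, cancers, positions, name = "c") {
  mito_cohort(
    tibble::tibble(
      sample_id = samples, cancer_type = cancers, position = positions
    ),
    name = name
  )
}

# Deterministic small multi-cancer variant sets for network/overlap tests.
toy_sets <- function() {
  list(
    GC = c("73", "489", "11719", "16189"),
    X = c("73", "489", "10810"),
    Y = c("11719", "12705"),
    Z = c("14560", "15043")
  )
}
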