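# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. `seed = NULL` leaves the session RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(list = ".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

assert_rcrs_position <- function(position, what = "position") {
  pos <- suppressWarnings(as.integer(position))
  bad <- is.na(pos) | pos < 1L | pos > MT_GENOME_LENGTH
  if (any(bad)) {
    stop(sprintf(
      "%s out of range 1..%d: %s", what, MT_GENOME_LENGTH,
      paste(utils::head(position[bad], 5L), collapse = ", ")
    ), call. = FALSE)
  }
  pos
}

# Numeric prefix of a variant key ("8584:G>A" -> 8584L, "73" -> 73L);
# NA for keys without one.
key_position <- function(keys) {
  suppressWarnings(as.integer(sub(":.*$", "", keys)))
}

# Sort variant keys by genomic position, then lexicographically; keys with no
# positional prefix sort last, lexicographically.
sort_keys <- function(keys) {
  keys <- unique(as.character(keys))
  pos <- key_position(keys)
  keys[order(is.na(pos), pos, keys)]
}
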