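# Internal helpers: seeded evaluation, seed derivation, file digests.

#' Evaluate an expression under a fixed RNG seed
#'
#' Restores the caller's RNG state afterwards so library code never clobbers
#' a user's random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from a global seed
#'
#' Counter-based derivation so pipeline stages can be re-run in isolation.
#' Result is always a positive integer below 2^31.
#' @param seed global integer seed.
#' @param stage stage index (0, 1, 2, ...) or stage name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  x <- (as.numeric(seed) * 48271 + as.numeric(stage) * 16807 + 12345) %%
    2147483647
  as.integer(max(1, x))
}

# md5 of a file (wrapper kept for mocking in tests)
file_digest <- function(path) {
  unname(tools::md5sum(path))
}

# md5 of an R object via its canonical JSON serialization
config_digest <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, null = "null")
  file_digest(tf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
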