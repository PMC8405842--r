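# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so that seeded generators are pure functions of their
#' arguments and never perturb the session RNG.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stage offset, kept inside the
# 32-bit signed-integer range R requires.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1000003 + offset) %% .Machine$integer.max)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# md5 of an arbitrary R object, via its JSON serialization (used for config
# hashes in run manifests; stable across sessions for plain lists).
object_md5 <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

file_md5 <- function(path) unname(tools::md5sum(path))
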