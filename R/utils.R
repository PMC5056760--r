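#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers' random streams are unaffected. With
#' `seed = NULL` the expression runs under the current RNG state.
#'
#' @param seed integer seed or NULL.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    # materialize a RNG state so it can be restored
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Derive a stream-specific child seed from a master seed
#'
#' Deterministic and kept below 2^31 so it is always a valid R integer seed.
#' @keywords internal
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + stream * 10007) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
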