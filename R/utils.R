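# Internal helpers: classed conditions, seed derivation, small numerics.

abort_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("madgan_validation_error", "error")))
}
abort_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("madgan_config_error", "error")))
}
abort_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("madgan_io_error", "error")))
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

#' Derive stage-level seeds from one global seed
#'
#' One experiment seed fans out to independent per-stage seeds (phantom
#' generation, weight initialisation, batch shuffling, interpolation draws,
#' ...) so that stages can be rerun in isolation without seed collisions.
#' The derivation hashes the stage name into an offset; results stay inside
#' the 32-bit range R requires of `set.seed()`.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is_count(seed, min = 0L))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435L + h * 97L) %% 2147483629)
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
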