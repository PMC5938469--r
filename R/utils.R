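# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a string label
#'
#' Quadrat-level null distributions and the synthetic-data generator each use
#' an RNG stream keyed by `(seed, label)`, so results do not depend on the
#' order in which units are processed. The hash is a 31-bit polynomial rolling
#' hash, kept below 2^31 - 1 so it is always a valid R integer seed.
#'
#' @param seed integer master seed.
#' @param label character scalar (e.g. a quadrat id).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(label) == 1L)
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 31 + ch) %% m
  as.integer((h * 69069 + (as.numeric(seed) %% m)) %% m)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)
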