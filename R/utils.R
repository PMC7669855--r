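# Internal helpers: seed handling, deterministic sub-seeds, config hashing.

#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' library code never clobbers the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministically mix a master seed with stream indices into a sub-seed
# below 2^31, so per-subject / per-permutation streams are independent and
# reproducible in isolation.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.numeric(seed) %% 2147483629
  for (k in idx) {
    h <- (h * 48271 + as.numeric(k) * 16807 + 11) %% 2147483629
  }
  as.integer(h + 1)
}

# FNV-1a hash of a string, reported as 8 hex digits; used to stamp result
# files with the configuration they came from.
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
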