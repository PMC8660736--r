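# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All user-facing randomness in the package goes through this so that a seed
# argument is both sufficient and side-effect free.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
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
  }
  force(expr)
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, positive = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) &&
    x >= if (positive) 1 else 0
  if (!ok) {
    stop(sprintf("`%s` must be a single %s integer", name,
                 if (positive) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Derive a stream-specific 32-bit seed from a base seed, so that independent
# stages (corpus, model init, per-epoch shuffles, ...) never share a stream.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
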