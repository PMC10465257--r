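# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic 31-bit hash of a character string (polynomial rolling hash).
# Used to derive per-(rater, image, round) sub-seeds so that adding a rater
# or an image never perturbs the randomness of the others.
string_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

derive_seed <- function(root, ...) {
  parts <- vapply(list(...), function(p) string_hash(as.character(p)), integer(1))
  h <- as.numeric(root) %% 2147483647
  for (p in parts) h <- (h * 48271 + p) %% 2147483647
  as.integer(h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Clip a numeric array to [lo, hi].
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)
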