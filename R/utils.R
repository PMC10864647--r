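# Internal helpers shared across modules.

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Run `expr` under `seed` (if non-NULL) without disturbing the caller's RNG
# stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic child seed derivation, kept below 2^31.
.child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629)
}

.is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min &&
    x == as.integer(x)
}
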