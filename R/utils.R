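# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All seeded generators in the package go through this so that
# calling them never perturbs an enclosing simulation stream.
local_seed <- function(seed, expr) {
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
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-library substream seed from a master seed and a 1-based
# library counter. Fixed affine-mod scheme: adding a library never changes
# the seed of an existing one.
substream_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index), index >= 1)
  as.integer((as.numeric(seed) * 1009 + index) %% 2147483647)
}

stop_param <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Numeric formatting for report files: 6 significant digits, stable.
fmt_num <- function(x) signif(x, 6)
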