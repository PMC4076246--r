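# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive the k-th independent substream seed from one master seed. All
# stochastic stages of the pipeline draw their seed through this, so a run
# is reproducible from a single integer. Kept below 2^31 - 1.
substream <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((abs(as.double(seed)) * 48271 + as.double(k) * 2654435) %%
               2147483646) + 1L
}

# Bound probabilities away from 0 and 1 so logits stay finite.
bound_prob <- function(p, lo = 1e-9, hi = 1 - 1e-9) {
  pmin(pmax(p, lo), hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Skewness of a numeric vector (moment estimator); used by the bootstrap
# symmetry diagnostic.
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  s <- stats::sd(x)
  if (s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}
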