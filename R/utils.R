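# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All exported stochastic entry points
# route their randomness through this so no call mutates global RNG state.
with_rng_seed <- function(seed, expr) {
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
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Geometric mean of linear-scale expression values, computed in log2 space.
geometric_mean <- function(x) 2^mean(log2(x))

# Zero-padded id vectors such as "G0001", "PS00017".
pad_ids <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", max(4L, nchar(n)), "d"), seq_len(n))
}
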