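# Shared internal helpers.

# Deterministic sub-seed derivation: every stochastic stage draws its seed from
# a master seed plus a stage label, so stages are independently reproducible.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Evaluate under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Smooth pseudo-random surface: sum of random plane waves, normalised to unit
# standard deviation over the grid. Used for all synthetic spatial texture.
smooth_field <- function(lon, lat, seed, n_waves = 12L, freq_range = c(0.1, 0.6)) {
  with_seed(seed, {
    u <- runif(n_waves, freq_range[1], freq_range[2]) * sample(c(-1, 1), n_waves, TRUE)
    v <- runif(n_waves, freq_range[1], freq_range[2]) * sample(c(-1, 1), n_waves, TRUE)
    ph <- runif(n_waves, 0, 2 * pi)
    a <- runif(n_waves, 0.5, 1)
    f <- matrix(0, nrow = length(lat), ncol = length(lon))
    for (k in seq_len(n_waves)) {
      f <- f + a[k] * cos(2 * pi * (outer(lat * v[k], lon * u[k], "+")) + ph[k])
    }
    f <- f - mean(f)
    s <- stats::sd(as.vector(f))
    if (s > 0) f <- f / s
    f
  })
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
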