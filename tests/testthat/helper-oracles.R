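# Independent oracles used by several test files. Both are deliberately
# brute-force and share no code with the package's implementations.

# Permutation oracle for the NPPEN probability: reference rows are drawn at
# random with replacement and each drawn row's squared distance to the niche
# centre is recomputed from scratch (explicit quadratic form, no shared code
# with the package's sorted-rank path); the ESI estimate is the fraction of
# draws whose distance exceeds the query's.
nppen_permutation_oracle <- function(reference, x, n_perm = 1e4, seed = 1) {
  X <- as.matrix(reference)
  n <- nrow(X)
  mu <- colMeans(X)
  Sinv <- solve(cov(X))
  qf <- function(v) {
    dv <- v - mu
    drop(t(dv) %*% Sinv %*% dv)
  }
  d2_x <- qf(x)
  set.seed(seed)
  rows <- sample.int(n, n_perm, replace = TRUE)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    if (qf(X[rows[k], ]) > d2_x) hits <- hits + 1L
  }
  hits / n_perm
}

# Sampler for CBI calibration experiments: presences drawn proportionally to
# a known suitability over a discrete uniform background.
cbi_experiment <- function(n = 1000, seed = 1, mode = c("true", "random",
                                                        "reversed")) {
  mode <- match.arg(mode)
  set.seed(seed)
  s_bg <- runif(n)
  pres_idx <- sample.int(n, n, replace = TRUE, prob = s_bg)
  switch(mode,
    true = list(p = s_bg[pres_idx], bg = s_bg),
    reversed = list(p = 1 - s_bg[pres_idx], bg = 1 - s_bg),
    random = list(p = runif(n), bg = runif(n)))
}
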