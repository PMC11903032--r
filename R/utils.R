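# RNG plumbing: every stochastic entry point takes an integer seed and
# derives per-unit substreams deterministically, so toggling one stage (or
# one subject) never shifts another's randomness.

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic substream seed, kept inside 32-bit integer range
derive_seed <- function(seed, index, salt = 0) {
  m <- 2147483629
  s <- (as.double(seed) %% m)
  s <- (s * 48271 + as.double(index) * 16807 + as.double(salt) * 69621) %% m
  as.integer(s) + 1L
}

clamp_r <- function(r, eps = 1e-7) {
  pmin(pmax(r, -1 + eps), 1 - eps)
}

col_vars <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

col_medians <- function(x) col_medians_cpp(as.matrix(x))
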