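# Internal helpers.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so simulation calls are reproducible
# without clobbering the session RNG.
with_seed_local <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific 31-bit sub-seed from a base seed.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 16807) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw one zero-mean Gaussian-process realization over points (x, y) with a
# squared-exponential kernel; uses the current RNG state.
gp_field <- function(x, y, length_scale, sd = 1, jitter = 1e-8) {
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  K <- sd^2 * exp(-d2 / (2 * length_scale^2))
  diag(K) <- diag(K) + jitter * max(sd^2, 1)
  L <- chol(K)
  drop(crossprod(L, stats::rnorm(length(x))))
}
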