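# Seeded RNG helpers. All stochastic operations in the package draw from a
# derived sub-stream so results are pure functions of (inputs, seed) and the
# caller's global RNG state is left untouched.

with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a 31-bit sub-seed from (seed, tag); a stateful counter lets one
# stream produce successive independent draws.
rng_stream <- function(seed, tag = "") {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  s0 <- (abs(as.numeric(seed)) * 48271 + h * 16807) %% (2^31 - 2) + 1
  env <- new.env(parent = emptyenv())
  env$s0 <- s0
  env$counter <- 0
  env
}

rng_next <- function(rng) {
  rng$counter <- rng$counter + 1
  as.integer((rng$s0 + rng$counter * 104729) %% (2^31 - 2) + 1)
}

rand_perm <- function(rng, n) with_seed(rng_next(rng), sample.int(n))

rand_norm <- function(rng, n, sd = 1) with_seed(rng_next(rng), rnorm(n, sd = sd))

rand_unif <- function(rng, n) with_seed(rng_next(rng), runif(n))

# Column-centre a matrix.
centre_cols <- function(m) sweep(m, 2, colMeans(m), "-")
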