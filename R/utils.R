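# Seed plumbing: all randomness in the package flows through these two
# helpers so that every generator is a pure function of its arguments.

# evaluate expr under a local RNG state, restoring the caller's state
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# derive a deterministic 31-bit sub-seed for the i-th draw of a stream
.sub_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + i) %% 2147483647)
}
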