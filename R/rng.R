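# Evaluate code under a fixed RNG seed without disturbing the caller's RNG
# state. All stochastic operations in the package route through this, so
# generators are pure functions of (arguments, seed).
with_seed <- function(seed, code) {
  if (is.na(seed) || seed != floor(seed)) stop("seed must be an integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a parent seed and a stage label, staying within
# the 32-bit signed integer range R requires.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 10007 + h) %% .Machine$integer.max)
}
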