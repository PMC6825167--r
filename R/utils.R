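# Seeded RNG scoped to the calling function: callers get reproducible draws
# without clobbering the user's global RNG stream.
local_rng <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(is.finite(seed))
    withr::local_seed(seed, .local_envir = env)
  }
  invisible(NULL)
}

# Derive a child seed from a master seed; keeps results piecewise
# reproducible (child streams are fixed offsets of the master).
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

`%||%` <- function(x, y) if (is.null(x)) y else x
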