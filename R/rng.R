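# RNG stream management. All seeded entry points use the L'Ecuyer-CMRG
# generator so that one top-level seed yields an arbitrary number of
# independent child streams (one per temporal sequence / grid cell) via
# parallel::nextRNGStream(). The caller's RNG state is always restored.

rng_snapshot <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

rng_restore <- function(snapshot) {
  if (is.null(snapshot)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", snapshot, envir = globalenv())
  }
  invisible(NULL)
}

rng_set_state <- function(state) {
  assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

# Run `expr` with a fresh L'Ecuyer-CMRG stream seeded by `seed`
# (seed = NULL: use the current RNG state as-is).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- rng_snapshot()
  on.exit(rng_restore(old), add = TRUE)
  suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
  set.seed(seed)
  expr
}

# `n` independent child streams derived from `seed`; each element is a
# .Random.seed state vector.
rng_streams <- function(seed, n) {
  old <- rng_snapshot()
  on.exit(rng_restore(old), add = TRUE)
  suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
  set.seed(seed)
  s <- rng_snapshot()
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    streams[[i]] <- s
  }
  streams
}

# Derive `n` plain integer sub-seeds from a top-level seed (for nested
# seeded calls, e.g. one Monte-Carlo estimate per grid cell).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
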