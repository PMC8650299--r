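# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a child seed from a master seed and a stream index; stays inside the
# 32-bit integer range so it is a valid `set.seed()` argument.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 7919) %% 2147483647)
}

# Balanced fold assignment within strata: each stratum's members are shuffled
# and dealt round-robin so fold sizes differ by at most one per stratum.
make_folds <- function(strata, n_folds, seed) {
  n <- length(strata)
  foldid <- integer(n)
  with_seed(seed, {
    for (lev in unique(strata)) {
      idx <- which(strata == lev)
      idx <- idx[sample.int(length(idx))]
      foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  foldid
}

`%||%` <- function(a, b) if (is.null(a)) b else a
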