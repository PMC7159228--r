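# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps package randomness from
# perturbing user scripts.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-trial sub-seed, kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  s <- (abs(as.double(seed)) * 48271 + as.double(index) * 16807) %% 2147483587
  as.integer(s) + 1L
}

canonical_name <- function(x) tolower(trimws(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
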