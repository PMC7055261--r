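# Deterministic sub-seed derivation: keeps every child simulation reproducible
# from one session seed while staying inside 32-bit integer range.
derive_seed <- function(seed, i, salt = 0L) {
  as.integer((as.double(seed) * 1009 + as.double(i) * 7919 + salt) %% 2147483647)
}

# run expr under a local RNG state seeded with `seed`, restoring the caller's
# stream afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
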