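# Seed hygiene: operations that consume randomness take an explicit seed,
# draw from it locally and restore the caller's RNG state afterwards, so that
# identical (inputs, seed) always produce identical output regardless of the
# surrounding session.

local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

with_seed <- function(seed, expr) {
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  expr
}
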