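# Seed handling: every stochastic operation derives a private stream from an
# integer seed so results are reproducible without clobbering the caller's RNG.

# keep derived seeds inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 1009 * as.double(offset)) %% 2147483647)
}

set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
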