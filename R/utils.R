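# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. `seed = NULL` leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed for an independent stream; always in [1, 2^31 - 2]
# so it is a valid 32-bit integer seed.
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(stream) * 12345 + 1
  as.integer(s %% 2147483645) + 1L
}

stop_line <- function(line, fmt, ...) {
  stop(sprintf("line %d: %s", line, sprintf(fmt, ...)), call. = FALSE)
}
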