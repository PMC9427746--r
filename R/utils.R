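#' Derive a child seed from a master seed and a stream label
#'
#' Deterministic 31-bit mixing (Lehmer-style multiplicative congruence) of a
#' master seed with any number of integer or character tokens. Used so that
#' every participant / condition / trial gets its own reproducible stream
#' without consuming the caller's RNG state.
#'
#' @param seed Master integer seed.
#' @param ... Integer or character tokens identifying the stream.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  a <- 48271
  state <- (abs(as.numeric(seed)) %% (m - 1)) + 1
  for (tok in list(...)) {
    ints <- if (is.character(tok)) utf8ToInt(paste(tok, collapse = "/")) else as.numeric(tok)
    for (k in ints) {
      state <- (state * a + (abs(k) %% m) + 1) %% m
      if (state == 0) state <- 1
    }
  }
  as.integer(state)
}

# Evaluate expr with a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# round() that also guards against floating drift in sample counts
.n_samples <- function(duration, rate) as.integer(round(duration * rate))
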