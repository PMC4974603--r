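# Seeded substreams: every stochastic operation derives its own stream from a
# root seed and a stream name, so call order elsewhere cannot perturb results.

#' Derive a substream seed from a root seed and a stream name
#'
#' Combines an integer root seed with a polynomial hash of `name` modulo
#' 2^31 - 1. The result is a valid 32-bit seed for [set.seed()].
#'
#' @param seed integer root seed.
#' @param name character scalar naming the stream.
#' @return an integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name),
            length(name) == 1L)
  m <- 2147483647            # 2^31 - 1, Mersenne prime
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 131 + code) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored on exit.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
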