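#' Derive a named RNG sub-stream seed
#'
#' All randomness in the simulators flows from one explicit integer seed.
#' Components that need independent, individually reproducible randomness
#' (vowel schedule, production noise, observer responses, stimulus roving)
#' derive their own seed from the master seed and a stream name, so that e.g.
#' regenerating the schedule alone gives the same schedule regardless of how
#' much noise was drawn elsewhere.
#'
#' @param seed Master integer seed.
#' @param name Stream name (character scalar).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.character(name), length(name) == 1L)
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + h) %% 2147483647)
}

# Evaluate `expr` under a named sub-stream without disturbing the caller's
# RNG state.
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  expr
}
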