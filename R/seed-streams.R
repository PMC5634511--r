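#' Derive a named substream seed from a root seed
#'
#' All randomness in the package flows from one root seed through named
#' substreams (one per pipeline stage), so each stage is reproducible on its
#' own: the landscape does not change when the survey is re-simulated and
#' vice versa.
#'
#' The substream seed is a deterministic hash of the root seed and the stream
#' name, folded into the non-negative 31-bit integer range R requires.
#'
#' @param seed integer root seed.
#' @param stream character stream name, e.g. `"landscape"`, `"survey"`.
#' @return a single integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' substream_seed(1, "landscape")
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(stream)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
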