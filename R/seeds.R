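#' Derive a per-stream child seed from a master seed
#'
#' Each simulation or resampling stage of the pipeline consumes its own child
#' seed so that adding a generator does not perturb the streams of the
#' others.  The splitting rule is a fixed polynomial hash of the stream name
#' folded with the master seed, reduced modulo 2^31 - 1 (so the result is
#' always a valid 32-bit integer seed).
#'
#' @param master integer master seed.
#' @param stream character scalar naming the stream (e.g. "two_choice").
#' @return an integer seed in [0, 2^31 - 2], deterministic in both arguments.
#' @examples
#' derive_stream_seed(1, "gradient")
#' @export
derive_stream_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.character(stream), length(stream) == 1L)
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (b in utf8ToInt(stream)) h <- (h * 131 + b) %% m
  # doubles hold (m-1)*131 + master exactly; fold master in last
  as.integer((h * 31 + (abs(master) %% m)) %% m)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG
# state.  A NULL seed leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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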