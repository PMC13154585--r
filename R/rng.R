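# Hierarchical RNG streams: one global seed, deterministic per-stage
# sub-seeds, so adding a simulation stage never perturbs earlier streams.

#' Derive a deterministic sub-seed for a named stream
#'
#' Hashes a stream label together with a global seed into an integer seed.
#' Used internally so that each simulation stage consumes its own RNG stream.
#'
#' @param seed Integer global seed.
#' @param stream Character label of the stream (e.g. `"counts"`).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @keywords internal
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% m
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% m)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
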