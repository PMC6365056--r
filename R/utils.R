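#' Derive a reproducible child seed for a named pipeline stage
#'
#' All randomness in a pipeline run flows from one master seed; each stage
#' draws from its own substream so stages can be re-run in isolation without
#' disturbing the others. The child seed is a deterministic hash of the
#' master seed and the stage name, kept below 2^31 so it is a valid R seed.
#'
#' @param seed master integer seed.
#' @param stage character stage label, e.g. "behavior" or "scalars".
#' @return an integer seed.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.integer(seed) %% 2147483647L
  for (ch in utf8ToInt(stage)) {
    # 64-bit-safe multiplicative hash in double precision (31 * h + ch mod p)
    h <- as.integer((31 * as.double(h) + ch) %% 2147483647)
  }
  if (h == 0L) h <- 1L
  h
}

# Evaluate an expression under a local RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
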