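## small internal helpers shared across modules

invlogit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a stage-specific RNG seed from a base seed
#'
#' A single pipeline seed fans out to per-stage seeds by hashing the stage
#' label, so each stage is reproducible in isolation while stages remain
#' statistically independent.
#'
#' @param seed base integer seed.
#' @param label character stage label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  v <- as.numeric(utf8ToInt(label))
  h <- sum(v * seq_along(v)) * 2654435
  as.integer((abs(seed) + h) %% (2^31 - 1))
}

## stop() with sprintf-style formatting, no call in message
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
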