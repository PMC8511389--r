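#' @keywords internal
"_PACKAGE"

# clamp to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' Independent named substreams (plant placement, emergence delays, tiller
#' draws, design candidates, ...) are all derived from one master seed so that
#' seed-matched experiments (e.g. a mixture and its pure references) consume
#' identical random draws. Result is always in `[1, 2^31 - 2]`.
#'
#' @param seed integer master seed.
#' @param stream character stream name.
#' @return integer sub-seed.
#' @export
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483563
  s <- (abs(as.numeric(seed)) %% 2147483563) * 40014 %% 2147483563
  as.integer((s + h) %% 2147483562 + 1)
}

# evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("canomix_invalid", "error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("canomix_degenerate", "error")))
}
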