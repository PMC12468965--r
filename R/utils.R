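#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats rnorm runif rpois rbinom predict var sd quantile setNames
#' @importFrom utils head tail
NULL

# Run code with a temporarily-seeded RNG, restoring the caller's stream.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
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
  force(code)
}

#' Derive a stage-specific seed from a global seed
#'
#' A single pipeline seed fans out to per-stage seeds so that stages can be
#' rerun independently while staying reproducible. The derivation hashes the
#' stage name into a 31-bit integer offset.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  codes <- utf8ToInt(stage)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 1000003L
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647L)
}

# round half away from zero (base round() is half-to-even)
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stop_ctrender <- function(msg, class = "ctrender_error") {
  abort(msg, class = class)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}
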