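#' Derive a stage-specific seed from a global run seed
#'
#' Every stage of a multi-stage run (phantom generation, classifier training,
#' subsampling, ...) draws its seed from the single run seed through this
#' deterministic map, so stages are independently reproducible. The result is
#' always a valid 32-bit R integer seed.
#'
#' @param seed Integer run seed.
#' @param stage Character stage name.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "phantom_1")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647 # 2^31 - 1
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% m
  as.integer((((seed %% m) * 48271) %% m + h) %% m)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_validation <- function(...) {
  stop(..., call. = FALSE)
}
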