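# Seed scoping: run stochastic code under a caller-supplied seed without
# clobbering the session RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a stage seed from a global seed
#'
#' A fixed arithmetic derivation so that pipeline stages can be rerun in
#' isolation while remaining reproducible from one global seed. The result
#' is always a valid 32-bit integer seed.
#'
#' @param global_seed integer master seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 48271 + h * 7919) %% 2147483647)
}
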