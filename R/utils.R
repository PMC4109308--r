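# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive reproducible sub-seeds from a master seed
#'
#' All randomness in the package is funnelled through one master seed per
#' entry point; component seeds (population, trials, resampling) are drawn
#' deterministically from it so that components can be varied independently.
#'
#' @param seed integer master seed.
#' @param n number of sub-seeds to derive.
#' @return integer vector of length `n`, each below 2^31.
#' @keywords internal
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

abort_if <- function(cond, msg) {
  if (cond) rlang::abort(msg)
  invisible(NULL)
}
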