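#' @keywords internal
#' @importFrom minpack.lm nlsLM nls.lm.control
#' @importFrom stats coef residuals predict
"_PACKAGE"

## Run code with a locally seeded RNG, restoring global state afterwards.
## All generators route randomness through this; no generator touches the
## global stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (strict && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  invisible(x)
}
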