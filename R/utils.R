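#' @keywords internal
"_PACKAGE"

## Standard gravity used for body-weight normalization (N/kg).
GRAVITY <- 9.80665

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state on
#' exit, so package functions with a `seed` argument never disturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}
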