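# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_field <- function(field, msg) {
  stop(sprintf("[%s] %s", field, msg), call. = FALSE)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(name, "must be a single finite number")
  if (positive && x <= 0) stop_field(name, "must be positive")
  invisible(x)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic stream splitting for per-participant / per-stage randomness.
#' Kept strictly below 2^31 so the result is a valid R integer seed.
#'
#' @param master master seed (integer-valued scalar).
#' @param index non-negative stream index.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 65011 + 1) * 32749 + as.numeric(index)) %% 2147483629L
}

# evaluate expr under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
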