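#' Round half away from zero
#'
#' Reporting helper matching the usual "commercial" rounding of published
#' tables (R's `round()` rounds half to even, so `round(28.25, 1)` is 28.2,
#' not 28.3).  Full precision is always retained internally; this is applied
#' only when a value is surfaced in a report or a derived cut-off.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up (half away from zero for negative values).
#' @export
#' @examples
#' round_half_up(28.25, 1) # 28.3
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Evaluate code with a fixed RNG seed, restoring the caller's RNG state.
# Used by every seeded operation so library calls never clobber user RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Stop with a consistent message when a scalar argument is out of range.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict = c(TRUE, TRUE)) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  lo_ok <- if (strict[1]) x > lower else x >= lower
  hi_ok <- if (strict[2]) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("'%s' = %g is outside (%g, %g)", name, x, lower, upper),
         call. = FALSE)
  invisible(x)
}
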