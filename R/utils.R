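#' Round half away from zero
#'
#' Reporting-boundary rounding used for all printed indices and angles:
#' ties are rounded away from zero (0.245 -> 0.25, -0.965 -> -0.97),
#' unlike [round()]'s round-half-even. Internal arithmetic is always kept
#' at full precision; rounding is applied only when tables are printed or
#' exported.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(c(0.245, -0.245, 2.5), c(2, 2, 0))
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small relative guard so values stored as ...49999999 (FP artifacts of
  # decimal inputs) still round up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# run code with a temporary RNG state; the caller's .Random.seed survives
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar_prob <- function(x, name, lo = 0, hi = 1, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    if (open) (x > lo && x < hi) else (x >= lo && x <= hi)
  if (!ok) {
    bounds <- if (open) sprintf("(%g, %g)", lo, hi) else sprintf("[%g, %g]", lo, hi)
    stop(sprintf("'%s' must be a single number in %s", name, bounds), call. = FALSE)
  }
  invisible(x)
}
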