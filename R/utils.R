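#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used for
#' every percentage and lift printed in reports; `base::round()` rounds ties
#' to even, which disagrees on exact .5 boundaries such as 37.25 -> 37.3).
#' Internal statistics are always kept at full precision; this applies only
#' at the formatting layer.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half-up (half-down for negatives).
#' @export
#' @examples
#' round_half_up(c(37.25, 1.15, 2.249), 1)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# stopifnot() with a formatted message
.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}
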