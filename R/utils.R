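#' @useDynLib jdnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Classed errors so pipeline drivers can catch specific failure modes.
jdnet_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "jdnet_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Round half away from zero
#'
#' Rounding convention used wherever a real quantity (Doane's bin count, the
#' edge budget of a fixed-density network) is mapped to "the nearest
#' integer". `base::round()` rounds half to even; half-away-from-zero is the
#' convention adopted here and ties are measure-zero for the quantities
#' involved.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Population (biased) skewness m3 / m2^(3/2); 0 for constant input.
moment_skewness <- function(x) {
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 <= 0) return(0)
  mean((x - mu)^3) / m2^1.5
}
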