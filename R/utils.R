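#' @keywords internal
#' @useDynLib cephvote, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

stopf <- function(fmt, ..., class = "cephvote_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)

#' Derive a stream of child seeds from one master seed
#'
#' All stochastic steps in the package draw their seeds from a single master
#' seed through this helper, so an entire train/detect/evaluate pipeline is
#' reproducible from one integer.  Child seeds stay below 2^31 - 1.
#'
#' @param seed master seed (single integer).
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is_count(n) || n == 0)
  if (n == 0) return(integer(0))
  a <- 16807  # minstd multiplier: a * s stays exact in double precision
  m <- 2147483647
  s <- as.double(seed %% m)
  out <- integer(n)
  for (i in seq_len(n)) {
    s <- (a * s + 12345 + i) %% m
    out[i] <- as.integer(s)
  }
  out
}
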