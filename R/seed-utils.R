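#' Derive a reproducible child seed from a top-level seed
#'
#' Deterministic substream derivation: a top-level seed plus a short key
#' path (replicate index, cell index, ...) is mixed into a new 31-bit seed
#' with a Lehmer-style multiplicative congruence. Identical keys always give
#' identical child seeds, so any subset of a simulated study (one replicate,
#' one cell) can be regenerated in isolation.
#'
#' All arithmetic stays below 2^53 so the derivation is exact in double
#' precision; keys must be non-negative integers below 2^21.
#'
#' @param seed integer(1) top-level seed.
#' @param ... integer keys identifying the substream (at least one).
#' @return integer(1) in [1, 2^31 - 2].
#' @examples
#' childSeed(1, 2, 3)
#' @export
childSeed <- function(seed, ...) {
  keys <- c(...)
  stopifnot(length(keys) >= 1, all(is.finite(keys)), all(keys >= 0),
            all(keys < 2^21))
  m <- 2147483647 # 2^31 - 1, prime
  x <- (abs(as.numeric(seed)) %% m)
  for (k in keys) {
    x <- (x * 48271 + ((as.numeric(k) + 1) * 2654435761) %% m + 1) %% m
  }
  as.integer(x + 1)
}

# wrap angle(s) to (-pi, pi]
wrapAngle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}
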