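#' Derive reproducible sub-seeds from a master seed
#'
#' All randomness in a pipeline run flows from one master seed. Sub-seeds
#' for the independent random stages (stimulus synthesis, peripheral
#' discharge generation, each GA repeat) are drawn by seeding R's default
#' generator with the master seed and sampling integers below 2^31 - 1.
#' The rule is purely positional: the k-th sub-seed depends only on
#' \code{master} and \code{k}.
#'
#' @param master integer master seed.
#' @param n number of sub-seeds to derive.
#' @return integer vector of length \code{n}.
#' @export
#' @examples
#' deriveSeeds(1, 3)
deriveSeeds <- function(master, n) {
  stopifnot(length(master) == 1L, is.finite(master), n >= 1)
  withr::with_seed(as.integer(master),
                   sample.int(.Machine$integer.max - 1L, n))
}

#' Index of the bank channel nearest a frequency
#'
#' Nearest on the logarithmic axis, matching the tonotopic spacing of the
#' bank. Ties resolve to the lower channel index.
#'
#' @param freq frequency in Hz.
#' @param bank a [ChannelBank-class].
#' @return integer channel index.
#' @export
#' @examples
#' nearestChannel(5000, cfGrid())
nearestChannel <- function(freq, bank) {
  stopifnot(is(bank, "ChannelBank"), freq > 0)
  d <- abs(log2(bank@cf) - log2(freq))
  which(d == min(d))[1]
}

## internal: uniform octave axis for n channels spanning `octaves`
.octaveAxis <- function(n, octaves) {
  seq(0, octaves, length.out = n)
}

.assertScalar <- function(x, name) {
  if (length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
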