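#' Derive a named substream seed from a master seed
#'
#' Every source of randomness in the package (network wiring, each stimulus,
#' drive noise, k-means initialisation, ...) draws its seed from a single
#' master seed through a named substream, so that a whole experiment is
#' reproducible from one integer and independent components stay decoupled
#' when one of them is re-drawn.
#'
#' The mapping is a small multiplicative-congruential mix (modulus
#' \eqn{2^{31}-1}) of a polynomial hash of the stream name with the master
#' seed; the result is always a valid positive 32-bit seed.
#'
#' @param master integer master seed.
#' @param stream character stream name, e.g. `"network"`, `"stimulus.A"`.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' substreamSeed(1, "network")
#' substreamSeed(1, "stimulus.A")
substreamSeed <- function(master, stream) {
  stopifnot(length(master) == 1, is.finite(master), length(stream) == 1)
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (b in utf8ToInt(as.character(stream))) h <- (h * 127 + b) %% m
  h <- (h + (abs(as.numeric(master)) %% m)) %% m
  for (i in 1:3) h <- (h * 48271) %% m  # minstd mixing rounds
  as.integer(h %% (m - 2) + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals do not disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
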