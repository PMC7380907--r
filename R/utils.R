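#' Derive a deterministic sub-seed from a master seed
#'
#' Every stochastic component of the pipeline draws from its own substream
#' derived from one master seed, so a single `--seed` reproduces the whole
#' run. Stays below 2^31 - 1.
#'
#' @param seed Master seed (integer).
#' @param stream Small non-negative integer identifying the component.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647
  s <- (abs(seed) %% m)
  as.integer((s * 69069 + stream * 7919 + 1) %% m)
}

soft_threshold <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

is_positive_definite <- function(m, tol = 1e-10) {
  if (!isSymmetric(unname(m), tol = 1e-8)) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol)
}
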