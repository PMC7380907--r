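#' Per-cell min-max scaler for feature grids
#'
#' Learns, on training grids only, a per-cell min-max map to `[0, 1]`.
#' Constant cells (including the structural-zero blocks of the grid
#' layout) map to 0; unseen values are clipped to `[0, 1]`.
#'
#' @param grids 18 x 20 x n training array.
#' @return A `grid_scaler` with `min` and `range` matrices.
#' @export
fit_scaler <- function(grids) {
  stopifnot(length(dim(grids)) == 3, dim(grids)[3] >= 1)
  mn <- apply(grids, c(1, 2), min)
  mx <- apply(grids, c(1, 2), max)
  structure(list(min = mn, range = mx - mn), class = "grid_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `grid_scaler`.
#' @return `apply_scaler`: the scaled array (same shape), values in
#'   `[0, 1]`, constant cells 0.
#' @export
apply_scaler <- function(grids, scaler) {
  stopifnot(inherits(scaler, "grid_scaler"))
  single <- length(dim(grids)) == 2
  if (single) grids <- array(grids, c(18, 20, 1))
  n <- dim(grids)[3]
  rng <- scaler$range
  safe_rng <- ifelse(rng > 0, rng, 1)
  out <- grids
  for (s in seq_len(n)) {
    z <- (grids[, , s] - scaler$min) / safe_rng
    z[rng == 0] <- 0
    out[, , s] <- pmin(pmax(z, 0), 1)
  }
  if (single) out[, , 1] else out
}
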