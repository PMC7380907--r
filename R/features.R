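check_calibrated <- function(...) {
  for (s in list(...)) {
    if (any(!is.finite(s)) || any(s < 1 | s > 3))
      stop("domain error: calibrated SIS scores must lie in [1, 3]",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Pairwise relationship signatures
#'
#' The three per-pair signatures computed over calibrated SIS scores
#' `s_i, s_j` in `[1, 3]`:
#' * `rel_interaction`: the interaction term `s_i * s_j` (symmetric,
#'   range 1--9);
#' * `rel_harmonic`: the harmonic mean `2 s_i s_j / (s_i + s_j)`
#'   (symmetric, range 1--3, never above the arithmetic mean);
#' * `rel_tangent`: the tangent of the angle difference,
#'   `tan(atan(s_i) - atan(s_j)) = (s_i - s_j) / (1 + s_i s_j)`
#'   (antisymmetric, range -0.5--0.5), which distinguishes the ordering of
#'   the pair.
#'
#' @param s_i,s_j Calibrated scores in `[1, 3]` (vectorized).
#' @return Numeric signature values.
#' @export
rel_interaction <- function(s_i, s_j) {
  check_calibrated(s_i, s_j)
  s_i * s_j
}

#' @rdname rel_interaction
#' @export
rel_harmonic <- function(s_i, s_j) {
  check_calibrated(s_i, s_j)
  2 * s_i * s_j / (s_i + s_j)
}

#' @rdname rel_interaction
#' @export
rel_tangent <- function(s_i, s_j) {
  check_calibrated(s_i, s_j)
  (s_i - s_j) / (1 + s_i * s_j)
}

#' Canonical SIS item pairs
#'
#' The 105 unordered pairs (i < j) of the 15 SIS items, in lexicographic
#' order; the relationship vector holds the three signatures of each pair
#' consecutively (I, H, T), giving 315 values.
#'
#' @return A 105 x 2 integer matrix.
#' @export
sis_pairs <- function() {
  idx <- which(upper.tri(diag(15)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

#' Position of a relationship feature in the canonical vector
#'
#' @param i,j Item indices with `i < j`.
#' @param type One of `"I"`, `"H"`, `"T"`.
#' @return 1-based position in the 315-length relationship vector.
#' @export
rel_position <- function(i, j, type = c("I", "H", "T")) {
  type <- match.arg(type)
  stopifnot(i >= 1, j <= 15, i < j)
  pairs <- sis_pairs()
  k <- which(pairs[, 1] == i & pairs[, 2] == j)
  3L * (k - 1L) + match(type, c("I", "H", "T"))
}

#' Build the 315-length relationship vector of one subject
#'
#' @param sis_cal 15 calibrated scores in `[1, 3]`.
#' @return Named numeric vector of length 315 (pair-major, types I, H, T
#'   within each pair).
#' @export
build_relationship_vector <- function(sis_cal) {
  if (length(sis_cal) != 15)
    stop("validation error: expected 15 calibrated SIS scores",
         call. = FALSE)
  drop(build_relationship_matrix(matrix(sis_cal, nrow = 1)))
}

#' Relationship vectors for a whole cohort
#'
#' @param sis_cal n x 15 matrix of calibrated scores.
#' @return n x 315 matrix, columns in canonical order.
#' @export
build_relationship_matrix <- function(sis_cal) {
  stopifnot(is.matrix(sis_cal), ncol(sis_cal) == 15)
  check_calibrated(sis_cal)
  pairs <- sis_pairs()
  si <- sis_cal[, pairs[, 1], drop = FALSE]
  sj <- sis_cal[, pairs[, 2], drop = FALSE]
  I <- si * sj
  H <- 2 * si * sj / (si + sj)
  T_ <- (si - sj) / (1 + si * sj)
  out <- matrix(NA_real_, nrow(sis_cal), 315)
  out[, seq(1, 315, 3)] <- I
  out[, seq(2, 315, 3)] <- H
  out[, seq(3, 315, 3)] <- T_
  nm <- character(315)
  for (t in 1:3)
    nm[seq(t, 315, 3)] <- paste0(c("I", "H", "T")[t], "_",
                                 pairs[, 1], "_", pairs[, 2])
  colnames(out) <- nm
  out
}

#' Layout of the 18 x 20 feature grid
#'
#' Row-major flat positions (0-based, matching the grid drawing):
#' 0--14 the calibrated SIS items, 15--28 the 14 confounders, 29--35 seven
#' structural zeros, 36--350 the 315 relationship features, 351--359 nine
#' structural zeros.
#'
#' @return A data.frame with `position` (0-based flat index), `row`, `col`
#'   (1-based), `kind` (`sis`/`confounder`/`zero`/`relationship`), `label`.
#' @export
grid_layout <- function() {
  rel_names <- colnames(build_relationship_matrix(matrix(2, 1, 15)))
  kind <- c(rep("sis", 15), rep("confounder", 14), rep("zero", 7),
            rep("relationship", 315), rep("zero", 9))
  label <- c(sis_labels, cohort_columns$confounders,
             paste0("blank", 1:7), rel_names, paste0("blank", 8:16))
  pos <- 0:359
  data.frame(position = pos, row = pos %/% 20 + 1L, col = pos %% 20 + 1L,
             kind = kind, label = label, stringsAsFactors = FALSE)
}

#' Assemble one subject's 18 x 20 feature grid
#'
#' @param sis_cal 15 calibrated scores.
#' @param confounders 14 numeric confounder values in canonical order
#'   (see [cohort_columns]).
#' @param rel The 315-length relationship vector
#'   ([build_relationship_vector()]).
#' @return An 18 x 20 numeric matrix (row-major fill per [grid_layout()]).
#' @export
assemble_grid <- function(sis_cal, confounders, rel) {
  if (length(sis_cal) != 15 || length(confounders) != 14 ||
      length(rel) != 315)
    stop("validation error: expected 15 SIS + 14 confounders + 315 ",
         "relationship values", call. = FALSE)
  flat <- c(sis_cal, confounders, rep(0, 7), rel, rep(0, 9))
  matrix(flat, nrow = 18, ncol = 20, byrow = TRUE)
}

#' Flatten a grid back to its row-major 360-vector
#' @param grid An 18 x 20 matrix.
#' @return Numeric vector of length 360.
#' @export
flatten_grid <- function(grid) {
  stopifnot(all(dim(grid) == c(18, 20)))
  as.vector(t(grid))
}

#' Feature grids for a preprocessed cohort
#'
#' @param cohort A preprocessed `cohort_table` (calibrated, imputed, dates
#'   encoded).
#' @param use_relationship If `FALSE`, the relationship block is left at
#'   zero (the ablation input: base features only, zero-padded to 18 x 20).
#' @return An 18 x 20 x n array, with `labels` attribute from
#'   [grid_layout()].
#' @export
build_feature_grids <- function(cohort, use_relationship = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(cohort$sis_cal) || any(cohort$mask))
    stop("cohort must be preprocessed (see preprocess_cohort)",
         call. = FALSE)
  n <- n_subjects(cohort)
  conf <- as.matrix(cohort$data[, cohort_columns$confounders])
  storage.mode(conf) <- "double"
  rel <- if (use_relationship) build_relationship_matrix(cohort$sis_cal)
         else matrix(0, n, 315)
  flat <- cbind(cohort$sis_cal, conf, matrix(0, n, 7), rel, matrix(0, n, 9))
  grids <- array(0, dim = c(18, 20, n))
  for (s in seq_len(n)) grids[, , s] <- matrix(flat[s, ], 18, 20, byrow = TRUE)
  attr(grids, "layout") <- grid_layout()
  grids
}

#' Write per-subject flattened grids and the layout sidecar
#'
#' @param grids 18 x 20 x n array from [build_feature_grids()].
#' @param csv_path Output CSV (n rows x 360 columns, canonical labels).
#' @param layout_path Optional JSON layout sidecar.
#' @return `csv_path`, invisibly.
#' @export
write_feature_grids <- function(grids, csv_path, layout_path = NULL) {
  n <- dim(grids)[3]
  flat <- t(vapply(seq_len(n), function(s) flatten_grid(grids[, , s]),
                   numeric(360)))
  colnames(flat) <- grid_layout()$label
  utils::write.csv(as.data.frame(flat), csv_path, row.names = FALSE)
  if (!is.null(layout_path))
    jsonlite::write_json(grid_layout(), layout_path, digits = NA)
  invisible(csv_path)
}
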