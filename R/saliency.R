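#' Linear surrogate model
#'
#' A single-layer linear scorer with known weights, mainly for validating
#' the attribution code against the analytic gradient `w (*) x`.
#'
#' @param weights 18 x 20 x 2 array (per-class weight grids: nonlethal,
#'   lethal).
#' @param bias Length-2 numeric.
#' @return An `intentnet_model` of kind `"linear"`.
#' @export
linear_surrogate <- function(weights, bias = c(0, 0)) {
  stopifnot(all(dim(weights) == c(18, 20, 2)), length(bias) == 2)
  structure(list(kind = "linear",
                 model = list(weights = weights, bias = bias),
                 scaler = NULL, uses_relationship_features = NA),
            class = "intentnet_model")
}

linear_logits <- function(model, grids) {
  if (length(dim(grids)) == 2) grids <- array(grids, c(18, 20, 1))
  n <- dim(grids)[3]
  W <- model$model$weights
  t(vapply(seq_len(n), function(s)
    c(sum(W[, , 1] * grids[, , s]), sum(W[, , 2] * grids[, , s])) +
      model$model$bias,
    numeric(2)))
}

#' Gradient*Input attribution
#'
#' Elementwise product of the input grid with the gradient of the
#' target-class pre-softmax score with respect to the input. Structural-
#' zero cells therefore always receive importance exactly 0. Supports the
#' E-GONet CNN and the linear surrogate; other model kinds are not
#' differentiable here.
#'
#' @param model A fitted `intentnet_model` of kind `"egonet"` or
#'   `"linear"`.
#' @param grids 18 x 20 matrix or 18 x 20 x n array.
#' @param target_class Per-subject target class (0 = nonlethal,
#'   1 = lethal), recycled.
#' @return 18 x 20 matrix (single grid) or 18 x 20 x n array of signed
#'   importances.
#' @export
gradient_x_input <- function(model, grids, target_class = 1L) {
  single <- length(dim(grids)) == 2
  if (single) grids <- array(grids, c(18, 20, 1))
  n <- dim(grids)[3]
  target <- as.integer(rep_len(target_class, n))
  stopifnot(all(target %in% 0:1))
  if (model$kind == "linear") {
    out <- grids
    for (s in seq_len(n))
      out[, , s] <- model$model$weights[, , target[s] + 1] * grids[, , s]
  } else if (model$kind == "egonet") {
    x <- grids_to_input(grids)
    fw <- egonet_forward(model$params, x, keep_cache = TRUE)
    dlogits <- matrix(0, n, 2)
    dlogits[cbind(seq_len(n), target + 1L)] <- 1
    g <- egonet_backward(model$params, fw$cache, dlogits,
                         input_grad = TRUE)
    out <- array(g$dx, c(18, 20, n)) * grids
  } else {
    stop("unsupported model kind for Gradient*Input: ", model$kind,
         call. = FALSE)
  }
  if (single) out[, , 1] else out
}

#' Class-averaged importance maps
#'
#' The two-stage average of the source procedure: per cross-validation
#' fold, Gradient*Input maps of that fold's held-out subjects are averaged
#' within each class; the fold means are then averaged into the final
#' per-class map. Folds without members of a class are skipped for that
#' class, with a flag.
#'
#' @param models List of fitted fold models (one per fold).
#' @param grids 18 x 20 x n array the folds index into (already scaled as
#'   each fold's model expects, or raw when models carry no scaler).
#' @param labels Logical outcomes.
#' @param folds Integer fold assignment (1..length(models)).
#' @param target `"true"` (default: gradient of each subject's true-class
#'   logit) or `"predicted"`.
#' @return An `importance_map`: `nonlethal` and `lethal` 18 x 20 matrices,
#'   `flags`, `provenance`.
#' @export
class_averaged_importance <- function(models, grids, labels, folds,
                                      target = c("true", "predicted")) {
  target <- match.arg(target)
  labels <- as.logical(labels)
  k <- length(models)
  stopifnot(max(folds) <= k)
  sums <- list(nonlethal = matrix(0, 18, 20), lethal = matrix(0, 18, 20))
  counts <- c(nonlethal = 0, lethal = 0)
  flags <- character(0)
  for (f in seq_len(k)) {
    idx <- which(folds == f)
    if (length(idx) == 0) next
    g <- grids[, , idx, drop = FALSE]
    if (!is.null(models[[f]]$scaler)) g <- apply_scaler(g, models[[f]]$scaler)
    if (length(dim(g)) == 2) g <- array(g, c(18, 20, 1))
    tc <- if (target == "true") as.integer(labels[idx])
          else as.integer(predict(models[[f]], g)$class)
    imp <- gradient_x_input(models[[f]], g, tc)
    for (cls in c("nonlethal", "lethal")) {
      members <- if (cls == "lethal") labels[idx] else !labels[idx]
      if (!any(members)) {
        flags <- c(flags, sprintf("fold %d: no %s cases, skipped", f, cls))
        next
      }
      m <- apply(imp[, , members, drop = FALSE], c(1, 2), mean)
      sums[[cls]] <- sums[[cls]] + m
      counts[cls] <- counts[cls] + 1
    }
  }
  structure(
    list(nonlethal = sums$nonlethal / max(counts["nonlethal"], 1),
         lethal = sums$lethal / max(counts["lethal"], 1),
         flags = flags,
         provenance = list(n_folds = k, target = target,
                           folds_used = counts)),
    class = "importance_map")
}

#' Write per-class importance grids as CSV
#'
#' @param map An `importance_map`.
#' @param nonlethal_path,lethal_path Output CSV paths (18 x 20 grids with
#'   layout labels as a header comment column order).
#' @return Invisibly, the two paths.
#' @export
write_importance_csv <- function(map, nonlethal_path, lethal_path) {
  for (p in list(c("nonlethal", nonlethal_path), c("lethal", lethal_path))) {
    m <- map[[p[1]]]
    utils::write.csv(as.data.frame(m), p[2], row.names = FALSE)
  }
  invisible(c(nonlethal_path, lethal_path))
}
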