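# Comparison models sharing the E-GONet preprocessing contract: both
# consume the flattened 360-cell grid (or any numeric feature matrix), so
# model comparisons isolate the architecture rather than the features.

#' Train a baseline lethality classifier
#'
#' * `kind = "linreg"`: least squares on the 0/1 target, class at a 0.5
#'   threshold (the classical "linear regression" classifier; a logistic
#'   fit is available via `logistic = TRUE`). A rank-deficient design
#'   (structural-zero columns are always constant) is solved with a ridge
#'   jitter of 1e-8, with a warning.
#' * `kind = "rf"`: a bagged CART forest (gini splits,
#'   `mtry = floor(sqrt(p))`, default 500 trees); the predicted
#'   probability is the mean of the trees' leaf class fractions.
#'
#' @param features n x p numeric matrix (e.g. flattened grids via
#'   [build_feature_grids()] + [flatten_grid()]), or an 18 x 20 x n array.
#' @param labels Logical or 0/1 outcome, `TRUE` = lethal.
#' @param kind `"linreg"` or `"rf"`.
#' @param seed RNG seed (rf bootstrap / feature sampling).
#' @param n_trees,min_node,max_depth,mtry Forest hyperparameters.
#' @param logistic Use logistic instead of least-squares regression.
#' @return An `intentnet_model`.
#' @export
train_baseline <- function(features, labels, kind = c("linreg", "rf"),
                           seed = 1, n_trees = 500, min_node = 5,
                           max_depth = 25, mtry = NULL, logistic = FALSE) {
  kind <- match.arg(kind)
  X <- grids_to_flat(features)
  y <- as.numeric(labels)
  stopifnot(nrow(X) == length(y), all(y %in% 0:1))
  if (kind == "linreg") {
    Xd <- cbind(`(intercept)` = 1, X)
    if (logistic) {
      keep <- c(TRUE, apply(X, 2, stats::sd) > 0)
      fit <- suppressWarnings(stats::glm.fit(Xd[, keep, drop = FALSE], y,
                                             family = stats::binomial()))
      beta <- numeric(ncol(Xd)); beta[keep] <- fit$coefficients
      beta[is.na(beta)] <- 0
      model <- list(beta = beta, logistic = TRUE)
    } else {
      qr_ <- qr(Xd)
      if (qr_$rank < ncol(Xd)) {
        warning("singular design; solving with ridge jitter 1e-8")
        beta <- solve(crossprod(Xd) + 1e-8 * diag(ncol(Xd)),
                      crossprod(Xd, y))
      } else {
        beta <- qr.coef(qr_, y)
      }
      model <- list(beta = as.numeric(beta), logistic = FALSE)
    }
    return(structure(list(kind = "linreg", model = model, scaler = NULL,
                          uses_relationship_features = NA),
                     class = "intentnet_model"))
  }
  set.seed(derive_seed(seed, 31))
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  trees <- vector("list", n_trees)
  n <- nrow(X)
  for (t in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- cart_build(X[boot, , drop = FALSE], y[boot], mtry,
                             min_node, max_depth)
  }
  structure(list(kind = "rf", model = list(trees = trees, mtry = mtry,
                                           n_trees = n_trees),
                 scaler = NULL, uses_relationship_features = NA),
            class = "intentnet_model")
}

predict_baseline <- function(object, X) {
  if (object$kind == "linreg") {
    s <- drop(cbind(1, X) %*% object$model$beta)
    if (object$model$logistic) s <- 1 / (1 + exp(-s))
    return(pmin(pmax(s, 0), 1))
  }
  preds <- vapply(object$model$trees, function(tr) cart_predict(tr, X),
                  numeric(nrow(X)))
  if (nrow(X) == 1) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

# --- minimal CART (gini, binary target), stored as parallel vectors ---

cart_best_split <- function(x, y) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(y)
  cum1 <- cumsum(ys)
  tot1 <- cum1[n]
  k <- seq_len(n - 1)
  valid <- xs[k] < xs[k + 1]
  if (!any(valid)) return(NULL)
  nl <- k; nr <- n - k
  l1 <- cum1[k]; r1 <- tot1 - l1
  gini <- nl * (1 - (l1 / nl)^2 - (1 - l1 / nl)^2) +
          nr * (1 - (r1 / nr)^2 - (1 - r1 / nr)^2)
  gini[!valid] <- Inf
  best <- which.min(gini)
  list(threshold = (xs[best] + xs[best + 1]) / 2, gini = gini[best])
}

cart_build <- function(X, y, mtry, min_node, max_depth) {
  feature <- integer(0); threshold <- numeric(0)
  left <- integer(0); right <- integer(0); prob <- numeric(0)
  new_node <- function() {
    feature[length(feature) + 1] <<- NA_integer_
    threshold[length(threshold) + 1] <<- NA_real_
    left[length(left) + 1] <<- 0L; right[length(right) + 1] <<- 0L
    prob[length(prob) + 1] <<- NA_real_
    length(feature)
  }
  grow <- function(idx, depth) {
    id <- new_node()
    ny <- y[idx]
    prob[id] <<- mean(ny)
    if (length(idx) < 2 * min_node || depth >= max_depth ||
        all(ny == ny[1])) return(id)
    feats <- sample.int(ncol(X), min(mtry, ncol(X)))
    best <- NULL; best_f <- NA_integer_
    for (f in feats) {
      sp <- cart_best_split(X[idx, f], ny)
      if (!is.null(sp) && (is.null(best) || sp$gini < best$gini)) {
        best <- sp; best_f <- f
      }
    }
    if (is.null(best)) return(id)
    go_left <- X[idx, best_f] <= best$threshold
    if (sum(go_left) < min_node || sum(!go_left) < min_node) return(id)
    feature[id] <<- best_f
    threshold[id] <<- best$threshold
    left[id] <<- grow(idx[go_left], depth + 1)
    right[id] <<- grow(idx[!go_left], depth + 1)
    id
  }
  grow(seq_along(y), 0)
  list(feature = feature, threshold = threshold, left = left,
       right = right, prob = prob)
}

cart_predict <- function(tree, X) {
  n <- nrow(X)
  node <- rep(1L, n)
  active <- !is.na(tree$feature[node])
  while (any(active)) {
    idx <- which(active)
    f <- tree$feature[node[idx]]
    thr <- tree$threshold[node[idx]]
    xv <- X[cbind(idx, f)]
    node[idx] <- ifelse(xv <= thr, tree$left[node[idx]],
                        tree$right[node[idx]])
    active <- !is.na(tree$feature[node])
  }
  tree$prob[node]
}
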