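# --- E-GONet: a small convolutional classifier on 18x20 feature grids ---
#
# Architecture (fixed topology, tunable sizes): three 3x3 same-padded
# convolution layers (channels c1, c2, c3) with rectified-linear
# activations, 2x2 max-pooling after layers 1 and 2, then two fully
# connected layers (width fc -> 2) with dropout after the first, softmax
# cross-entropy loss, Adam (or plain SGD) optimizer. Implemented in pure R
# via im2col + BLAS matrix multiplications; backpropagation reaches the
# input grid, which the saliency module reuses.

#' E-GONet configuration
#'
#' @param conv_channels Channels of the three 3x3 convolution layers.
#' @param fc_width Width of the first fully connected layer (output layer
#'   is fixed at 2 softmax units: nonlethal / lethal).
#' @param dropout_rate Dropout after the first FC layer during training.
#' @param learning_rate,batch_size,epochs Optimizer settings.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param seed Seed for weight initialization, shuffling and dropout.
#' @return An `egonet_config` list.
#' @export
egonet_config <- function(conv_channels = c(16, 32, 64), fc_width = 128,
                          dropout_rate = 0.25, learning_rate = 1e-3,
                          batch_size = 64, epochs = 100,
                          optimizer = c("adam", "sgd"), seed = 1) {
  optimizer <- match.arg(optimizer)
  stopifnot(length(conv_channels) == 3, all(conv_channels >= 1),
            fc_width >= 1, dropout_rate >= 0, dropout_rate < 1)
  structure(list(conv_channels = as.integer(conv_channels),
                 fc_width = as.integer(fc_width),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), optimizer = optimizer,
                 seed = as.integer(seed)),
            class = "egonet_config")
}

# im2col for a 3x3 same-padded convolution. x: (H, W, Cin, N).
# Returns (H*W*N) x (9*Cin), rows ordered (i, j, n) with i fastest,
# column blocks ordered by kernel offset k (column-major over the 3x3
# window), channel within block.
conv_im2col <- function(x) {
  d <- dim(x)
  cpp_im2col(x, d[1], d[2], d[3], d[4])
}

# Scatter-add of a column gradient back to the input. dcol as produced
# against conv_im2col(x); returns gradient with dim(x).
conv_col2im <- function(dcol, xdim) {
  cpp_col2im(dcol, xdim[1], xdim[2], xdim[3], xdim[4])
}

conv_forward <- function(x, Wm, b) {
  d <- dim(x); H <- d[1]; W_ <- d[2]; N <- d[4]
  col <- conv_im2col(x)
  out <- col %*% Wm
  out <- out + rep(b, each = nrow(out))
  Cout <- ncol(Wm)
  list(out = cpp_swap34(out, H, W_, N, Cout), col = col)
}

conv_backward <- function(dout, col, Wm, xdim) {
  d <- dim(dout); H <- d[1]; W_ <- d[2]; Cout <- d[3]; N <- d[4]
  dmat <- matrix(cpp_swap34(dout, H, W_, Cout, N), H * W_ * N, Cout)
  list(dW = crossprod(col, dmat), db = colSums(dmat),
       dx = conv_col2im(dmat %*% t(Wm), xdim))
}

maxpool_forward <- function(x) {
  d <- dim(x)
  mp <- cpp_maxpool_fwd(x, d[1], d[2], d[3], d[4])
  list(out = mp$out, argmax = mp$argmax, xdim = d)
}

maxpool_backward <- function(dout, cache) {
  d <- cache$xdim
  cpp_maxpool_bwd(dout, cache$argmax, d[1], d[2], d[3], d[4])
}

flatten4 <- function(x) {
  d <- dim(x)
  t(matrix(x, prod(d[1:3]), d[4]))
}

init_egonet_params <- function(config) {
  ch <- config$conv_channels
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  flat_dim <- 4 * 5 * ch[3]   # 18x20 -> pool -> 9x10 -> pool -> 4x5
  list(W1 = he(9 * 1, ch[1]), b1 = numeric(ch[1]),
       W2 = he(9 * ch[1], ch[2]), b2 = numeric(ch[2]),
       W3 = he(9 * ch[2], ch[3]), b3 = numeric(ch[3]),
       Wf1 = he(flat_dim, config$fc_width), bf1 = numeric(config$fc_width),
       Wf2 = he(config$fc_width, 2), bf2 = numeric(2))
}

# Forward pass. x: (18, 20, 1, N). Returns logits and, if keep_cache,
# every intermediate needed for backprop.
egonet_forward <- function(params, x, dropout_mask = NULL,
                           keep_cache = FALSE) {
  c1 <- conv_forward(x, params$W1, params$b1)
  a1 <- pmax(c1$out, 0)
  p1 <- maxpool_forward(a1)
  c2 <- conv_forward(p1$out, params$W2, params$b2)
  a2 <- pmax(c2$out, 0)
  p2 <- maxpool_forward(a2)
  c3 <- conv_forward(p2$out, params$W3, params$b3)
  a3 <- pmax(c3$out, 0)
  f <- flatten4(a3)
  z1 <- sweep(f %*% params$Wf1, 2, params$bf1, "+")
  h1 <- pmax(z1, 0)
  if (!is.null(dropout_mask)) h1 <- h1 * dropout_mask
  logits <- sweep(h1 %*% params$Wf2, 2, params$bf2, "+")
  out <- list(logits = logits)
  if (keep_cache)
    out$cache <- list(x = x, c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2,
                      p2 = p2, c3 = c3, a3 = a3, f = f, z1 = z1, h1 = h1,
                      dropout_mask = dropout_mask)
  out
}

# Backward pass from dlogits (N x 2). Returns parameter gradients and,
# optionally, the gradient w.r.t. the input grids.
egonet_backward <- function(params, cache, dlogits, input_grad = FALSE) {
  g <- list()
  g$Wf2 <- crossprod(cache$h1, dlogits)
  g$bf2 <- colSums(dlogits)
  dh1 <- dlogits %*% t(params$Wf2)
  if (!is.null(cache$dropout_mask)) dh1 <- dh1 * cache$dropout_mask
  dz1 <- dh1 * (cache$z1 > 0)
  g$Wf1 <- crossprod(cache$f, dz1)
  g$bf1 <- colSums(dz1)
  df <- dz1 %*% t(params$Wf1)
  da3 <- array(t(df), dim(cache$a3))
  dc3 <- da3 * (cache$c3$out > 0)
  b3 <- conv_backward(dc3, cache$c3$col, params$W3, dim(cache$p2$out))
  g$W3 <- b3$dW; g$b3 <- b3$db
  da2 <- maxpool_backward(b3$dx, cache$p2)
  dc2 <- da2 * (cache$c2$out > 0)
  b2 <- conv_backward(dc2, cache$c2$col, params$W2, dim(cache$p1$out))
  g$W2 <- b2$dW; g$b2 <- b2$db
  da1 <- maxpool_backward(b2$dx, cache$p1)
  dc1 <- da1 * (cache$c1$out > 0)
  if (input_grad) {
    b1 <- conv_backward(dc1, cache$c1$col, params$W1, dim(cache$x))
    g$W1 <- b1$dW; g$b1 <- b1$db
    g$dx <- b1$dx
  } else {
    d <- dim(dc1)
    dmat <- matrix(cpp_swap34(dc1, d[1], d[2], d[3], d[4]),
                   d[1] * d[2] * d[4], d[3])
    g$W1 <- crossprod(cache$c1$col, dmat)
    g$b1 <- colSums(dmat)
  }
  g
}

softmax_rows <- function(logits) {
  z <- exp(logits - apply(logits, 1, max))
  z / rowSums(z)
}

grids_to_input <- function(grids) {
  if (length(dim(grids)) == 2) grids <- array(grids, c(18, 20, 1))
  stopifnot(dim(grids)[1] == 18, dim(grids)[2] == 20)
  array(grids, c(18, 20, 1, dim(grids)[3]))
}

#' Train the E-GONet convolutional classifier
#'
#' Minimizes softmax cross-entropy over the two outcome classes
#' (nonlethal, lethal) on 18 x 20 feature grids. Fully deterministic for a
#' given config seed (weight init, shuffling and dropout all draw from it).
#'
#' @param grids 18 x 20 x n array of (scaled) feature grids.
#' @param labels Logical or 0/1 vector: `TRUE`/1 = lethal.
#' @param config An [egonet_config()].
#' @return An `intentnet_model` of kind `"egonet"` with the fitted
#'   parameters and the per-epoch training-loss trace.
#' @export
train_egonet <- function(grids, labels, config = egonet_config()) {
  x_all <- grids_to_input(grids)
  y <- as.integer(labels)
  n <- dim(x_all)[4]
  stopifnot(length(y) == n, all(y %in% 0:1))
  set.seed(derive_seed(config$seed, 21))
  params <- init_egonet_params(config)
  opt <- if (config$optimizer == "adam") adam_state(params) else NULL
  loss_trace <- numeric(config$epochs)
  step <- 0
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    epoch_loss <- 0
    for (bt in batches) {
      xb <- x_all[, , , bt, drop = FALSE]
      yb <- y[bt]
      nb <- length(bt)
      mask <- NULL
      if (config$dropout_rate > 0) {
        mask <- matrix(
          (stats::runif(nb * config$fc_width) >= config$dropout_rate) /
            (1 - config$dropout_rate),
          nb, config$fc_width)
      }
      fw <- egonet_forward(params, xb, dropout_mask = mask,
                           keep_cache = TRUE)
      probs <- softmax_rows(fw$logits)
      loss <- -mean(log(pmax(probs[cbind(seq_len(nb), yb + 1L)], 1e-12)))
      if (!is.finite(loss))
        stop("training error: non-finite loss at epoch ", epoch,
             call. = FALSE)
      epoch_loss <- epoch_loss + loss * nb
      dlogits <- probs
      dlogits[cbind(seq_len(nb), yb + 1L)] <-
        dlogits[cbind(seq_len(nb), yb + 1L)] - 1
      dlogits <- dlogits / nb
      g <- egonet_backward(params, fw$cache, dlogits)
      step <- step + 1
      if (config$optimizer == "adam") {
        upd <- adam_update(params, g, opt, config$learning_rate, step)
        params <- upd$params; opt <- upd$state
      } else {
        for (nm in names(params))
          params[[nm]] <- params[[nm]] - config$learning_rate * g[[nm]]
      }
    }
    loss_trace[epoch] <- epoch_loss / n
  }
  structure(list(kind = "egonet", params = params, config = config,
                 loss_trace = loss_trace, scaler = NULL,
                 uses_relationship_features = NA),
            class = "intentnet_model")
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_update <- function(params, grads, state, lr, step,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^step)
    vhat <- state$v[[nm]] / (1 - beta2^step)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' @export
print.intentnet_model <- function(x, ...) {
  cat("<intentnet_model> kind: ", x$kind, "\n", sep = "")
  if (x$kind == "egonet")
    cat("  final training loss: ",
        signif(utils::tail(x$loss_trace, 1), 4), "\n", sep = "")
  invisible(x)
}

#' Predict lethality from feature grids
#'
#' @param object A fitted `intentnet_model`.
#' @param grids 18 x 20 x n array (E-GONet / grid-trained baselines).
#' @param ... Unused.
#' @return A data.frame: `prob_lethal`, `class` (logical, probability
#'   >= 0.5); E-GONet rows carry both class probabilities (summing to 1).
#' @export
predict.intentnet_model <- function(object, grids, ...) {
  n <- if (length(dim(grids)) == 3) dim(grids)[3]
       else if (length(dim(grids)) == 2 && all(dim(grids) == c(18, 20))) 1
       else nrow(grids)
  if (is.null(n) || (length(n) == 1 && n == 0) ||
      (length(dim(grids)) == 3 && dim(grids)[3] == 0))
    return(data.frame(prob_lethal = numeric(0), class = logical(0)))
  if (object$kind == "egonet") {
    x <- grids_to_input(grids)
    logits <- egonet_forward(object$params, x)$logits
    probs <- softmax_rows(logits)
    out <- data.frame(prob_lethal = probs[, 2],
                      class = probs[, 2] >= 0.5)
    out$prob_nonlethal <- probs[, 1]
    return(out)
  }
  X <- grids_to_flat(grids)
  p <- predict_baseline(object, X)
  data.frame(prob_lethal = p, class = p >= 0.5)
}

grids_to_flat <- function(grids) {
  if (length(dim(grids)) == 3) {
    n <- dim(grids)[3]
    t(vapply(seq_len(n), function(s) flatten_grid(grids[, , s]),
             numeric(360)))
  } else if (length(dim(grids)) == 2 && all(dim(grids) == c(18, 20))) {
    matrix(flatten_grid(grids), 1)
  } else {
    as.matrix(grids)
  }
}
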