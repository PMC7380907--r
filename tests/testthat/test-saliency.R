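test_that("Gradient*Input is exact on linear surrogates and zero inputs", {
  set.seed(21)
  W <- array(rnorm(18 * 20 * 2), c(18, 20, 2))
  md <- linear_surrogate(W, bias = c(0.1, -0.2))
  x <- matrix(rnorm(360), 18, 20)
  # analytic w (*) x for each target class
  expect_equal(gradient_x_input(md, x, 1L), W[, , 2] * x)
  expect_equal(gradient_x_input(md, x, 0L), W[, , 1] * x)
  # all-zero input -> all-zero importance
  expect_equal(gradient_x_input(md, matrix(0, 18, 20), 1L),
               matrix(0, 18, 20))
  # linearity: the map of a sum surrogate is the sum of the maps
  W2 <- array(rnorm(18 * 20 * 2), c(18, 20, 2))
  md2 <- linear_surrogate(W2)
  md_sum <- linear_surrogate(W + W2)
  expect_equal(gradient_x_input(md_sum, x, 1L),
               gradient_x_input(md, x, 1L) + gradient_x_input(md2, x, 1L))
})

test_that("egonet Gradient*Input matches finite differences and zero cells", {
  set.seed(22)
  n <- 30
  g <- array(runif(18 * 20 * n), c(18, 20, n))
  zero_pos <- which(grid_layout()$kind == "zero")
  for (s in 1:n) {
    flat <- flatten_grid(g[, , s]); flat[zero_pos] <- 0
    g[, , s] <- matrix(flat, 18, 20, byrow = TRUE)
  }
  y <- rep(c(TRUE, FALSE), length.out = n)
  m <- train_egonet(g, y, egonet_config(conv_channels = c(4, 8, 8),
                                        fc_width = 16, epochs = 5,
                                        seed = 7))
  imp <- gradient_x_input(m, g[, , 1], 1L)
  # structural-zero cells have importance exactly 0 (x = 0 there)
  expect_true(all(flatten_grid(imp)[zero_pos] == 0))
  # finite-difference check of the underlying gradient at two cells
  logit1 <- function(grid) {
    x <- intentnet:::grids_to_input(array(grid, c(18, 20, 1)))
    intentnet:::egonet_forward(m$params, x)$logits[1, 2]
  }
  eps <- 1e-6
  for (cell in list(c(3, 4), c(10, 2))) {
    gp <- g[, , 1]; gp[cell[1], cell[2]] <- gp[cell[1], cell[2]] + eps
    num <- (logit1(gp) - logit1(g[, , 1])) / eps
    expect_equal(imp[cell[1], cell[2]],
                 num * g[, , 1][cell[1], cell[2]], tolerance = 1e-4)
  }
  expect_error(
    gradient_x_input(train_baseline(matrix(rnorm(40), 10), rep(0:1, 5),
                                    "linreg"),
                     g[, , 1]),
    "unsupported")
})

test_that("class-averaged importance implements the two-stage mean", {
  set.seed(23)
  W <- array(0, c(18, 20, 2))
  W[, , 2] <- matrix(rnorm(360), 18, 20)
  md <- linear_surrogate(W)
  n <- 12
  g <- array(rnorm(18 * 20 * n), c(18, 20, n))
  labels <- rep(c(TRUE, FALSE), each = n / 2)

  # identical grids -> map equals that single importance grid
  gsame <- g
  for (s in 2:n) gsame[, , s] <- gsame[, , 1]
  map1 <- class_averaged_importance(list(md, md), gsame, labels,
                                    rep(1:2, n / 2))
  expect_equal(map1$lethal, gradient_x_input(md, gsame[, , 1], 1L))

  # single fold -> map equals the within-fold class mean
  map2 <- class_averaged_importance(list(md), g, labels, rep(1, n))
  manual <- apply(gradient_x_input(md, g[, , labels], 1L), c(1, 2), mean)
  expect_equal(map2$lethal, manual)

  # equally sized, class-balanced folds: two-stage mean == one-stage mean
  folds <- rep(1:2, times = n / 2)   # 3 lethal + 3 nonlethal per fold
  map3 <- class_averaged_importance(list(md, md), g, labels, folds)
  one_stage <- apply(gradient_x_input(md, g[, , labels], 1L), c(1, 2),
                     mean)
  expect_equal(map3$lethal, one_stage)

  # fold without a class is flagged and skipped
  map4 <- class_averaged_importance(list(md, md), g, labels,
                                    c(rep(1, 6), rep(2, 6)))
  expect_true(any(grepl("no lethal cases", map4$flags)) ||
                any(grepl("no nonlethal cases", map4$flags)))
})
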