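test_that("scaler maps to [0,1], passes structural zeros, clips, no leakage", {
  co <- small_cohort()
  g <- build_feature_grids(co)
  sc <- fit_scaler(g)
  gs <- apply_scaler(g, sc)
  expect_true(all(gs >= 0 & gs <= 1))
  # structural-zero cells remain exactly 0
  zero_pos <- grid_layout()$position[grid_layout()$kind == "zero"]
  for (s in c(1, 5)) {
    flat <- flatten_grid(gs[, , s])
    expect_true(all(flat[zero_pos + 1] == 0))
  }
  # values above the training max clip to 1; constant cells map to 0
  g2 <- g[, , 1]
  g2[1, 1] <- max(g[1, 1, ]) + 100
  expect_equal(apply_scaler(g2, sc)[1, 1], 1)
  # leakage guard: scaler depends on training grids only
  sc_b <- fit_scaler(g[, , 1:100])
  g_perturbed <- g
  g_perturbed[, , 101:150] <- g_perturbed[, , 101:150] * 7
  sc_b2 <- fit_scaler(g_perturbed[, , 1:100])
  expect_identical(sc_b, sc_b2)
})

test_that("egonet separates separable data, is deterministic, handles nulls", {
  # linearly separable grids: one informative cell
  set.seed(10)
  n <- 200
  g <- array(runif(18 * 20 * n, 0, 0.2), c(18, 20, n))
  y <- rep(c(TRUE, FALSE), each = n / 2)
  g[5, 5, y] <- g[5, 5, y] + 0.8
  cfg <- test_egonet_config(epochs = 40, seed = 3)
  m <- train_egonet(g, y, cfg)
  pr <- predict(m, g)
  expect_gte(mean(pr$class == y), 0.99)
  # softmax probabilities sum to 1
  expect_equal(pr$prob_lethal + pr$prob_nonlethal, rep(1, n))
  # same seed and data -> identical predictions
  m2 <- train_egonet(g, y, cfg)
  expect_identical(predict(m2, g), pr)
  # empty input -> empty output
  expect_equal(nrow(predict(m, g[, , integer(0), drop = FALSE])), 0)

  # permuted labels: held-out accuracy at chance (capacity null check)
  set.seed(11)
  yp <- sample(y)
  m0 <- train_egonet(g[, , 1:150], yp[1:150],
                     test_egonet_config(epochs = 15, seed = 5))
  pr0 <- predict(m0, g[, , 151:200])
  expect_lt(abs(mean(pr0$class == yp[151:200]) - 0.5), 0.25)
})

test_that("full-batch SGD training loss is non-increasing", {
  set.seed(12)
  n <- 40
  g <- array(runif(18 * 20 * n), c(18, 20, n))
  y <- rep(c(TRUE, FALSE), each = n / 2)
  cfg <- egonet_config(conv_channels = c(4, 8, 8), fc_width = 16,
                       dropout_rate = 0, batch_size = n, epochs = 30,
                       optimizer = "sgd", learning_rate = 0.005, seed = 2)
  m <- train_egonet(g, y, cfg)
  expect_true(all(diff(m$loss_trace) <= 1e-8))
})

test_that("baselines recover a perfect feature and honor contracts", {
  set.seed(14)
  n <- 1000
  X <- matrix(rnorm(n * 20), n, 20)
  y <- X[, 7] > 0
  tr <- 1:600; te <- 601:1000
  lin <- train_baseline(X[tr, ], y[tr], "linreg")
  rf <- train_baseline(X[tr, ], y[tr], "rf", seed = 2, n_trees = 100)
  for (m in list(lin, rf)) {
    pred <- intentnet:::predict_baseline(m, X[te, ]) >= 0.5
    cm <- confusion_metrics(y[te], pred)
    expect_gte(cm$f1_weighted, 0.95)
  }
  # rf determinism
  rf2 <- train_baseline(X[tr, ], y[tr], "rf", seed = 2, n_trees = 100)
  expect_identical(intentnet:::predict_baseline(rf, X[te, ]),
                   intentnet:::predict_baseline(rf2, X[te, ]))
  # constant labels -> constant prediction
  rfc <- train_baseline(X[tr, ], rep(TRUE, 600), "rf", seed = 1,
                        n_trees = 10)
  expect_true(all(intentnet:::predict_baseline(rfc, X[te, ]) == 1))
  linc <- train_baseline(X[tr, ], rep(TRUE, 600), "linreg")
  expect_true(all(intentnet:::predict_baseline(linc, X[te, ]) >= 0.5))
  # singular design warns and still fits
  Xs <- cbind(X[tr, ], X[tr, 1])
  expect_warning(train_baseline(Xs, y[tr], "linreg"), "ridge jitter")
})
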