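test_that("glasso at penalty 0 matches brute-force inversion", {
  set.seed(31)
  for (p in c(4, 6)) {
    theta_true <- diag(p)
    theta_true[1, 2] <- theta_true[2, 1] <- -0.4
    theta_true[2, 3] <- theta_true[3, 2] <- -0.3
    sigma <- solve(theta_true)
    X <- MASS::mvrnorm(2000, rep(0, p), sigma)
    fit <- estimate_glasso(X, penalty = 0)
    expect_lt(max(abs(fit$weights - oracle_partial_cor(X))), 1e-6)
    expect_true(isSymmetric(fit$weights))
    expect_equal(diag(fit$weights), rep(0, p))
  }
})

test_that("glasso recovers analytic partial correlations at tiny penalty", {
  # large-n draws from a known 4-variable precision matrix
  theta <- diag(4)
  theta[1, 2] <- theta[2, 1] <- -0.35
  theta[3, 4] <- theta[4, 3] <- -0.25
  analytic <- -cov2cor(theta)  # partial corr = -theta_ij/sqrt(ii jj)
  diag(analytic) <- 0
  set.seed(8)
  X <- MASS::mvrnorm(100000, rep(0, 4), solve(theta))
  fit0 <- estimate_glasso(X, penalty = 0)
  expect_lt(max(abs(fit0$weights - analytic)), 0.02)
  # small nonzero penalty stays close and keeps symmetry/zero diagonal
  fit <- estimate_glasso(X, penalty = 0.01)
  expect_lt(max(abs(fit$weights - analytic)), 0.05)
  expect_true(isSymmetric(fit$weights, tol = 1e-8))
})

test_that("independence plus strong shrinkage gives an empty graph", {
  set.seed(5)
  X <- matrix(rnorm(500 * 6), 500, 6)
  fit <- estimate_glasso(X, penalty = 0.9)
  expect_true(all(abs(fit$weights[upper.tri(fit$weights)]) < 1e-10))
  expect_error(estimate_glasso(cbind(X, X[, 1] * NA)), "non-finite")
  expect_warning(estimate_glasso(matrix(rnorm(10 * 6), 10, 6),
                                 penalty = 0.5), "unstable")
})

test_that("permutation p-values are calibrated on noise and reproducible", {
  set.seed(77)
  X <- matrix(rnorm(300 * 6), 300, 6)
  ps <- permutation_significance(X, penalty = 0.05, n_perm = 200,
                                 alpha = 0.05, seed = 3)
  m <- ps$significant
  # stochastic: realized false-positive rate within 3 binomial SEs of alpha
  n_edges <- sum(upper.tri(m))
  expect_lte(mean(m[upper.tri(m)]),
             0.05 + 3 * sqrt(0.05 * 0.95 / n_edges))
  # and p-values are roughly uniform under the null
  expect_lt(abs(mean(ps$edge_p[upper.tri(ps$edge_p)]) - 0.5), 0.2)
  ps2 <- permutation_significance(X, penalty = 0.05, n_perm = 200,
                                  alpha = 0.05, seed = 3)
  expect_identical(ps$edge_p, ps2$edge_p)
  expect_true(all(ps$edge_p >= 1 / 201 & ps$edge_p <= 1))
  expect_warning(
    permutation_significance(X, penalty = 0.05, n_perm = 10, seed = 1),
    "n_perm too small")
})

test_that("topology matches hand-enumerated graphs", {
  mk <- function(adj, nodes) {
    dimnames(adj) <- list(nodes, nodes)
    list(significant = adj, nodes = nodes)
  }
  # path a-b-c
  adj <- matrix(FALSE, 3, 3)
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- TRUE
  tp <- topology(mk(adj, c("a", "b", "c")))
  expect_equal(unname(tp$degree), c(1, 2, 1))
  expect_equal(unname(tp$avg_shortest_path), c(1.5, 1, 1.5))
  expect_equal(tp$edge_count, 2)
  expect_equal(sum(tp$degree), 2 * tp$edge_count)

  # empty graph
  tp0 <- topology(mk(matrix(FALSE, 3, 3), c("a", "b", "c")))
  expect_equal(unname(tp0$degree), c(0, 0, 0))
  expect_true(all(is.na(tp0$avg_shortest_path)))

  # star on 5 nodes
  adj5 <- matrix(FALSE, 5, 5)
  adj5[1, 2:5] <- adj5[2:5, 1] <- TRUE
  tp5 <- topology(mk(adj5, letters[1:5]))
  expect_equal(unname(tp5$degree[1]), 4)
  expect_equal(unname(tp5$avg_shortest_path[1]), 1)
  expect_equal(unname(tp5$avg_shortest_path[2]), (1 + 2 + 2 + 2) / 4)
})

test_that("group networks have 16 nodes and export cleanly", {
  co <- small_cohort()
  suppressWarnings(
    nets <- build_group_networks(co, n_perm = 50, alpha = 0.05, seed = 2))
  for (nw in nets) {
    expect_length(nw$nodes, 16)
    expect_equal(nw$nodes[16], "Fatality")
    expect_true(all(nw$edge_p >= 0 & nw$edge_p <= 1))
    expect_true(all(!nw$significant | abs(nw$edge_weight) > 0))
  }
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network_graphml(nets$lethal, gml, tsv)
  expect_true(file.exists(gml))
  x <- xml2::read_xml(gml)
  expect_equal(xml2::xml_name(x), "graphml")
  edges <- utils::read.delim(tsv)
  if (nrow(edges) > 0)
    expect_true(all(c("from", "to", "weight", "p") %in% names(edges)))
})

test_that("edge recall of planted truth grows with sample size", {
  # monotone non-decreasing recall at n in {500, 2000, 8000}
  recall <- sapply(c(500, 2000, 8000), function(n) {
    synth <- generate_cohort(generator_config(n_subjects = n, seed = 17,
                                              missing_rate = 0))
    co <- preprocess_cohort(synth$cohort)
    idx <- co$lethal
    X <- co$sis_cal[idx, ]
    fit <- estimate_glasso(X)
    edges <- synth$truth$lethal$true_edges
    mean(abs(fit$weights[edges]) > 1e-8)
  })
  expect_true(all(diff(recall) >= 0))
  expect_gt(recall[3], 0.9)
})
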