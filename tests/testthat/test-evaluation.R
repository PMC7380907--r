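test_that("stratified folds partition exactly with balanced classes", {
  labels <- rep(c(TRUE, FALSE), c(10, 10))
  f <- stratified_folds(labels, 5, seed = 3)
  expect_setequal(unique(f), 1:5)
  expect_true(all(table(f[labels]) == 2))
  expect_equal(sort(unname(unlist(split(seq_along(f), f)))), 1:20)
  expect_identical(f, stratified_folds(labels, 5, seed = 3))
  expect_false(identical(f, stratified_folds(labels, 5, seed = 4)))
  expect_error(stratified_folds(rep(c(TRUE, FALSE), c(3, 17)), 5),
               "smaller k")

  # imbalanced: every fold within one subject of the global ratio
  set.seed(2)
  lab <- runif(173) < 0.2
  f2 <- stratified_folds(lab, 10, seed = 1)
  pos_per_fold <- table(factor(f2[lab], levels = 1:10))
  expect_lte(diff(range(pos_per_fold)), 1)
})

test_that("confusion metrics match hand-computed tables", {
  # perfect predictions
  m <- confusion_metrics(c(T, T, F, F), c(T, T, F, F))
  for (v in c("ppv", "npv", "sensitivity", "specificity", "accuracy",
              "f1_weighted"))
    expect_equal(m[[v]], 1)
  expect_length(m$flags, 0)

  # all-negative predictor at prevalence 0.2
  truth <- rep(c(TRUE, FALSE), c(2, 8))
  m2 <- confusion_metrics(truth, rep(FALSE, 10))
  expect_equal(m2$ppv, 0)
  expect_true("ppv" %in% m2$flags)
  expect_equal(m2$sensitivity, 0)
  expect_equal(m2$specificity, 1)
  expect_equal(m2$accuracy, 0.8)

  # TP=3 FP=1 FN=2 TN=4, against the independent 2x2 oracle
  truth3 <- c(rep(TRUE, 5), rep(FALSE, 5))
  pred3 <- c(TRUE, TRUE, TRUE, FALSE, FALSE,
             TRUE, FALSE, FALSE, FALSE, FALSE)
  m3 <- confusion_metrics(truth3, pred3)
  expect_equal(m3$counts, c(tp = 3, fp = 1, fn = 2, tn = 4))
  expect_equal(m3$ppv, 0.75)
  expect_equal(m3$sensitivity, 0.6)
  expect_equal(m3$f1_weighted, oracle_weighted_f1(3, 1, 2, 4))
  # accuracy identity from counts
  expect_equal(m3$accuracy, (3 + 4) / 10)

  # invariant to simultaneous permutation
  set.seed(9)
  perm <- sample(10)
  m4 <- confusion_metrics(truth3[perm], pred3[perm])
  expect_equal(m4[c("ppv", "npv", "sensitivity", "specificity",
                    "accuracy", "f1_weighted")],
               m3[c("ppv", "npv", "sensitivity", "specificity",
                    "accuracy", "f1_weighted")])
  expect_error(confusion_metrics(truth3, pred3[-1]), "length")
})

test_that("PRG curve endpoints and hand example behave as defined", {
  # perfect ranking
  expect_equal(auprg(prg_curve(c(1, 1, 0, 0), c(.9, .8, .2, .1))), 1)
  # always-positive operating point: recall gain 1, precision gain 0
  cu <- prg_curve(c(1, 0, 1, 1, 0, 0), c(.9, .8, .7, .4, .3, .2))
  last <- cu$operating[nrow(cu$operating), ]
  expect_equal(last$recall_gain, 1)
  expect_equal(last$precision_gain, 0)
  expect_true(all(diff(cu$points$recall_gain) >= 0))
  # 6-point hand example equals the independent brute-force oracle
  expect_equal(auprg(cu),
               oracle_auprg(c(1, 0, 1, 1, 0, 0), c(.9, .8, .7, .4, .3, .2)))
  expect_error(prg_curve(c(1, 1, 1), c(.1, .2, .3)), "degenerate")
})

test_that("auprg equals the brute-force oracle on fuzzed instances", {
  set.seed(123)
  for (rep in 1:1000) {
    n <- 8
    truth <- runif(n) < runif(1, 0.2, 0.8)
    if (sum(truth) == 0) truth[sample(n, 1)] <- TRUE
    if (sum(truth) == n) truth[sample(n, 1)] <- FALSE
    scores <- round(runif(n), 2)   # frequent ties
    expect_equal(auprg(prg_curve(truth, scores)),
                 oracle_auprg(truth, scores), tolerance = 1e-12)
  }
})

test_that("run_cv is deterministic and degrades to majority on noise", {
  co <- small_cohort()
  # constant-ish scores: linreg on pure-noise grids predicts near-majority
  set.seed(4)
  noise <- array(rnorm(18 * 20 * 120), c(18, 20, 120))
  labels <- rep(c(TRUE, FALSE), c(24, 96))
  r <- suppressWarnings(
    run_cv(noise, kinds = "linreg", k = 4, seed = 6, labels = labels))
  expect_lt(abs(r$linreg$mean["accuracy"] - 0.8), 0.15)

  r1 <- suppressWarnings(
    run_cv(co, kinds = "linreg", k = 5, seed = 11))
  r2 <- suppressWarnings(
    run_cv(co, kinds = "linreg", k = 5, seed = 11))
  expect_identical(r1$linreg$per_fold, r2$linreg$per_fold)
  expect_equal(r1$linreg$n_folds, 5)
  expect_named(r1$linreg$mean,
               c("f1_weighted", "ppv", "npv", "sensitivity", "specificity",
                 "accuracy", "auprg"))
  expect_true(all(r1$linreg$per_fold[, "accuracy"] >= 0 &
                    r1$linreg$per_fold[, "accuracy"] <= 1))

  # n_trials = 2 with same master seed reproduces the whole report
  r3 <- suppressWarnings(
    run_cv(co, kinds = "linreg", k = 4, n_trials = 2, seed = 21))
  r4 <- suppressWarnings(
    run_cv(co, kinds = "linreg", k = 4, n_trials = 2, seed = 21))
  expect_identical(r3$linreg$per_fold, r4$linreg$per_fold)
  expect_false(is.na(r3$linreg$sd_trials["f1_weighted"]))
})
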