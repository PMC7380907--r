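#' Stratified k-fold assignment
#'
#' Shuffles each class separately and deals subjects round-robin, so every
#' fold's class ratio is within one subject of the global ratio and the
#' folds partition the index set exactly.
#'
#' @param labels Logical (or 0/1) outcomes.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (min(n_pos, n_neg) < k)
    stop("class smaller than k = ", k, "; use a smaller k", call. = FALSE)
  set.seed(derive_seed(seed, 41))
  fold <- integer(length(labels))
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

cv_metric_names <- c("f1_weighted", "ppv", "npv", "sensitivity",
                     "specificity", "accuracy", "auprg")

fold_metrics <- function(truth, prob) {
  cm <- confusion_metrics(truth, prob >= 0.5)
  au <- if (length(unique(truth)) < 2) NA_real_ else auprg(truth, prob)
  c(f1_weighted = cm$f1_weighted, ppv = cm$ppv, npv = cm$npv,
    sensitivity = cm$sensitivity, specificity = cm$specificity,
    accuracy = cm$accuracy, auprg = au)
}

#' Cross-validated evaluation of the lethality models
#'
#' Stratified k-fold cross-validation, optionally repeated over
#' `n_trials` re-splits. Per fold, the min-max scaler and the model are
#' fitted on the training folds only; metrics (weighted F1, PPV, NPV,
#' sensitivity, specificity, accuracy, AUPRG) are computed on the held-out
#' fold. A test fold with one class gets `NA` AUPRG and is flagged.
#'
#' @param cohort A preprocessed `cohort_table`, or an 18 x 20 x n grid
#'   array (then `labels` must be given).
#' @param kinds Models to evaluate: subset of
#'   `c("egonet", "linreg", "rf")`.
#' @param k Folds (default 10).
#' @param n_trials Repeated CV trials (default 1).
#' @param seed Master seed; everything below derives from it.
#' @param use_relationship Build grids with (default) or without the 315
#'   relationship features (ablation).
#' @param config E-GONet configuration (its seed is overridden per
#'   trial/fold from `seed`).
#' @param labels Outcomes when `cohort` is a grid array.
#' @param rf_trees Trees for the forest baseline.
#' @return Named list (per kind) of `cv_report`s: `per_fold` data.frame,
#'   `mean`, `sd_folds` (within-trial), `sd_trials`, `flags`, `seeds`.
#' @export
run_cv <- function(cohort, kinds = c("egonet", "linreg", "rf"), k = 10,
                   n_trials = 1, seed = 1, use_relationship = TRUE,
                   config = egonet_config(), labels = NULL,
                   rf_trees = 500) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  if (inherits(cohort, "cohort_table")) {
    grids <- build_feature_grids(cohort, use_relationship = use_relationship)
    labels <- cohort$lethal
  } else {
    grids <- cohort
    if (is.null(labels)) stop("labels required with a grid array",
                              call. = FALSE)
  }
  labels <- as.logical(labels)
  reports <- stats::setNames(vector("list", length(kinds)), kinds)
  rows <- lapply(kinds, function(x) list())
  names(rows) <- kinds
  flags <- stats::setNames(rep(list(character(0)), length(kinds)), kinds)
  seeds_used <- list(master = seed)
  for (trial in seq_len(n_trials)) {
    fold_seed <- derive_seed(seed, 100 + trial)
    seeds_used[[paste0("trial_", trial)]] <- fold_seed
    fold <- stratified_folds(labels, k, fold_seed)
    for (f in seq_len(k)) {
      test <- fold == f
      scaler <- fit_scaler(grids[, , !test, drop = FALSE])
      tr <- apply_scaler(grids[, , !test, drop = FALSE], scaler)
      te <- apply_scaler(grids[, , test, drop = FALSE], scaler)
      model_seed <- derive_seed(seed, 1000 * trial + f)
      for (kind in kinds) {
        model <- switch(
          kind,
          egonet = {
            cfg <- config; cfg$seed <- model_seed
            train_egonet(tr, labels[!test], cfg)
          },
          linreg = suppressWarnings(
            train_baseline(tr, labels[!test], "linreg")),
          rf = train_baseline(tr, labels[!test], "rf", seed = model_seed,
                              n_trees = rf_trees)
        )
        model$scaler <- scaler
        model$uses_relationship_features <- use_relationship
        prob <- predict(model, te)$prob_lethal
        m <- fold_metrics(labels[test], prob)
        if (is.na(m["auprg"]))
          flags[[kind]] <- c(flags[[kind]],
                             sprintf("trial %d fold %d: one-class test fold, AUPRG skipped",
                                     trial, f))
        rows[[kind]][[length(rows[[kind]]) + 1]] <-
          c(trial = trial, fold = f, m)
      }
    }
  }
  for (kind in kinds) {
    per_fold <- as.data.frame(do.call(rbind, rows[[kind]]))
    mean_ <- colMeans(per_fold[cv_metric_names], na.rm = TRUE)
    sd_folds <- stats::aggregate(per_fold[cv_metric_names],
                                 by = list(trial = per_fold$trial),
                                 FUN = stats::sd)
    trial_means <- stats::aggregate(per_fold[cv_metric_names],
                                    by = list(trial = per_fold$trial),
                                    FUN = mean, na.rm = TRUE)
    sd_trials <- if (n_trials > 1)
      apply(trial_means[cv_metric_names], 2, stats::sd)
    else stats::setNames(rep(NA_real_, length(cv_metric_names)),
                         cv_metric_names)
    reports[[kind]] <- structure(
      list(kind = kind, per_fold = per_fold, mean = mean_,
           sd_folds = sd_folds, sd_trials = sd_trials,
           n_folds = k, n_trials = n_trials,
           uses_relationship_features = use_relationship,
           flags = flags[[kind]], seeds = seeds_used),
      class = "cv_report")
  }
  reports
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$kind, " (", x$n_folds, "-fold x ", x$n_trials,
      " trial(s), relationship features: ",
      x$uses_relationship_features, ")\n", sep = "")
  print(round(x$mean, 4))
  invisible(x)
}

#' Serialize a CV report (or list of reports) as JSON
#'
#' @param reports Output of [run_cv()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cv_json <- function(reports, path) {
  if (inherits(reports, "cv_report")) reports <- list(reports)
  out <- lapply(reports, function(r)
    list(kind = r$kind, mean = as.list(r$mean),
         sd_trials = as.list(r$sd_trials),
         n_folds = r$n_folds, n_trials = r$n_trials,
         uses_relationship_features = r$uses_relationship_features,
         per_fold = r$per_fold, flags = r$flags, seeds = r$seeds))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
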