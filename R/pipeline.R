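#' Resolved end-to-end run configuration
#'
#' One master seed drives every stage; every tunable is explicit here and
#' echoed into the run manifest so a run is reproducible from the config
#' alone.
#'
#' @param seed Master seed.
#' @param generator A [generator_config()] (its seed is overridden by
#'   `seed`).
#' @param network List: `penalty` (NULL = EBIC), `alpha`, `n_perm`.
#' @param model An [egonet_config()].
#' @param cv List: `k`, `n_trials`, `kinds`, `rf_trees`.
#' @param impute_k Neighbours for kNN imputation.
#' @return A `run_config`.
#' @export
run_config <- function(seed = 1,
                       generator = generator_config(seed = seed),
                       network = list(penalty = NULL, alpha = 0.05,
                                      n_perm = 1000),
                       model = egonet_config(seed = seed),
                       cv = list(k = 10, n_trials = 1,
                                 kinds = c("egonet", "linreg", "rf"),
                                 rf_trees = 500),
                       impute_k = 10) {
  generator$seed <- as.integer(seed)
  model$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), generator = generator,
                 network = network, model = model, cv = cv,
                 impute_k = impute_k),
            class = "run_config")
}

#' Run the full pipeline
#'
#' generate -> preprocess -> features -> network -> train -> evaluate ->
#' saliency, writing every artifact plus a manifest (config echo, seeds,
#' versions, md5 checksums) into `outdir`. Any stage failure aborts with
#' the stage name after writing a partial-artifact manifest.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_all <- function(config = run_config(), outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(outdir, f)
  manifest <- list(config = config_echo(config),
                   versions = list(R = R.version.string,
                                   intentnet = as.character(utils::packageVersion("intentnet"))),
                   artifacts = list(), notes = character(0))
  fail <- function(name, e) {
    manifest$notes <- c(manifest$notes,
                        paste0("stage '", name, "' FAILED: ",
                               conditionMessage(e)))
    write_manifest(manifest, pth("manifest.json"))
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  stage <- function(name, expr) tryCatch(expr, error = function(e) fail(name, e))

  synth <- stage("generate", {
    s <- generate_cohort(config$generator)
    write_cohort(s$cohort, pth("cohort.csv"))
    write_truth_json(s, pth("truth.json"))
    manifest$artifacts$cohort <- pth("cohort.csv")
    manifest$artifacts$truth <- pth("truth.json")
    s
  })

  cohort <- stage("preprocess", {
    had_missing <- any(synth$cohort$mask)
    co <- preprocess_cohort(synth$cohort, k = config$impute_k)
    if (!had_missing)
      manifest$notes <- c(manifest$notes,
                           "no missing cells: imputation skipped")
    write_imputation_sidecar(co, pth("imputation.json"), seed = config$seed)
    write_cohort(co, pth("cohort_preprocessed.csv"))
    manifest$artifacts$imputation <- pth("imputation.json")
    manifest$artifacts$cohort_preprocessed <- pth("cohort_preprocessed.csv")
    co
  })

  grids <- stage("features", {
    g <- build_feature_grids(cohort, use_relationship = TRUE)
    write_feature_grids(g, pth("features.csv"), pth("layout.json"))
    manifest$artifacts$features <- pth("features.csv")
    manifest$artifacts$layout <- pth("layout.json")
    g
  })

  stage("network", {
    nets <- build_group_networks(cohort, penalty = config$network$penalty,
                                 n_perm = config$network$n_perm,
                                 alpha = config$network$alpha,
                                 seed = config$seed)
    topo <- do.call(rbind, lapply(nets, function(nw)
      data.frame(group = nw$group, node = nw$nodes,
                 degree = as.numeric(nw$topology$degree),
                 avg_shortest_path = as.numeric(nw$topology$avg_shortest_path))))
    for (grp in names(nets))
      write_network_graphml(nets[[grp]],
                            pth(paste0("network_", grp, ".graphml")),
                            pth(paste0("edges_", grp, ".tsv")))
    utils::write.table(topo, pth("topology.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    manifest$artifacts$networks <-
      pth(paste0("network_", names(nets), ".graphml"))
    manifest$artifacts$topology <- pth("topology.tsv")
    nets
  })

  models <- stage("train", {
    scaler <- fit_scaler(grids)
    scaled <- apply_scaler(grids, scaler)
    cfg <- config$model
    m <- list(
      egonet = train_egonet(scaled, cohort$lethal, cfg),
      linreg = suppressWarnings(
        train_baseline(scaled, cohort$lethal, "linreg")),
      rf = train_baseline(scaled, cohort$lethal, "rf", seed = config$seed,
                          n_trees = config$cv$rf_trees)
    )
    for (kind in names(m)) {
      m[[kind]]$scaler <- scaler
      m[[kind]]$uses_relationship_features <- TRUE
      saveRDS(m[[kind]], pth(paste0("model_", kind, ".rds")))
      jsonlite::write_json(config_echo(config)$model,
                           pth(paste0("model_", kind, "_config.json")),
                           auto_unbox = TRUE, digits = NA)
    }
    manifest$artifacts$models <- pth(paste0("model_", names(m), ".rds"))
    m
  })

  stage("evaluate", {
    with_rel <- run_cv(cohort, kinds = config$cv$kinds, k = config$cv$k,
                       n_trials = config$cv$n_trials, seed = config$seed,
                       use_relationship = TRUE, config = config$model,
                       rf_trees = config$cv$rf_trees)
    without_rel <- run_cv(cohort, kinds = config$cv$kinds, k = config$cv$k,
                          n_trials = config$cv$n_trials, seed = config$seed,
                          use_relationship = FALSE, config = config$model,
                          rf_trees = config$cv$rf_trees)
    write_cv_json(with_rel, pth("cv_with_relationship.json"))
    write_cv_json(without_rel, pth("cv_without_relationship.json"))
    manifest$artifacts$cv <- pth(c("cv_with_relationship.json",
                                    "cv_without_relationship.json"))
    NULL
  })

  stage("saliency", {
    folds <- stratified_folds(cohort$lethal, config$cv$k,
                              derive_seed(config$seed, 101))
    fold_models <- lapply(seq_len(config$cv$k), function(f) {
      tr <- grids[, , folds != f, drop = FALSE]
      sc <- fit_scaler(tr)
      cfg <- config$model
      cfg$seed <- derive_seed(config$seed, 1000 + f)
      md <- train_egonet(apply_scaler(tr, sc), cohort$lethal[folds != f],
                         cfg)
      md$scaler <- sc
      md
    })
    map <- class_averaged_importance(fold_models, grids, cohort$lethal,
                                     folds)
    write_importance_csv(map, pth("importance_nonlethal.csv"),
                         pth("importance_lethal.csv"))
    manifest$artifacts$importance <- pth(c("importance_nonlethal.csv",
                                            "importance_lethal.csv"))
    NULL
  })

  manifest <- write_manifest(manifest, pth("manifest.json"))
  invisible(manifest)
}

config_echo <- function(config) {
  g <- config$generator
  list(seed = config$seed,
       generator = list(n_subjects = g$n_subjects,
                        prevalence = g$prevalence,
                        missing_rate = g$missing_rate,
                        sis_mean_shift = g$sis_mean_shift,
                        age_mean_lethal = g$age_mean_lethal,
                        age_mean_nonlethal = g$age_mean_nonlethal,
                        male_prob_lethal = g$male_prob_lethal,
                        male_prob_nonlethal = g$male_prob_nonlethal,
                        seed = g$seed),
       network = config$network,
       model = unclass(config$model),
       cv = config$cv,
       impute_k = config$impute_k)
}

write_manifest <- function(manifest, path) {
  files <- as.character(unlist(manifest$artifacts, use.names = FALSE))
  files <- files[file.exists(files)]
  manifest$checksums <- if (length(files) > 0)
    as.list(tools::md5sum(files)) else list()
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
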