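#' Permutation significance of network edges
#'
#' Shuffles every column independently across subjects, refits the
#' graphical lasso at the observed-data penalty, and computes per-edge
#' two-sided empirical p-values
#' `p = (1 + #\{|null weight| >= |observed|\}) / (n_perm + 1)`.
#' An edge is significant when `p < alpha` and its observed weight is
#' nonzero.
#'
#' @param data Subjects x variables matrix (the observed data).
#' @param penalty Penalty used for the observed fit (re-used for every
#'   null fit).
#' @param n_perm Number of permutations (the source analysis used 10,000;
#'   a few hundred suffice for alpha = .05 at desk scale).
#' @param alpha Significance level.
#' @param seed RNG seed.
#' @param observed Optional precomputed `glasso_fit` of `data` at
#'   `penalty`.
#' @return List: `edge_p` (symmetric matrix), `significant` (logical
#'   matrix), `observed` fit, `n_perm`, `alpha`, `seed`.
#' @export
permutation_significance <- function(data, penalty, n_perm = 1000,
                                     alpha = 0.05, seed = 1,
                                     observed = NULL) {
  stopifnot(n_perm >= 1)
  if (1 / (n_perm + 1) >= alpha)
    warning("n_perm too small to resolve alpha = ", alpha,
            " (minimum attainable p = ", signif(1 / (n_perm + 1), 3), ")")
  data <- as.matrix(data)
  if (is.null(observed)) observed <- estimate_glasso(data, penalty = penalty)
  obs_w <- abs(observed$weights)
  p <- ncol(data)
  counts <- matrix(0L, p, p)
  set.seed(derive_seed(seed, 11))
  n <- nrow(data)
  for (b in seq_len(n_perm)) {
    perm <- apply(data, 2, function(col) col[sample.int(n)])
    S <- stats::cor(perm)
    theta <- glasso_precision(S, penalty)
    null_w <- abs(precision_to_partial(theta))
    counts <- counts + (null_w >= obs_w)
  }
  edge_p <- (1 + counts) / (n_perm + 1)
  diag(edge_p) <- 1
  dimnames(edge_p) <- dimnames(observed$weights)
  significant <- edge_p < alpha & abs(observed$weights) > 1e-10
  diag(significant) <- FALSE
  list(edge_p = edge_p, significant = significant, observed = observed,
       n_perm = n_perm, alpha = alpha, seed = seed)
}

new_intent_network <- function(nodes, weights, edge_p, significant, group,
                               penalty) {
  dimnames(weights) <- dimnames(edge_p) <- dimnames(significant) <-
    list(nodes, nodes)
  net <- structure(
    list(nodes = nodes, edge_weight = weights, edge_p = edge_p,
         significant = significant, group = group, penalty = penalty),
    class = "intent_network"
  )
  net$topology <- topology(net)
  net
}

#' @export
print.intent_network <- function(x, ...) {
  cat("<intent_network> group: ", x$group, "\n", sep = "")
  cat("  nodes: ", length(x$nodes),
      " | significant edges: ", sum(x$significant[upper.tri(x$significant)]),
      " | penalty: ", signif(x$penalty, 4), "\n", sep = "")
  invisible(x)
}

#' Topology of the significant-edge graph
#'
#' Degree and per-node mean unweighted shortest-path length within the
#' node's connected component (lower = more central); isolated nodes get
#' degree 0 and `NA` path length.
#'
#' @param network An `intent_network` (or a list with a `significant`
#'   logical adjacency matrix and `nodes`).
#' @return List of class `topology_report`: `degree`,
#'   `avg_shortest_path` (named vectors), `connected_node_count`,
#'   `edge_count`.
#' @export
topology <- function(network) {
  adj <- network$significant
  nodes <- network$nodes
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected")
  deg <- igraph::degree(g)
  d <- igraph::distances(g)
  avg <- apply(d, 1, function(row) {
    reach <- is.finite(row) & row > 0
    if (!any(reach)) NA_real_ else mean(row[reach])
  })
  names(deg) <- names(avg) <- nodes
  structure(
    list(degree = deg, avg_shortest_path = avg,
         connected_node_count = sum(deg > 0),
         edge_count = sum(adj[upper.tri(adj)])),
    class = "topology_report"
  )
}

#' Group-wise intent networks
#'
#' Splits a preprocessed cohort by the lethality label and, per group,
#' fits the graphical lasso over the 16 node variables (15 calibrated SIS
#' items plus the raw C-SSRS grade as the Fatality node), tests edges by
#' column-wise permutation, and computes the topology report.
#'
#' @param cohort A preprocessed `cohort_table`.
#' @param penalty L1 penalty, or `NULL` for per-group EBIC selection.
#' @param n_perm Permutations per group.
#' @param alpha Edge significance level.
#' @param seed RNG seed.
#' @param permute_all Permute all 16 columns (default); if `FALSE`, the
#'   Fatality column is held fixed under the null.
#' @return List with `lethal` and `nonlethal` `intent_network`s.
#' @export
build_group_networks <- function(cohort, penalty = NULL, n_perm = 1000,
                                 alpha = 0.05, seed = 1,
                                 permute_all = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(cohort$sis_cal) || is.null(cohort$lethal))
    stop("cohort must be preprocessed and labeled", call. = FALSE)
  nodes <- c(sis_labels, "Fatality")
  out <- list()
  for (grp in c("lethal", "nonlethal")) {
    idx <- which(cohort$lethal == (grp == "lethal"))
    if (length(idx) < 30)
      warning("group '", grp, "' has fewer than 30 subjects")
    X <- cbind(cohort$sis_cal[idx, , drop = FALSE],
               cohort$data[[cohort_columns$cssrs]][idx])
    colnames(X) <- nodes
    fit <- estimate_glasso(X, penalty = penalty)
    if (permute_all) {
      sig <- permutation_significance(X, fit$penalty, n_perm = n_perm,
                                      alpha = alpha,
                                      seed = derive_seed(seed, match(grp, c("lethal", "nonlethal"))),
                                      observed = fit)
    } else {
      sig <- permutation_significance_fixed(X, fit, n_perm, alpha,
                                            derive_seed(seed, match(grp, c("lethal", "nonlethal"))),
                                            fixed_col = ncol(X))
    }
    out[[grp]] <- new_intent_network(nodes, fit$weights, sig$edge_p,
                                     sig$significant, grp, fit$penalty)
  }
  out
}

# Variant null: permute every column except `fixed_col`.
permutation_significance_fixed <- function(data, observed, n_perm, alpha,
                                           seed, fixed_col) {
  obs_w <- abs(observed$weights)
  p <- ncol(data)
  n <- nrow(data)
  counts <- matrix(0L, p, p)
  set.seed(derive_seed(seed, 11))
  for (b in seq_len(n_perm)) {
    perm <- data
    for (j in setdiff(seq_len(p), fixed_col))
      perm[, j] <- data[sample.int(n), j]
    theta <- glasso_precision(stats::cor(perm), observed$penalty)
    counts <- counts + (abs(precision_to_partial(theta)) >= obs_w)
  }
  edge_p <- (1 + counts) / (n_perm + 1)
  diag(edge_p) <- 1
  significant <- edge_p < alpha & abs(observed$weights) > 1e-10
  diag(significant) <- FALSE
  list(edge_p = edge_p, significant = significant, observed = observed,
       n_perm = n_perm, alpha = alpha, seed = seed)
}

#' Export an intent network as GraphML and an edge list
#'
#' Node attributes: label, degree, average shortest path; edge attributes:
#' weight, sign, p-value. Only significant edges are written as graph
#' edges.
#'
#' @param network An `intent_network`.
#' @param graphml_path Output GraphML path.
#' @param edges_path Optional TSV edge-list path (all nonzero-weight edges
#'   with p-values and significance flags).
#' @return `graphml_path`, invisibly.
#' @export
write_network_graphml <- function(network, graphml_path,
                                  edges_path = NULL) {
  g <- igraph::graph_from_adjacency_matrix(network$significant * 1,
                                           mode = "undirected")
  igraph::V(g)$label <- network$nodes
  igraph::V(g)$degree <- as.numeric(network$topology$degree)
  igraph::V(g)$avg_shortest_path <-
    as.numeric(network$topology$avg_shortest_path)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) > 0) {
    w <- network$edge_weight[el]
    igraph::E(g)$weight <- w
    igraph::E(g)$sign <- ifelse(w >= 0, "positive", "negative")
    igraph::E(g)$p <- network$edge_p[el]
  }
  igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edges_path)) {
    ut <- which(upper.tri(network$edge_weight) &
                  abs(network$edge_weight) > 1e-10, arr.ind = TRUE)
    df <- data.frame(
      from = network$nodes[ut[, 1]], to = network$nodes[ut[, 2]],
      weight = network$edge_weight[ut], p = network$edge_p[ut],
      significant = network$significant[ut]
    )
    utils::write.table(df, edges_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(graphml_path)
}
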