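# Graphical lasso by block coordinate descent (Friedman, Hastie &
# Tibshirani 2008), operating on a correlation/covariance matrix. Returns
# the penalized precision matrix. Pure R: the node sets here are small
# (16 variables), so the inner lasso is a plain coordinate-descent loop.
glasso_precision <- function(S, rho, tol = 1e-6, maxit = 200) {
  p <- ncol(S)
  if (any(!is.finite(S)))
    stop("validation error: non-finite covariance input", call. = FALSE)
  if (rho < 0) stop("penalty must be non-negative", call. = FALSE)
  if (rho == 0) {
    theta <- tryCatch(solve(S), error = function(e)
      stop("convergence error: singular covariance at penalty 0",
           call. = FALSE))
    return((theta + t(theta)) / 2)
  }
  W <- S
  diag(W) <- diag(S) + rho
  B <- matrix(0, p, p)
  for (it in seq_len(maxit)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- B[idx, j]
      # lasso: min 0.5 b'W11 b - s12'b + rho|b|_1, coordinate descent
      for (inner in seq_len(200)) {
        beta_old <- beta
        for (l in seq_along(idx)) {
          r <- s12[l] - sum(W11[l, -l] * beta[-l])
          beta[l] <- soft_threshold(r, rho) / W11[l, l]
        }
        if (max(abs(beta - beta_old)) < tol * 1e-2) break
      }
      w12 <- drop(W11 %*% beta)
      W[idx, j] <- w12
      W[j, idx] <- w12
      B[idx, j] <- beta
    }
    if (mean(abs(W - W_old)) < tol * mean(abs(S[upper.tri(S)]) + tol))
      return(recover_theta(W, S, B, rho, p))
  }
  stop(sprintf("convergence error: graphical lasso did not converge at penalty %g",
               rho), call. = FALSE)
}

recover_theta <- function(W, S, B, rho, p) {
  theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    beta <- B[idx, j]
    theta[j, j] <- 1 / (W[j, j] - sum(W[idx, j] * beta))
    theta[idx, j] <- -beta * theta[j, j]
  }
  (theta + t(theta)) / 2
}

precision_to_partial <- function(theta) {
  d <- sqrt(diag(theta))
  pc <- -theta / (d %o% d)
  diag(pc) <- 0
  (pc + t(pc)) / 2
}

glasso_loglik <- function(theta, S, n) {
  (n / 2) * (determinant(theta, logarithm = TRUE)$modulus[1] -
               sum(S * theta))
}

#' Select the GLASSO penalty by EBIC
#'
#' Fits the graphical lasso over a log-spaced penalty grid and returns the
#' penalty minimizing the extended BIC
#' `-2 loglik + E log(n) + 4 E gamma log(p)`, with `E` the number of
#' selected edges - the standard convention of the network-psychometrics
#' stack.
#'
#' @param S Sample correlation matrix.
#' @param n Number of observations.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_penalties Grid size.
#' @param penalty_ratio Smallest grid value as a fraction of the maximum
#'   absolute off-diagonal correlation.
#' @return List: `penalty`, `grid`, `ebic` values.
#' @export
select_penalty_ebic <- function(S, n, gamma = 0.5, n_penalties = 30,
                                penalty_ratio = 0.01) {
  p <- ncol(S)
  rho_max <- max(abs(S[upper.tri(S)]))
  if (rho_max <= 0) return(list(penalty = 0.1, grid = 0.1, ebic = NA_real_))
  grid <- exp(seq(log(penalty_ratio * rho_max), log(rho_max),
                  length.out = n_penalties))
  ebic <- rep(NA_real_, n_penalties)
  for (g in seq_along(grid)) {
    theta <- tryCatch(glasso_precision(S, grid[g]), error = function(e) NULL)
    if (is.null(theta)) next
    E <- sum(abs(theta[upper.tri(theta)]) > 1e-8)
    ebic[g] <- -2 * glasso_loglik(theta, S, n) + E * log(n) +
      4 * E * gamma * log(p)
  }
  if (all(is.na(ebic)))
    stop("convergence error: no penalty in the EBIC grid converged",
         call. = FALSE)
  best <- which.min(ebic)
  list(penalty = grid[best], grid = grid, ebic = ebic)
}

#' Estimate a regularized partial-correlation network
#'
#' Fits the graphical lasso to the Pearson correlation matrix of the data
#' and returns the implied partial correlations
#' `-Theta_ij / sqrt(Theta_ii Theta_jj)`. When `penalty` is `NULL` it is
#' selected by EBIC (gamma = 0.5) over a log-spaced grid.
#'
#' @param data Subjects x variables numeric matrix.
#' @param penalty Non-negative L1 penalty, or `NULL` for EBIC selection.
#' @param gamma EBIC gamma.
#' @param min_ratio Warn when `nrow(data) <` this multiple of the variable
#'   count.
#' @return List of class `glasso_fit`: `weights` (partial correlations),
#'   `precision`, `penalty`, `S`, `n`.
#' @export
estimate_glasso <- function(data, penalty = NULL, gamma = 0.5,
                            min_ratio = 3) {
  data <- as.matrix(data)
  if (any(!is.finite(data)))
    stop("validation error: non-finite values in data", call. = FALSE)
  if (ncol(data) < 2) stop("need at least 2 variables", call. = FALSE)
  sds <- apply(data, 2, stats::sd)
  if (any(sds == 0))
    stop("validation error: constant column(s): ",
         paste(colnames(data)[sds == 0], collapse = ", "), call. = FALSE)
  if (nrow(data) < min_ratio * ncol(data))
    warning("fewer than ", min_ratio, "x as many subjects as variables; ",
            "estimates may be unstable")
  S <- stats::cor(data)
  if (is.null(penalty))
    penalty <- select_penalty_ebic(S, nrow(data), gamma = gamma)$penalty
  theta <- glasso_precision(S, penalty)
  structure(list(weights = precision_to_partial(theta), precision = theta,
                 penalty = penalty, S = S, n = nrow(data)),
            class = "glasso_fit")
}
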