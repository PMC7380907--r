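#' SIS node labels
#'
#' The conventional abbreviations for the 15 SIS items plus the C-SSRS
#' fatality node used in network figures.
#' @export
sis_labels <- c("Iso", "Tinter", "ArecInter", "ActHelp", "FinActD",
                "ActPrep", "SNote", "OvertSI", "APurpo", "ExFatal",
                "ConMeth", "SeriAtt", "AttiLiv", "ConResc", "Dimpuls")

# Build a 15x15 correlation matrix whose inverse has the given edge support.
# edges: 2-column matrix of item pairs; w: partial correlation planted on
# each edge (precision off-diagonal -w with unit diagonal, rescaled to a
# correlation matrix, which leaves partial correlations unchanged).
planted_correlation <- function(edges, w) {
  p <- 15
  theta <- diag(p)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    theta[i, j] <- theta[j, i] <- -w[r]
  }
  ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-6)
    stop("planted precision matrix not positive definite", call. = FALSE)
  sigma <- solve(theta)
  stats::cov2cor(sigma)
}

# Edge support of the inverse of a correlation matrix, above tolerance.
inverse_support <- function(corr, tol = 1e-8) {
  theta <- solve(corr)
  pc <- -theta / sqrt(diag(theta) %o% diag(theta))
  idx <- which(upper.tri(pc) & abs(pc) > tol, arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Default planted partial-correlation networks
#'
#' Encodes the qualitative group structure the analysis looks for: in the
#' lethal group, a hub at item 11 (conception of the method's lethality,
#' `ConMeth`) connected to items 10 (`ExFatal`) and 12 (`SeriAtt`), plus a
#' sparse chain among the objective-circumstance items; in the nonlethal
#' group, a hub at item 9 (alleged purpose, `APurpo`) while the
#' method-related items 10 and 11 are completely disconnected.
#'
#' @return A list with `lethal` and `nonlethal`, each holding `corr`
#'   (15 x 15 positive-definite correlation matrix), `truth`
#'   (a `planted_truth`: `group`, `true_edges` 2-column matrix, `hub_item`).
#' @export
default_planted_networks <- function() {
  hub_w <- 0.40
  chain_w <- 0.30
  # Sparse links elsewhere are disjoint pairs so the planted hub is the
  # strictly highest-degree SIS node of its group.
  lethal_edges <- rbind(
    c(10, 11), c(11, 12),                      # ConMeth hub
    c(1, 2), c(3, 4), c(5, 6), c(13, 14)
  )
  lethal_w <- c(hub_w, hub_w, rep(chain_w, 4))
  nonlethal_edges <- rbind(
    c(8, 9), c(9, 12), c(9, 13), c(9, 15),     # APurpo hub
    c(1, 2), c(3, 4), c(5, 6)
  )
  nonlethal_w <- c(rep(0.35, 4), rep(chain_w, 3))
  mk <- function(edges, w, group, hub) {
    corr <- planted_correlation(edges, w)
    truth <- structure(
      list(group = group, true_edges = inverse_support(corr),
           hub_item = hub),
      class = "planted_truth"
    )
    list(corr = corr, truth = truth)
  }
  list(lethal = mk(lethal_edges, lethal_w, "lethal", 11L),
       nonlethal = mk(nonlethal_edges, nonlethal_w, "nonlethal", 9L))
}

#' Synthetic cohort generator configuration
#'
#' Defaults restate the source cohort's published structure: n = 1112
#' subjects, 17.1% lethal prevalence, male fraction 56.3% (lethal) vs 38.7%
#' (nonlethal), mean age 47.3 vs 42.3 years (SDs 18.4 / 18.1), 2.7%
#' missingness, visits between 2013-05-01 and 2013-11-07, and within-group
#' C-SSRS grade frequencies 152/33/5 (lethal 4/5/6) and 177/387/358
#' (nonlethal 1/2/3).
#'
#' @param n_subjects Cohort size.
#' @param prevalence Fraction with a lethal outcome.
#' @param sis_corr_lethal,sis_corr_nonlethal 15x15 positive-definite latent
#'   correlation matrices (defaults: [default_planted_networks()]).
#' @param sis_mean_shift Latent mean offsets added for the lethal group
#'   (default raises items 10--12 by 0.5 SD).
#' @param age_mean_lethal,age_mean_nonlethal,age_sd_lethal,age_sd_nonlethal
#'   Age model (years).
#' @param male_prob_lethal,male_prob_nonlethal Probability of male sex.
#' @param grade_probs_lethal,grade_probs_nonlethal C-SSRS grade
#'   probabilities over grades 4:6 and 1:3 respectively.
#' @param missing_rate MCAR masking rate over SIS and confounder cells.
#' @param date_range Study window for ER visit dates.
#' @param seed Master seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_subjects = 1112,
                             prevalence = 0.171,
                             sis_corr_lethal = NULL,
                             sis_corr_nonlethal = NULL,
                             sis_mean_shift = c(rep(0, 9), 0.5, 0.5, 0.5,
                                                rep(0, 3)),
                             age_mean_lethal = 47.3,
                             age_mean_nonlethal = 42.3,
                             age_sd_lethal = 18.4,
                             age_sd_nonlethal = 18.1,
                             male_prob_lethal = 0.563,
                             male_prob_nonlethal = 0.387,
                             grade_probs_lethal = c(152, 33, 5) / 190,
                             grade_probs_nonlethal = c(177, 387, 358) / 922,
                             missing_rate = 0.027,
                             date_range = as.Date(c("2013-05-01",
                                                    "2013-11-07")),
                             seed = 1L) {
  planted <- default_planted_networks()
  if (is.null(sis_corr_lethal)) sis_corr_lethal <- planted$lethal$corr
  if (is.null(sis_corr_nonlethal)) sis_corr_nonlethal <- planted$nonlethal$corr
  if (!(prevalence > 0 && prevalence < 1))
    stop("config error: prevalence must be in (0,1)", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("config error: missing_rate must be in [0,1)", call. = FALSE)
  for (m in list(sis_corr_lethal, sis_corr_nonlethal)) {
    if (!is.matrix(m) || any(dim(m) != 15) ||
        max(abs(diag(m) - 1)) > 1e-8 || !is_positive_definite(m))
      stop("config error: SIS correlation matrix must be 15x15 ",
           "positive-definite with unit diagonal", call. = FALSE)
  }
  stopifnot(length(sis_mean_shift) == 15,
            abs(sum(grade_probs_lethal) - 1) < 1e-8,
            abs(sum(grade_probs_nonlethal) - 1) < 1e-8)
  structure(
    list(n_subjects = n_subjects, prevalence = prevalence,
         sis_corr_lethal = sis_corr_lethal,
         sis_corr_nonlethal = sis_corr_nonlethal,
         sis_mean_shift = sis_mean_shift,
         age_mean_lethal = age_mean_lethal,
         age_mean_nonlethal = age_mean_nonlethal,
         age_sd_lethal = age_sd_lethal, age_sd_nonlethal = age_sd_nonlethal,
         male_prob_lethal = male_prob_lethal,
         male_prob_nonlethal = male_prob_nonlethal,
         grade_probs_lethal = grade_probs_lethal,
         grade_probs_nonlethal = grade_probs_nonlethal,
         missing_rate = missing_rate, date_range = date_range,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Fixed discretization thresholds: standard-normal tertiles, so each raw
# SIS category has probability 1/3 in the unshifted latent model.
sis_thresholds <- function() stats::qnorm(c(1 / 3, 2 / 3))

#' Generate a seeded synthetic cohort
#'
#' Draws group labels Bernoulli(prevalence); per group, samples latent
#' Gaussian SIS vectors with the group correlation matrix (lethal group
#' shifted by `sis_mean_shift`), discretizes each item to raw scores
#' \{0,1,2\} at fixed standard-normal tertile thresholds, samples
#' confounders (sex, age, visit dates in the study window with the weekend
#' flag derived from the actual weekday, coded categories uniform over
#' their legal codes, log-normal income), assigns C-SSRS grades consistent
#' with the group, then masks SIS and confounder cells MCAR.
#'
#' @param config A [generator_config()].
#' @param return_latent Also return the pre-discretization latent draws
#'   (for checking the planted partial-correlation structure).
#' @return A list of class `synthetic_cohort`: `cohort` (a `cohort_table`),
#'   `truth` (planted truths per group), `config`, and optionally `latent`.
#' @export
generate_cohort <- function(config = generator_config(),
                            return_latent = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  cc <- cohort_columns
  n <- config$n_subjects
  planted <- default_planted_networks()
  truth <- list(
    lethal = structure(list(group = "lethal",
                            true_edges = inverse_support(config$sis_corr_lethal),
                            hub_item = planted$lethal$truth$hub_item),
                       class = "planted_truth"),
    nonlethal = structure(list(group = "nonlethal",
                               true_edges = inverse_support(config$sis_corr_nonlethal),
                               hub_item = planted$nonlethal$truth$hub_item),
                          class = "planted_truth")
  )

  set.seed(derive_seed(config$seed, 1))
  lethal <- stats::rbinom(n, 1, config$prevalence) == 1

  # latent SIS draws, group-specific correlation + mean shift
  set.seed(derive_seed(config$seed, 2))
  latent <- matrix(NA_real_, n, 15)
  for (grp in c(TRUE, FALSE)) {
    idx <- which(lethal == grp)
    if (length(idx) == 0) next
    sigma <- if (grp) config$sis_corr_lethal else config$sis_corr_nonlethal
    z <- matrix(stats::rnorm(length(idx) * 15), length(idx), 15) %*%
      chol(sigma)
    if (grp) z <- sweep(z, 2, config$sis_mean_shift, "+")
    latent[idx, ] <- z
  }
  thr <- sis_thresholds()
  sis_raw <- matrix(0L, n, 15)
  sis_raw[latent > thr[1]] <- 1L
  sis_raw[latent > thr[2]] <- 2L

  set.seed(derive_seed(config$seed, 3))
  male_p <- ifelse(lethal, config$male_prob_lethal, config$male_prob_nonlethal)
  sex <- ifelse(stats::runif(n) < male_p, 1L, 2L)
  age_mu <- ifelse(lethal, config$age_mean_lethal, config$age_mean_nonlethal)
  age_sd <- ifelse(lethal, config$age_sd_lethal, config$age_sd_nonlethal)
  age <- round(pmin(pmax(stats::rnorm(n, age_mu, age_sd), 15), 95))

  set.seed(derive_seed(config$seed, 4))
  dom <- cc$domains
  unif_code <- function(codes) sample(codes, n, replace = TRUE)
  marital <- unif_code(dom$marital_status)
  religion <- unif_code(dom$religion)
  living <- unif_code(dom$living_status)
  education <- unif_code(dom$education)
  urbanicity <- unif_code(dom$urbanicity)
  route <- unif_code(dom$admission_route)
  transport <- unif_code(dom$admission_transport)
  income <- round(stats::rlnorm(n, meanlog = log(2e6), sdlog = 0.7), -4)

  set.seed(derive_seed(config$seed, 5))
  span <- as.integer(config$date_range[2] - config$date_range[1])
  visit <- config$date_range[1] + sample.int(span + 1, n, replace = TRUE) - 1L
  weekend <- ifelse(format(visit, "%u") %in% c("6", "7"), 1L, 2L)
  visit_time <- sample(0:23, n, replace = TRUE)
  discharge <- visit + stats::rpois(n, 3)

  set.seed(derive_seed(config$seed, 6))
  grade <- integer(n)
  grade[lethal] <- sample(4:6, sum(lethal), replace = TRUE,
                          prob = config$grade_probs_lethal)
  grade[!lethal] <- sample(1:3, sum(!lethal), replace = TRUE,
                           prob = config$grade_probs_nonlethal)

  data <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    stringsAsFactors = FALSE
  )
  for (i in 1:15) data[[cc$sis[i]]] <- sis_raw[, i]
  data$sex <- sex; data$age <- age; data$marital_status <- marital
  data$religion <- religion; data$monthly_income <- income
  data$living_status <- living; data$education <- education
  data$urbanicity <- urbanicity; data$er_visit_date <- visit
  data$weekend_visit <- weekend; data$er_visit_time <- visit_time
  data$admission_route <- route; data$admission_transport <- transport
  data$discharge_date <- discharge
  data$cssrs_grade <- grade
  data <- data[, c("subject_id", cc$all)]

  mask <- matrix(FALSE, n, length(cc$all), dimnames = list(NULL, cc$all))
  if (config$missing_rate > 0) {
    set.seed(derive_seed(config$seed, 7))
    maskable <- c(cc$sis, cc$confounders)
    m <- matrix(stats::runif(n * length(maskable)) < config$missing_rate,
                n, length(maskable))
    mask[, maskable] <- m
    for (j in seq_along(maskable))
      data[m[, j], maskable[j]] <- NA
  }

  cohort <- new_cohort_table(data, mask,
                             meta = list(dates_encoded = FALSE,
                                         synthetic = TRUE,
                                         seed = config$seed))
  out <- list(cohort = cohort, truth = truth, config = config)
  if (return_latent) out$latent <- latent
  structure(out, class = "synthetic_cohort")
}

#' Write the planted-truth sidecar
#'
#' @param synth A `synthetic_cohort`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(synth, path) {
  stopifnot(inherits(synth, "synthetic_cohort"))
  tr <- lapply(synth$truth, function(t)
    list(group = t$group, hub_item = t$hub_item,
         true_edges = apply(t$true_edges, 1, function(e)
           paste0(e[1], "-", e[2]))))
  jsonlite::write_json(
    list(truth = tr,
         config = list(n_subjects = synth$config$n_subjects,
                       prevalence = synth$config$prevalence,
                       missing_rate = synth$config$missing_rate,
                       seed = synth$config$seed)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
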