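#' @keywords internal
#' @useDynLib intentnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' Canonical cohort column names
#'
#' The cohort CSV schema: one row per subject, 15 raw SIS item columns
#' (`sis_1` ... `sis_15`, ordinal 0--2), 14 confounder columns collected in
#' the emergency room, and the C-SSRS actual-lethality grade (1--6).
#' Empty cells denote missing values.
#'
#' @format A list with elements `sis` (15 names), `confounders` (14 names),
#'   `cssrs` (one name), `coded`, `continuous`, `dates` (confounder
#'   subsets), and `domains` (legal value sets for coded columns).
#' @export
cohort_columns <- local({
  sis <- paste0("sis_", 1:15)
  confounders <- c(
    "sex", "age", "marital_status", "religion", "monthly_income",
    "living_status", "education", "urbanicity", "er_visit_date",
    "weekend_visit", "er_visit_time", "admission_route",
    "admission_transport", "discharge_date"
  )
  list(
    sis = sis,
    confounders = confounders,
    cssrs = "cssrs_grade",
    all = c(sis, confounders, "cssrs_grade"),
    # coded columns are imputed by neighbour mode, continuous by mean
    coded = c("sex", "marital_status", "religion", "living_status",
              "education", "urbanicity", "weekend_visit",
              "admission_route", "admission_transport"),
    continuous = c("age", "monthly_income", "er_visit_date",
                   "er_visit_time", "discharge_date"),
    dates = c("er_visit_date", "discharge_date"),
    domains = list(
      sex = 1:2, marital_status = 1:6, religion = 1:5,
      living_status = 1:4, education = 1:5, urbanicity = 1:3,
      weekend_visit = 1:2, admission_route = 1:4,
      admission_transport = 1:5
    )
  )
})

new_cohort_table <- function(data, mask, sis_cal = NULL, lethal = NULL,
                             meta = list()) {
  stopifnot(is.data.frame(data), is.matrix(mask),
            nrow(mask) == nrow(data))
  structure(
    list(data = data, mask = mask, sis_cal = sis_cal, lethal = lethal,
         meta = meta),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x$data), " subjects\n", sep = "")
  cat("  missing cells: ", sum(x$mask), " (",
      format(100 * mean(x$mask), digits = 3), "% of data cells)\n", sep = "")
  cat("  dates encoded: ", isTRUE(x$meta$dates_encoded),
      " | imputed: ", isTRUE(x$meta$imputed),
      " | calibrated: ", !is.null(x$sis_cal),
      " | labeled: ", !is.null(x$lethal), "\n", sep = "")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param x A `cohort_table`.
#' @export
n_subjects <- function(x) nrow(x$data)

validate_cohort_values <- function(data) {
  cc <- cohort_columns
  for (col in cc$sis) {
    v <- data[[col]]
    bad <- which(!is.na(v) & !(v %in% 0:2))
    if (length(bad) > 0)
      stop(sprintf("validation error: %s out of domain {0,1,2} at row %d",
                   col, bad[1]), call. = FALSE)
  }
  v <- data[[cc$cssrs]]
  bad <- which(!is.na(v) & !(v %in% 1:6))
  if (length(bad) > 0)
    stop(sprintf("validation error: cssrs_grade out of domain {1..6} at row %d",
                 bad[1]), call. = FALSE)
  bad <- which(!is.na(data$age) & data$age < 0)
  if (length(bad) > 0)
    stop(sprintf("validation error: negative age at row %d", bad[1]),
         call. = FALSE)
  invisible(TRUE)
}

#' Read a cohort table from CSV
#'
#' Parses the documented cohort schema (see [cohort_columns]): a header row
#' naming the 15 SIS items, 14 confounders and the C-SSRS grade, empty
#' cells meaning missing. Date columns are parsed as ISO `YYYY-MM-DD`.
#' No calibration, labeling or imputation is applied.
#'
#' @param path Path to a CSV file.
#' @return A `cohort_table` with the missingness mask set from empty cells.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  cc <- cohort_columns
  missing_cols <- setdiff(c("subject_id", cc$all), names(df))
  if (length(missing_cols) > 0)
    stop("format error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- data.frame(subject_id = df$subject_id, stringsAsFactors = FALSE)
  for (col in cc$all) {
    v <- df[[col]]
    v[v == ""] <- NA
    if (col %in% cc$dates) {
      out[[col]] <- as.Date(v)
      if (any(!is.na(v) & is.na(out[[col]])))
        stop("validation error: unparseable date in column ", col,
             call. = FALSE)
    } else {
      suppressWarnings(num <- as.numeric(v))
      if (any(!is.na(v) & is.na(num)))
        stop("validation error: non-numeric value in column ", col,
             call. = FALSE)
      out[[col]] <- num
    }
  }
  validate_cohort_values(out)
  mask <- sapply(cc$all, function(col) is.na(out[[col]]))
  mask <- matrix(as.logical(mask), nrow = nrow(out),
                 dimnames = list(NULL, cc$all))
  new_cohort_table(out, mask)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: writes the raw data columns with dates as
#' ISO strings and missing values as empty cells.
#'
#' @param table A `cohort_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  df <- table$data
  for (col in cohort_columns$dates)
    if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]], "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Calibrate raw SIS scores
#'
#' Maps the raw 0--2 ordinal item scores to the calibrated 1--3 scale used
#' by the relationship signatures (a shift by one; strictly positive scores
#' are required by the harmonic-mean signature).
#'
#' @param raw Numeric vector/matrix of raw scores in \{0, 1, 2\}.
#' @return `raw + 1`, same shape.
#' @export
calibrate_sis <- function(raw) {
  ok <- is.na(raw) | raw %in% 0:2
  if (!all(ok))
    stop("validation error: raw SIS score outside {0,1,2}", call. = FALSE)
  raw + 1
}

#' Encode a calendar date as a decimal year
#'
#' `year + (day_of_year - 1)/366`, rounded to three decimals, so that
#' 2013-06-30 encodes as 2013.492. Strictly increasing over the days of
#' any one year.
#'
#' @param date A `Date` vector or ISO `YYYY-MM-DD` strings.
#' @return Numeric decimal years (3 decimals).
#' @export
encode_date <- function(date) {
  if (!inherits(date, "Date")) {
    parsed <- tryCatch(as.Date(date), error = function(e) NULL)
    if (is.null(parsed) || any(!is.na(date) & is.na(parsed)))
      stop("validation error: invalid date", call. = FALSE)
    date <- parsed
  }
  year <- as.integer(format(date, "%Y"))
  doy <- as.integer(format(date, "%j"))
  round(year + (doy - 1) / 366, 3)
}

#' Dichotomize a C-SSRS actual-lethality grade
#'
#' Grades 4--6 (moderately severe physical damage up to death) are lethal;
#' grades 1--3 nonlethal.
#'
#' @param cssrs_grade Integer vector of grades in 1--6 (NA allowed).
#' @return Logical vector: `TRUE` for a lethal attempt.
#' @export
label_lethality <- function(cssrs_grade) {
  ok <- is.na(cssrs_grade) | cssrs_grade %in% 1:6
  if (!all(ok))
    stop("validation error: C-SSRS grade outside {1..6}", call. = FALSE)
  cssrs_grade >= 4
}

#' Encode the date columns of a cohort in place
#'
#' Replaces `er_visit_date` / `discharge_date` by their decimal-year
#' encoding (see [encode_date()]).
#'
#' @param table A `cohort_table`.
#' @return The table with numeric date columns and `meta$dates_encoded`.
#' @export
encode_cohort_dates <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  if (isTRUE(table$meta$dates_encoded)) return(table)
  for (col in cohort_columns$dates)
    table$data[[col]] <- encode_date(table$data[[col]])
  table$meta$dates_encoded <- TRUE
  table
}

knn_mode <- function(v) {
  tab <- table(v)
  vals <- as.numeric(names(tab))
  vals[order(-as.integer(tab), vals)][1]
}

#' Impute missing cohort cells by k-nearest neighbours
#'
#' For each incomplete subject, distances to all other subjects are
#' computed as the root-mean-square difference over the standardized
#' columns observed in both; the k nearest neighbours observed at the
#' target cell vote. Ordinal / coded columns receive the neighbour mode
#' (ties broken toward the smaller value), continuous columns the mean.
#' Observed cells are never altered.
#'
#' @param table A `cohort_table` with dates already encoded
#'   (see [encode_cohort_dates()]).
#' @param k Number of neighbours (default 10).
#' @return The imputed table (`mask` all-`FALSE`), with
#'   `meta$imputation` recording the imputed cells and `k`.
#' @export
impute_knn <- function(table, k = 10) {
  stopifnot(inherits(table, "cohort_table"), k >= 1)
  cc <- cohort_columns
  if (!isTRUE(table$meta$dates_encoded) && any(table$mask))
    stop("encode dates before imputation (see encode_cohort_dates)",
         call. = FALSE)
  if (!any(table$mask)) {
    table$meta$imputed <- TRUE
    return(table)
  }
  X <- as.matrix(table$data[, cc$all])
  storage.mode(X) <- "double"
  entirely_missing <- colnames(X)[colSums(!is.na(X)) == 0]
  if (length(entirely_missing) > 0)
    stop("imputation error: column(s) entirely missing: ",
         paste(entirely_missing, collapse = ", "), call. = FALSE)
  mu <- colMeans(X, na.rm = TRUE)
  sd_ <- apply(X, 2, stats::sd, na.rm = TRUE)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  obs <- !is.na(X)
  mode_cols <- c(cc$sis, cc$coded, cc$cssrs)
  imputed_cells <- list()
  todo <- which(rowSums(!obs) > 0)
  for (r in todo) {
    zr <- Z[r, ]
    shared <- obs & matrix(obs[r, ], nrow(Z), ncol(Z), byrow = TRUE)
    shared[r, ] <- FALSE
    diff2 <- sweep(Z, 2, zr)^2
    diff2[!shared] <- NA
    n_shared <- rowSums(shared)
    d <- sqrt(rowSums(diff2, na.rm = TRUE) / pmax(n_shared, 1))
    d[n_shared == 0] <- Inf
    d[r] <- Inf
    for (col in colnames(X)[!obs[r, ]]) {
      eligible <- which(obs[, col] & is.finite(d))
      if (length(eligible) < k)
        stop("imputation error: fewer than k=", k,
             " eligible neighbours for column ", col, call. = FALSE)
      nb <- eligible[order(d[eligible])][seq_len(k)]
      val <- if (col %in% mode_cols) knn_mode(X[nb, col]) else mean(X[nb, col])
      table$data[r, col] <- val
      imputed_cells[[length(imputed_cells) + 1]] <-
        list(row = r, column = col, value = val)
    }
  }
  table$mask[] <- FALSE
  table$meta$imputed <- TRUE
  table$meta$imputation <- list(k = k, n_cells = length(imputed_cells),
                                cells = imputed_cells)
  table
}

#' Full preprocessing chain
#'
#' Encodes dates, labels lethality from the C-SSRS grade, imputes missing
#' cells by kNN, and calibrates the SIS items to 1--3, in that order
#' (imputation runs on raw 0--2 scores).
#'
#' @param table A `cohort_table` as returned by [read_cohort()] or
#'   [generate_cohort()].
#' @param k Neighbours for imputation.
#' @return The preprocessed table: `sis_cal` (n x 15 matrix in 1--3) and
#'   `lethal` (logical) populated, `mask` all-`FALSE`.
#' @export
preprocess_cohort <- function(table, k = 10) {
  table <- encode_cohort_dates(table)
  table$lethal <- label_lethality(table$data[[cohort_columns$cssrs]])
  table <- impute_knn(table, k = k)
  sis <- as.matrix(table$data[, cohort_columns$sis])
  table$sis_cal <- calibrate_sis(sis)
  # C-SSRS may have been imputed for subjects read with a missing grade
  table$lethal <- label_lethality(table$data[[cohort_columns$cssrs]])
  table
}

#' Write an imputation provenance sidecar
#'
#' Records which cells were imputed, with what values, and the `k` used,
#' as JSON next to a cohort CSV.
#'
#' @param table A preprocessed `cohort_table`.
#' @param path Output JSON path.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_imputation_sidecar <- function(table, path, seed = NULL) {
  info <- table$meta$imputation
  if (is.null(info)) info <- list(k = NA, n_cells = 0, cells = list())
  info$seed <- seed
  jsonlite::write_json(info, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
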