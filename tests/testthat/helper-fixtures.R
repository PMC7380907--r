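# Shared fixtures built in code at test time.

# A tiny 3-row cohort CSV; `blank_sis` empties one SIS cell, `bad_sis`
# writes an out-of-domain score.
write_fixture_csv <- function(path, blank_sis = FALSE, bad_sis = FALSE) {
  synth <- generate_cohort(generator_config(n_subjects = 3, seed = 99,
                                            missing_rate = 0))
  df <- synth$cohort$data
  for (col in cohort_columns$dates) df[[col]] <- format(df[[col]], "%Y-%m-%d")
  if (blank_sis) df$sis_3[2] <- NA
  if (bad_sis) df$sis_3[2] <- 5
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# Small preprocessed synthetic cohort shared across model tests.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- preprocess_cohort(
        generate_cohort(generator_config(n_subjects = 250, seed = 7))$cohort)
    cache
  }
})

# Fast E-GONet config for tests (identical architecture family, smaller
# sizes / fewer epochs so the suite stays within its compute budget).
test_egonet_config <- function(epochs = 25, seed = 1, ...) {
  egonet_config(conv_channels = c(8, 16, 32), fc_width = 64,
                epochs = epochs, seed = seed, ...)
}
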