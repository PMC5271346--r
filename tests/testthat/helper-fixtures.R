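# fixtures are generated in code; no data files

random_count_table <- function(n_samples, n_taxa, seed, max_count = 60) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_taxa, lambda = runif(n_taxa, 1, max_count)),
              n_samples, n_taxa, byrow = TRUE)
  ## guarantee positive row sums
  m[, 1] <- m[, 1] + 1L
  rownames(m) <- sprintf("S%02d", seq_len(n_samples))
  colnames(m) <- sprintf("T%02d", seq_len(n_taxa))
  taxon_count_table(m)
}

random_series <- function(j, k, seed, days = NULL) {
  set.seed(seed)
  if (is.null(days)) days <- sort(sample(0:25, j))
  m <- matrix(rpois(j * k, lambda = runif(j * k, 1, 40)) + 1L, j, k)
  subject_series(paste0("subj", seed), days = days, counts = m)
}

write_tsv_fixture <- function(df_matrix, path) {
  df <- data.frame(sample_id = rownames(df_matrix), df_matrix,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## small cohort config for fast pipeline tests
small_cohort_config <- function(seed = 1, ...) {
  cohort_config(n_subjects = c(mild = 8, moderate = 8, severe = 8),
                seed = seed, ...)
}

## independent mutual-information oracle for the Shannon beta decomposition:
## joint p(j, k) = c_jk / c_++ against the product of its marginals
mutual_information_oracle <- function(m) {
  p <- m / sum(m)
  pj <- rowSums(p)
  pk <- colSums(p)
  mi <- 0
  for (j in seq_len(nrow(m))) for (k in seq_len(ncol(m))) {
    if (p[j, k] > 0) mi <- mi + p[j, k] * log(p[j, k] / (pj[j] * pk[k]))
  }
  mi
}
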