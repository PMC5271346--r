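#' Read per-sample metadata
#'
#' The metadata table joins samples to subjects and carries the covariates of
#' the longitudinal design: collection day (days of age), outcome group
#' (e.g. mild/moderate/severe disease), and optionally the total bacterial
#' load in log10 copies per reaction from qPCR.
#'
#' @param path CSV file with required columns `sample_id`, `subject_id`,
#'   `collection_day`, `group`, and optional `bacterial_load_log10`.
#' @param group_levels declared set of group labels; defaults to the sorted
#'   unique labels in the file. A label outside this set is an error.
#' @return a `data.frame` with `group` as a factor.
#' @export
read_sample_metadata <- function(path, group_levels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_metadata(df, group_levels)
}

#' Validate a sample metadata data frame
#'
#' @param df data frame with the columns documented in
#'   [read_sample_metadata()].
#' @inheritParams read_sample_metadata
#' @return the validated data frame, `group` converted to a factor.
#' @export
validate_sample_metadata <- function(df, group_levels = NULL) {
  need <- c("sample_id", "subject_id", "collection_day", "group")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample id(s) in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (anyNA(df$collection_day) || any(df$collection_day < 0))
    stop("collection_day must be non-negative for every sample")
  if (is.null(group_levels)) group_levels <- sort(unique(as.character(df$group)))
  bad <- setdiff(unique(as.character(df$group)), group_levels)
  if (length(bad))
    stop("group label(s) outside the declared set: ",
         paste(bad, collapse = ", "))
  df$group <- factor(as.character(df$group), levels = group_levels)
  df
}

#' Write sample metadata as CSV
#' @param df a metadata data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' A subject's time-ordered series of samples
#'
#' The unit over which all turnover statistics are computed: the serial
#' samples of one subject, strictly ordered by collection day, sharing one
#' taxon index.
#'
#' @param subject_id subject identifier.
#' @param days integer collection days (days of age), strictly increasing
#'   after sorting; duplicates are an error (turnover statistics assume
#'   distinct time points).
#' @param counts matrix of counts, one row per sample in `days` order,
#'   columns = taxa.
#' @param group outcome group label (may be `NA` for ad-hoc series).
#' @param sample_ids optional per-sample identifiers.
#' @param load_log10 optional per-sample bacterial load, log10 copies/reaction.
#' @return an object of class `subject_series`.
#' @examples
#' s <- subject_series("p1", days = c(7, 14),
#'                     counts = rbind(c(10, 0), c(5, 5)))
#' pairwise_turnover(s)
#' @export
subject_series <- function(subject_id, days, counts, group = NA,
                           sample_ids = NULL, load_log10 = NULL) {
  counts <- as.matrix(counts)
  if (length(days) != nrow(counts))
    stop("'days' length must equal the number of sample rows")
  if (anyDuplicated(days))
    stop("subject '", subject_id, "' has two samples on day ",
         days[duplicated(days)][1], "; ambiguous ordering")
  if (is.null(sample_ids)) sample_ids <- rownames(counts)
  if (is.null(sample_ids))
    sample_ids <- paste0(subject_id, "_d", days)
  o <- order(days)
  structure(list(subject_id = as.character(subject_id),
                 group = group,
                 days = as.numeric(days)[o],
                 counts = counts[o, , drop = FALSE],
                 sample_ids = as.character(sample_ids)[o],
                 load_log10 = if (is.null(load_log10)) NULL
                              else as.numeric(load_log10)[o]),
            class = "subject_series")
}

#' @export
print.subject_series <- function(x, ...) {
  cat(sprintf("subject_series '%s' (group %s): %d samples on days %s\n",
              x$subject_id, as.character(x$group), length(x$days),
              paste(x$days, collapse = ", ")))
  invisible(x)
}

#' Group samples into per-subject time series
#'
#' Joins a count table to its metadata and partitions the samples into one
#' [subject_series()] per subject, sorted by collection day. Every retained
#' sample appears in exactly one series. Subjects with fewer than
#' `min_samples` samples are dropped (the longitudinal analysis uses subjects
#' with at least two aspirates).
#'
#' @param x a `taxon_count_table`.
#' @param metadata metadata data frame (see [read_sample_metadata()]); every
#'   sample id in `x` must appear exactly once.
#' @param min_samples minimum samples per retained subject (default 2).
#' @return named list of `subject_series`.
#' @export
build_subject_series <- function(x, metadata, min_samples = 2) {
  stopifnot(is_taxon_count_table(x))
  metadata <- validate_sample_metadata(metadata,
                                       group_levels = levels(metadata$group))
  ids <- rownames(x$counts)
  orphan <- setdiff(ids, metadata$sample_id)
  if (length(orphan))
    stop("sample(s) missing from metadata: ", paste(orphan, collapse = ", "))
  md <- metadata[match(ids, metadata$sample_id), ]
  dup <- duplicated(md[, c("subject_id", "collection_day")])
  if (any(dup))
    stop("subject '", md$subject_id[dup][1], "' has two samples on day ",
         md$collection_day[dup][1], "; ambiguous ordering")
  series <- lapply(split(seq_along(ids), md$subject_id), function(i) {
    subject_series(md$subject_id[i[1]],
                   days = md$collection_day[i],
                   counts = x$counts[i, , drop = FALSE],
                   group = as.character(md$group[i[1]]),
                   sample_ids = ids[i],
                   load_log10 = if ("bacterial_load_log10" %in% names(md))
                     md$bacterial_load_log10[i] else NULL)
  })
  series[vapply(series, function(s) length(s$days), 0L) >= min_samples]
}
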