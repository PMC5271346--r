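## stamped CSV output: every table carries the config hash and seed in a
## header comment line so results are traceable to the run that made them
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config), tf)
  unname(tools::md5sum(tf))
}

write_stamped_csv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%s", hash,
                     if (is.null(seed)) "NA" else seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

log_msg <- function(..., log_con = NULL) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(log_con)) writeLines(msg, log_con)
}

#' Simulate a cohort and write it to disk
#'
#' Runs [generate_cohort()] and writes the count table (TSV), the sample
#' metadata (CSV) and the truth record (flat key/value text) into `outdir`.
#' With a fixed seed the outputs are byte-identical across runs.
#'
#' @param config a [cohort_config()].
#' @param outdir output directory (created if needed).
#' @param null_cohort simulate under [generate_null_cohort()] instead?
#' @return invisibly, the list returned by the generator, with a `files`
#'   element naming the written paths.
#' @export
run_simulate <- function(config, outdir, null_cohort = FALSE) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  cohort <- if (null_cohort) generate_null_cohort(config)
            else generate_cohort(config)
  files <- c(counts = file.path(outdir, "counts.tsv"),
             metadata = file.path(outdir, "metadata.csv"),
             truth = file.path(outdir, "truth.tsv"))
  write_count_table(cohort$table, files["counts"])
  write_sample_metadata(cohort$metadata, files["metadata"])
  write_truth_record(cohort$truth, files["truth"])
  message("simulated cohort written to ", outdir, " (seed ", config$seed, ")")
  cohort$files <- files
  invisible(cohort)
}

select_cross_sectional <- function(metadata, window = c(5, 9),
                                   target_day = 7) {
  stopifnot(window[1] <= window[2])
  md <- metadata[metadata$collection_day >= window[1] &
                   metadata$collection_day <= window[2], ]
  if (nrow(md) == 0)
    stop("no samples fall inside the cross-sectional window [",
         window[1], ", ", window[2], "]")
  picked <- lapply(split(md, md$subject_id), function(d) {
    dist <- abs(d$collection_day - target_day)
    ## tie (equidistant from the target day) -> the earlier sample
    d[order(dist, d$collection_day), ][1, ]
  })
  do.call(rbind, c(picked, make.row.names = FALSE))
}

#' Cross-sectional analysis around day 7
#'
#' Selects one sample per subject inside the day window (the sample closest
#' to the target day; ties go to the earlier day), then computes per-sample
#' alpha diversity and evenness, per-group summaries of diversity and
#' bacterial load, and Kruskal-Wallis rank tests across groups. Subjects
#' with no sample inside the window are excluded.
#'
#' @param table a [taxon_count_table()].
#' @param metadata sample metadata (see [read_sample_metadata()]).
#' @param window inclusive day window, default `c(5, 9)`.
#' @param target_day day the selected sample should be closest to.
#' @param base Shannon log base.
#' @param outdir optional directory for `alpha.csv`, `cross_sectional_groups.csv`
#'   and `report.txt`; `NULL` writes nothing.
#' @param seed recorded in output headers (the analysis itself is
#'   deterministic).
#' @return list: `selected` (metadata rows used), `alpha` (per-sample
#'   results), `group_summary`, `tests` (Kruskal-Wallis p-values).
#' @export
run_cross_sectional <- function(table, metadata, window = c(5, 9),
                                target_day = 7, base = 2, outdir = NULL,
                                seed = NULL) {
  stopifnot(is_taxon_count_table(table))
  metadata <- validate_sample_metadata(metadata,
                                       group_levels = levels(metadata$group))
  sel <- select_cross_sectional(metadata, window, target_day)
  sub <- taxon_count_table(table$counts[sel$sample_id, , drop = FALSE],
                           rare_taxon = table$rare_taxon)
  alpha <- alpha_diversity(sub, base = base)
  alpha <- merge(alpha, sel[, c("sample_id", "subject_id", "group",
                                intersect("bacterial_load_log10",
                                          names(sel)))],
                 by = "sample_id", sort = FALSE)
  has_load <- "bacterial_load_log10" %in% names(alpha)
  agg <- function(v) c(n = sum(!is.na(v)),
                       median = stats::median(v, na.rm = TRUE),
                       iqr = stats::IQR(v, na.rm = TRUE))
  group_summary <- do.call(rbind, lapply(split(alpha, alpha$group), function(d)
    data.frame(group = d$group[1],
               n = nrow(d),
               median_shannon = stats::median(d$shannon),
               median_evenness = stats::median(d$evenness, na.rm = TRUE),
               median_load_log10 = if (has_load)
                 stats::median(d$bacterial_load_log10, na.rm = TRUE)
               else NA_real_)))
  tests <- data.frame(
    outcome = c("shannon", "evenness", if (has_load) "bacterial_load_log10"),
    kruskal_p = c(
      stats::kruskal.test(alpha$shannon, alpha$group)$p.value,
      stats::kruskal.test(alpha$evenness, alpha$group)$p.value,
      if (has_load)
        stats::kruskal.test(alpha$bacterial_load_log10, alpha$group)$p.value))
  res <- list(selected = sel, alpha = alpha, group_summary = group_summary,
              tests = tests)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    h <- config_hash(list(window = window, target_day = target_day,
                          base = base))
    write_stamped_csv(alpha, file.path(outdir, "alpha.csv"), h, seed)
    write_stamped_csv(group_summary,
                      file.path(outdir, "cross_sectional_groups.csv"), h, seed)
    rpt <- c("Cross-sectional analysis",
             sprintf("window [%g, %g] days, target day %g; %d subjects",
                     window[1], window[2], target_day, nrow(sel)),
             sprintf("%s: Kruskal-Wallis p = %.4f", tests$outcome,
                     tests$kruskal_p))
    writeLines(rpt, file.path(outdir, "report.txt"))
  }
  res
}

#' Longitudinal turnover and trajectory analysis
#'
#' The full longitudinal pipeline on subjects with at least `min_samples`
#' aspirates: per-subject Shannon beta diversity as a normalized Hill number
#' and pairwise Morisita-Horn similarities ([turnover_tables()]); a
#' log-normal GEE comparing MH across groups with repeated measures; a GEE
#' time-trend of bacterial load (skipped with a notice when no load column
#' is present); and a beta-binomial join-point mixed model for each taxon in
#' `taxa`, with pairwise group contrasts of mean relative abundance at
#' `contrast_days`.
#'
#' @inheritParams run_cross_sectional
#' @param min_samples minimum samples per subject (default 2).
#' @param taxa taxa to model longitudinally (default the two dominant
#'   genera).
#' @param knot `"fixed"` (use `knot_day`) or `"select"` (data-driven via
#'   [select_knot()], pooled across groups).
#' @param knot_day knot used when `knot = "fixed"` and the fallback for
#'   `"select"`.
#' @param contrast_days days for group contrasts of mean RA.
#' @param outdir optional output directory (`turnover_subject.csv`,
#'   `turnover_pairs.csv`, `gee_mh.csv`, `gee_load.csv`,
#'   `joinpoint_<taxon>.csv`, `report.txt`).
#' @return list: `series`, `turnover` (subject + pairs tables), `gee_mh`,
#'   `gee_load` (or `NULL`), `joinpoint` (named list of fits), `knot_used`.
#' @export
run_longitudinal <- function(table, metadata, min_samples = 2,
                             taxa = c("Staphylococcus", "Ureaplasma"),
                             knot = c("fixed", "select"), knot_day = 10,
                             contrast_days = 14, outdir = NULL, seed = NULL) {
  stopifnot(is_taxon_count_table(table))
  knot <- match.arg(knot)
  metadata <- validate_sample_metadata(metadata,
                                       group_levels = levels(metadata$group))
  if (nlevels(droplevels(metadata$group)) < 2)
    stop("fewer than 2 groups present; group comparisons undefined")
  series <- build_subject_series(table, metadata, min_samples = min_samples)
  to <- turnover_tables(series)

  gee_mh <- fit_gee_lognormal(to$pairs$morisita_horn, to$pairs$subject_id,
                              to$pairs$group)

  gee_load <- NULL
  if ("bacterial_load_log10" %in% names(metadata) &&
      any(!is.na(metadata$bacterial_load_log10))) {
    keep <- metadata$subject_id %in% names(series) &
      !is.na(metadata$bacterial_load_log10)
    md <- metadata[keep, ]
    gee_load <- fit_gee_lognormal(md$bacterial_load_log10, md$subject_id,
                                  md$group, time = md$collection_day / 7,
                                  values_are_log = TRUE)
  } else {
    message("no bacterial load column: load analyses skipped")
  }

  taxa <- intersect(taxa, colnames(table$counts))
  fits <- list()
  knot_used <- knot_day
  for (tx in taxa) {
    k <- knot_day
    if (knot == "select") {
      long <- assemble_joinpoint_data(series, tx)
      k <- as.numeric(select_knot(long$day, long$y, long$n,
                                  default_knot = knot_day))
    }
    knot_used <- k
    fits[[tx]] <- fit_betabin_joinpoint(series, tx, knot = k,
                                        contrast_days = contrast_days)
  }

  res <- list(series = series, turnover = to, gee_mh = gee_mh,
              gee_load = gee_load, joinpoint = fits, knot_used = knot_used)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    h <- config_hash(list(min_samples = min_samples, taxa = taxa,
                          knot = knot, knot_day = knot_day,
                          contrast_days = contrast_days))
    write_stamped_csv(to$subjects, file.path(outdir, "turnover_subject.csv"),
                      h, seed)
    write_stamped_csv(to$pairs, file.path(outdir, "turnover_pairs.csv"),
                      h, seed)
    write_stamped_csv(gee_mh$contrasts, file.path(outdir, "gee_mh.csv"),
                      h, seed)
    if (!is.null(gee_load))
      write_stamped_csv(gee_load$time_slope,
                        file.path(outdir, "gee_load.csv"), h, seed)
    for (tx in names(fits))
      write_stamped_csv(fits[[tx]]$coefficients,
                        file.path(outdir, paste0("joinpoint_", tx, ".csv")),
                        h, seed)
    rpt <- utils::capture.output({
      cat("Longitudinal analysis:", length(series), "subjects,",
          nrow(to$pairs), "within-subject sample pairs\n\n")
      cat("Median normalized Hill number by group:\n")
      print(tapply(to$subjects$hill_normalized, to$subjects$group,
                   stats::median))
      cat("\nMorisita-Horn GEE:\n"); print(gee_mh)
      if (!is.null(gee_load)) { cat("\nBacterial load GEE:\n"); print(gee_load) }
      for (tx in names(fits)) { cat("\n"); print(fits[[tx]]) }
    })
    writeLines(rpt, file.path(outdir, "report.txt"))
  }
  res
}
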