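#' Configuration for the synthetic longitudinal cohort generator
#'
#' Bundles every knob of [generate_cohort()]. The defaults emulate the
#' sampling design of a multi-site tracheal-aspirate study of ventilated
#' preterm infants: serial aspirates at enrollment (around day 3 of age) and
#' at target days 7, 14 and 21, each within +/- 48 hours; three outcome
#' groups (mild/moderate/severe disease) of 25/30/39 subjects; 2-4 samples
#' per subject with median 2; per-sample sequencing depth spanning 6,451 to
#' 196,691 reads; communities dominated by *Staphylococcus* and *Ureaplasma*;
#' stronger community drift (hence more turnover) with increasing severity;
#' and total bacterial load rising by about 1.05 log10 copies/reaction per
#' week.
#'
#' Two target taxa carry explicit join-point logit-linear trajectories
#' (intercept, pre-knot slope, slope change at the knot, knot at day 10) and
#' receive a per-taxon subject random intercept plus beta-binomial
#' overdispersion; the remaining taxa are exchangeable background whose
#' composition evolves as a Dirichlet random walk with group-specific
#' concentration (lower concentration = larger steps = more turnover).
#'
#' @param n_subjects named integer vector: subjects per group.
#' @param collection_days target collection days; the first is the
#'   enrollment visit, which is always sampled.
#' @param jitter_days integer half-width of the uniform day jitter (+/- 48 h
#'   = 2 days).
#' @param missingness probability that each post-enrollment visit is missed;
#'   if all are missed one is retained at random so every subject keeps at
#'   least 2 samples. The default 0.6 puts samples/subject in 2..4 with
#'   median 2.
#' @param depth_range min/max sequencing depth; depths are drawn log-uniform
#'   (only the range of the emulated study is known, not the shape).
#' @param n_taxa total taxa including the two targets.
#' @param drift_concentration named per-group Dirichlet random-walk
#'   concentration for the background composition.
#' @param staph_trajectory,urea_trajectory named lists of per-group
#'   `c(intercept, slope_pre, slope_change)` on the logit scale for the two
#'   target taxa.
#' @param knot_day knot of the generating trajectories.
#' @param dispersion named per-group beta-binomial dispersion `phi`.
#' @param re_sd SD of the per-subject (and per-target-taxon) random logit
#'   intercept.
#' @param load_intercept,load_slope_per_week,load_sd bacterial-load model:
#'   `load_log10 = intercept + slope * day/7 + Normal(0, sd^2)`.
#' @param seed integer seed; a fixed seed gives bit-identical cohorts.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_subjects = c(mild = 25, moderate = 30, severe = 39),
    collection_days = c(3, 7, 14, 21),
    jitter_days = 2,
    missingness = 0.6,
    depth_range = c(6451, 196691),
    n_taxa = 18,
    drift_concentration = c(mild = 40, moderate = 15, severe = 6),
    staph_trajectory = list(mild = c(-2.5, 0.35, -0.65),
                            moderate = c(-2.5, 0.22, -0.40),
                            severe = c(-2.5, 0.10, -0.18)),
    urea_trajectory = list(mild = c(-4.5, 0.02, -0.02),
                           moderate = c(-3.6, 0.02, -0.02),
                           severe = c(-2.6, 0.02, -0.02)),
    knot_day = 10,
    dispersion = c(mild = 0.08, moderate = 0.12, severe = 0.18),
    re_sd = 1.0,
    load_intercept = 3.8,
    load_slope_per_week = 1.05,
    load_sd = 0.6,
    seed = 1L) {
  cfg <- list(n_subjects = n_subjects, collection_days = collection_days,
              jitter_days = jitter_days, missingness = missingness,
              depth_range = depth_range, n_taxa = n_taxa,
              drift_concentration = drift_concentration,
              staph_trajectory = staph_trajectory,
              urea_trajectory = urea_trajectory, knot_day = knot_day,
              dispersion = dispersion, re_sd = re_sd,
              load_intercept = load_intercept,
              load_slope_per_week = load_slope_per_week, load_sd = load_sd,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  grp <- names(cfg$n_subjects)
  if (is.null(grp) || any(grp == ""))
    stop("n_subjects must be a named vector of group sizes")
  for (field in c("drift_concentration", "staph_trajectory",
                  "urea_trajectory", "dispersion")) {
    missing_g <- setdiff(grp, names(cfg[[field]]))
    if (length(missing_g))
      stop("group label(s) without ", field, " parameters: ",
           paste(missing_g, collapse = ", "))
  }
  stopifnot(cfg$missingness >= 0, cfg$missingness <= 1,
            all(cfg$depth_range > 0), diff(cfg$depth_range) >= 0,
            all(unlist(cfg$drift_concentration) > 0),
            all(unlist(cfg$dispersion) >= 0), cfg$re_sd >= 0,
            cfg$n_taxa >= 3, cfg$jitter_days >= 0)
  invisible(cfg)
}

background_taxa <- c(
  "Enterococcus", "Escherichia", "Klebsiella", "Pseudomonas",
  "Acinetobacter", "Streptococcus", "Corynebacterium", "Prevotella",
  "Haemophilus", "Neisseria", "Veillonella", "Moraxella", "Lactobacillus",
  "Enterobacter", "Serratia", "Mycoplasma", "Bacteroides", "Stenotrophomonas",
  "Rothia", "Fusobacterium", "Gemella", "Actinomyces", "Micrococcus",
  "Delftia")

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

joinpoint_logit <- function(traj, day, knot) {
  traj[1] + traj[2] * day + traj[3] * pmax(day - knot, 0)
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates a taxon count table, sample metadata and a truth record under
#' the generative model described in [cohort_config()]: per subject a random
#' logit intercept for each target taxon; per visit a jittered collection
#' day, a log-uniform sequencing depth, beta-binomially thinned counts for
#' the two target taxa along their group-specific join-point trajectories,
#' multinomial background counts from a group-concentration Dirichlet random
#' walk, and a noisy increasing bacterial load.
#'
#' @param config a [cohort_config()].
#' @return list with `table` (a [taxon_count_table()]), `metadata` (data
#'   frame as in [read_sample_metadata()]), and `truth` (nested list of
#'   every generating parameter plus per-subject latent intercepts; see
#'   [write_truth_record()]).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  grp_labels <- names(config$n_subjects)
  n_bg <- config$n_taxa - 2L
  if (n_bg > length(background_taxa))
    taxa_bg <- c(background_taxa,
                 paste0("Taxon", seq_len(n_bg - length(background_taxa))))
  else taxa_bg <- background_taxa[seq_len(n_bg)]
  taxa <- c("Staphylococcus", "Ureaplasma", taxa_bg)

  jit <- function() if (config$jitter_days == 0) 0L else
    sample.int(2L * config$jitter_days + 1L, 1L) - config$jitter_days - 1L

  counts <- NULL
  meta <- NULL
  subj_truth <- NULL
  sid <- 0L
  for (gl in grp_labels) {
    conc <- config$drift_concentration[[gl]]
    phi <- config$dispersion[[gl]]
    tr_s <- config$staph_trajectory[[gl]]
    tr_u <- config$urea_trajectory[[gl]]
    for (i in seq_len(config$n_subjects[[gl]])) {
      sid <- sid + 1L
      subject <- sprintf("P%03d", sid)
      b_s <- stats::rnorm(1, 0, config$re_sd)
      b_u <- stats::rnorm(1, 0, config$re_sd)
      ## visit schedule: enrollment always; later visits each kept with
      ## probability 1 - missingness, at least one retained
      nvis <- length(config$collection_days)
      keep <- c(TRUE, stats::runif(nvis - 1) >= config$missingness)
      if (nvis > 1 && !any(keep[-1]))
        keep[1 + sample.int(nvis - 1, 1)] <- TRUE
      repeat {
        days <- pmax(config$collection_days +
                       vapply(seq_len(nvis), function(k) as.integer(jit()),
                              0L), 0)
        if (!anyDuplicated(days[keep])) break
      }
      days <- days[keep]
      pi_bg <- rdirichlet1(rep(2, n_bg))
      for (v in seq_along(days)) {
        day <- days[v]
        if (v > 1) pi_bg <- rdirichlet1(conc * pi_bg + 0.01)
        depth <- round(exp(stats::runif(1, log(config$depth_range[1]),
                                        log(config$depth_range[2]))))
        mu_s <- stats::plogis(joinpoint_logit(tr_s, day, config$knot_day) + b_s)
        y_s <- rbetabinom(1, depth, mu_s, phi)
        mu_u <- stats::plogis(joinpoint_logit(tr_u, day, config$knot_day) + b_u)
        rest <- depth - y_s
        y_u <- if (rest > 0)
          rbetabinom(1, rest, min(mu_u / max(1 - mu_s, 1e-8), 0.995), phi)
        else 0L
        y_bg <- drop(stats::rmultinom(1, depth - y_s - y_u, pi_bg))
        counts <- rbind(counts, c(y_s, y_u, y_bg))
        meta <- rbind(meta, data.frame(
          sample_id = sprintf("%s_d%02d", subject, day),
          subject_id = subject, collection_day = day, group = gl,
          bacterial_load_log10 = config$load_intercept +
            config$load_slope_per_week * day / 7 +
            stats::rnorm(1, 0, config$load_sd)))
      }
      subj_truth <- rbind(subj_truth, data.frame(
        subject_id = subject, group = gl, b_staph = b_s, b_urea = b_u))
    }
  }
  rownames(counts) <- meta$sample_id
  colnames(counts) <- taxa
  list(table = taxon_count_table(counts),
       metadata = validate_sample_metadata(meta, group_levels = grp_labels),
       truth = list(config = unclass(config), subjects = subj_truth))
}

#' Generate a null cohort (no group differences)
#'
#' Same generator as [generate_cohort()] but with every group-specific
#' parameter (trajectories, drift concentration, dispersion) forced equal to
#' the first group's value, so the group labels carry no signal. Used for
#' type-I-error simulations.
#'
#' @inheritParams generate_cohort
#' @return as [generate_cohort()].
#' @export
generate_null_cohort <- function(config) {
  validate_cohort_config(config)
  grp <- names(config$n_subjects)
  for (field in c("drift_concentration", "dispersion")) {
    config[[field]][] <- config[[field]][[grp[1]]]
  }
  for (field in c("staph_trajectory", "urea_trajectory")) {
    config[[field]] <- stats::setNames(
      rep(config[[field]][grp[1]], length(grp)), grp)
  }
  generate_cohort(config)
}

flatten_kv <- function(x, prefix = character(0)) {
  if (is.data.frame(x)) {
    out <- list()
    for (r in seq_len(nrow(x))) for (cn in names(x))
      out[[paste(c(prefix, r, cn), collapse = ".")]] <- x[[cn]][r]
    return(out)
  }
  if (is.list(x)) {
    nm <- names(x)
    if (is.null(nm)) nm <- seq_along(x)
    out <- list()
    for (k in seq_along(x))
      out <- c(out, flatten_kv(x[[k]], c(prefix, nm[k])))
    return(out)
  }
  if (length(x) == 1 && is.null(names(x)))
    return(stats::setNames(list(x), paste(prefix, collapse = ".")))
  nm <- names(x)
  if (is.null(nm)) nm <- seq_along(x)
  out <- list()
  for (k in seq_along(x))
    out[[paste(c(prefix, nm[k]), collapse = ".")]] <- unname(x[k])
  out
}

#' Serialize / restore a truth record
#'
#' The truth record of a synthetic cohort (all generator parameters plus
#' per-subject latent values) is written as a flat two-column tab-delimited
#' key/value text file, one scalar per line, keys joined by `.`. Reading
#' returns the flat named list (numbers as numeric, everything else as
#' character); the flat form round-trips exactly.
#'
#' @param truth nested list (the `truth` element of [generate_cohort()]'s
#'   result), or any nested list of scalars/vectors.
#' @param path file path.
#' @return `write_truth_record`: `path`, invisibly. `read_truth_record`: a
#'   flat named list.
#' @export
write_truth_record <- function(truth, path) {
  kv <- flatten_kv(truth)
  vals <- vapply(kv, function(v)
    if (is.numeric(v)) format(v, digits = 17) else as.character(v), "")
  writeLines(paste(names(kv), vals, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_truth_record
#' @export
read_truth_record <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(parts, `[`, "", 1)
  vals <- vapply(parts, function(p) paste(p[-1], collapse = "\t"), "")
  num <- suppressWarnings(as.numeric(vals))
  out <- as.list(ifelse(is.na(num), vals, num))
  out <- lapply(seq_along(out), function(i)
    if (is.na(num[i])) vals[i] else num[i])
  stats::setNames(out, keys)
}
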