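#' Multi-sample Shannon beta diversity of a subject, as a Hill number
#'
#' Quantifies how many distinct bacterial communities a subject's serial
#' samples represent. With counts `c_jk` (sample `j`, taxon `k`), per-sample
#' totals `c_j+`, per-taxon totals `c_+k` and grand total `c_++`, the
#' abundance-weighted Shannon beta diversity is
#'
#' \deqn{H_\beta = \sum_j \frac{c_{j+}}{c_{++}} \sum_k \frac{c_{jk}}{c_{j+}}
#'   \ln\!\left( \frac{c_{jk}/c_{j+}}{c_{+k}/c_{++}} \right)}
#'
#' i.e. the average Kullback-Leibler divergence of each sample's composition
#' from the subject's pooled composition, which equals the mutual information
#' between the sample label and the taxon label (`0 ln 0 = 0`). It is
#' computed in nats and expressed as a Hill number `exp(H_beta)`, the
#' effective number of communities: 1 when all samples share one composition,
#' up to `N` (the number of samples) when the samples are fully disjoint with
#' equal depths.
#'
#' @param x a [subject_series()] with at least two samples, or a counts
#'   matrix with samples as rows (every row sum positive).
#' @return list with `shannon_beta_nats` and `hill = exp(shannon_beta_nats)`.
#' @seealso [normalize_hill()], [pairwise_turnover()]
#' @examples
#' # four samples, each entirely one distinct taxon: 4 effective communities
#' shannon_beta_hill(diag(4) * 1000)$hill
#' @export
shannon_beta_hill <- function(x) {
  m <- if (inherits(x, "subject_series")) x$counts else as.matrix(x)
  if (nrow(m) < 2)
    stop("turnover is undefined for a single-sample series")
  row_tot <- rowSums(m)
  if (any(row_tot == 0)) stop("zero-total sample in series")
  grand <- sum(row_tot)
  w <- row_tot / grand
  q <- m / row_tot                 # within-sample composition
  qbar <- colSums(m) / grand       # pooled composition
  ratio <- sweep(q, 2, qbar, "/")
  term <- q * log(ratio)
  term[m == 0] <- 0                # 0 * ln 0 := 0
  hb <- sum(w * rowSums(term))
  hb <- max(hb, 0)                 # guard tiny negative round-off
  list(shannon_beta_nats = hb, hill = exp(hb))
}

#' Normalize a Hill number for the number of samples
#'
#' The effective number of communities depends on how many samples were
#' collected; `(hill - 1) / (j - 1)` rescales it to `[0, 1]` so subjects with
#' different sample counts are comparable (0 = identical communities, 1 =
#' every sample a distinct community).
#'
#' @param hill Hill number (`>= 1`) from [shannon_beta_hill()].
#' @param j number of samples it was computed from (`>= 2`).
#' @return normalized value in `[0, 1]` (when `hill <= j`).
#' @export
normalize_hill <- function(hill, j) {
  if (any(j < 2))
    stop("normalization is undefined for fewer than 2 samples")
  if (any(hill < 1 - 1e-12)) stop("hill must be >= 1")
  (hill - 1) / (j - 1)
}

#' Morisita-Horn similarity between two samples
#'
#' Abundance-based similarity `2 sum(p q) / (sum(p^2) + sum(q^2))` computed
#' on within-sample proportions `p`, `q`, so the value is invariant to
#' sequencing depth. Ranges over `[0, 1]`: 1 iff the compositions are
#' proportional, 0 iff the supports are disjoint; symmetric in its arguments.
#' Lower values indicate greater community turnover between the two samples.
#'
#' @param x,y count (or abundance) vectors over the same taxon index, each
#'   with positive sum.
#' @return similarity in `[0, 1]`.
#' @examples
#' morisita_horn(c(10, 0), c(5, 5))  # 2/3
#' @export
morisita_horn <- function(x, y) {
  if (length(x) != length(y))
    stop("count vectors must share one taxon index (length mismatch)")
  if (sum(x) <= 0 || sum(y) <= 0) stop("both samples must have positive totals")
  p <- x / sum(x)
  q <- y / sum(y)
  2 * sum(p * q) / (sum(p^2) + sum(q^2))
}

#' Within-subject turnover summary
#'
#' Computes, for one subject's series, the multi-sample Shannon beta
#' diversity (in nats and as a Hill number), its normalization for the number
#' of samples, and the Morisita-Horn similarity for every pair of samples
#' together with the day interval separating them.
#'
#' @param x a [subject_series()] with at least two samples.
#' @return object of class `turnover_result`: a list with `subject_id`,
#'   `group`, `n_samples`, `shannon_beta_nats`, `hill`, `hill_normalized`,
#'   and `pairwise` (data frame: `day_a`, `day_b`, `interval_days`,
#'   `morisita_horn`, one row per unordered pair).
#' @export
pairwise_turnover <- function(x) {
  stopifnot(inherits(x, "subject_series"))
  j <- nrow(x$counts)
  hb <- shannon_beta_hill(x)
  pairs <- utils::combn(j, 2)
  pw <- data.frame(
    day_a = x$days[pairs[1, ]],
    day_b = x$days[pairs[2, ]],
    interval_days = abs(x$days[pairs[2, ]] - x$days[pairs[1, ]]),
    morisita_horn = apply(pairs, 2, function(ij)
      morisita_horn(x$counts[ij[1], ], x$counts[ij[2], ]))
  )
  structure(list(subject_id = x$subject_id, group = x$group, n_samples = j,
                 shannon_beta_nats = hb$shannon_beta_nats, hill = hb$hill,
                 hill_normalized = normalize_hill(hb$hill, j),
                 pairwise = pw),
            class = "turnover_result")
}

#' @export
print.turnover_result <- function(x, ...) {
  cat(sprintf(
    "turnover_result '%s' (group %s): %d samples\n  Hill %.4f (%.4f nats), normalized %.4f; %d sample pairs, mean MH %.4f\n",
    x$subject_id, as.character(x$group), x$n_samples, x$hill,
    x$shannon_beta_nats, x$hill_normalized, nrow(x$pairwise),
    mean(x$pairwise$morisita_horn)))
  invisible(x)
}

#' Turnover statistics for a whole cohort
#'
#' Applies [pairwise_turnover()] to every series and returns tidy tables.
#'
#' @param series list of [subject_series()] (see [build_subject_series()]).
#'   Series with a single sample are reported with `NA` turnover values
#'   (turnover is undefined, not zero) and contribute no pairs.
#' @return list of two data frames: `subjects` (one row per subject:
#'   `subject_id`, `group`, `n_samples`, `shannon_beta_nats`, `hill`,
#'   `hill_normalized`) and `pairs` (long format, one row per within-subject
#'   sample pair with `morisita_horn` and `interval_days`).
#' @export
turnover_tables <- function(series) {
  rows <- lapply(series, function(s) {
    if (nrow(s$counts) < 2) {
      return(list(subj = data.frame(subject_id = s$subject_id,
                                    group = as.character(s$group),
                                    n_samples = nrow(s$counts),
                                    shannon_beta_nats = NA_real_,
                                    hill = NA_real_,
                                    hill_normalized = NA_real_),
                  pairs = NULL))
    }
    tr <- pairwise_turnover(s)
    list(subj = data.frame(subject_id = tr$subject_id,
                           group = as.character(tr$group),
                           n_samples = tr$n_samples,
                           shannon_beta_nats = tr$shannon_beta_nats,
                           hill = tr$hill,
                           hill_normalized = tr$hill_normalized),
         pairs = cbind(subject_id = tr$subject_id,
                       group = as.character(tr$group), tr$pairwise))
  })
  list(subjects = do.call(rbind, c(lapply(rows, `[[`, "subj"),
                                   make.row.names = FALSE)),
       pairs = do.call(rbind, c(Filter(Negate(is.null),
                                       lapply(rows, `[[`, "pairs")),
                                make.row.names = FALSE)))
}
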