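#' Shannon alpha diversity of one sample
#'
#' `H = -sum(p_k log_base p_k)` over taxa with positive counts. The default
#' base is 2 (the convention of the diversity software used for amplicon
#' panels); base `exp(1)` gives nats. The index is invariant to taxon order
#' and to rescaling all counts by a constant.
#'
#' @param counts non-negative count (or abundance) vector with positive sum.
#' @param base logarithm base (default 2).
#' @return Shannon index, `>= 0`; 0 iff exactly one taxon is present.
#' @export
shannon_alpha <- function(counts, base = 2) {
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) stop("all-zero count vector: Shannon diversity undefined")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Pielou evenness of one sample
#'
#' Shannon diversity divided by its maximum `log_base(S)` for the observed
#' richness `S`. Evenness is small when the community is dominated by a few
#' organisms and 1 for a perfectly uniform community. With fewer than two
#' observed taxa the ratio is undefined and `NA` is returned (never 0: a
#' monoculture has no evenness, not zero evenness).
#'
#' @inheritParams shannon_alpha
#' @return evenness in `[0, 1]`, or `NA_real_` when fewer than 2 taxa are
#'   observed.
#' @export
evenness <- function(counts, base = 2) {
  s_obs <- sum(counts > 0)
  if (s_obs < 2) return(NA_real_)
  shannon_alpha(counts, base = base) / log(s_obs, base = base)
}

## exact multivariate hypergeometric subsample (sequential conditionals)
subsample_without_replacement <- function(counts, depth) {
  k <- length(counts)
  out <- integer(k)
  remaining <- sum(counts)
  need <- depth
  for (i in seq_len(k)) {
    if (need == 0L) break
    remaining <- remaining - counts[i]
    out[i] <- stats::rhyper(1, counts[i], remaining, need)
    need <- need - out[i]
  }
  out
}

#' Rarefied Good's coverage
#'
#' Good's coverage, `1 - singletons/depth`, estimated on subsamples drawn
#' without replacement (multivariate hypergeometric) at a fixed rarefaction
#' depth; the median over `n_draws` subsamples is returned. Samples shallower
#' than `depth` are not rarefiable: they yield `NA` and should be excluded,
#' never imputed.
#'
#' @inheritParams shannon_alpha
#' @param depth rarefaction depth (total counts drawn per subsample).
#' @param n_draws number of subsamples (default 100).
#' @param seed optional integer seed applied locally (the caller's RNG state
#'   is restored on exit).
#' @return median coverage in `[0, 1]`, or `NA_real_` if `sum(counts) <
#'   depth`.
#' @export
goods_coverage_rarefied <- function(counts, depth, n_draws = 100, seed = NULL) {
  counts <- as.integer(counts)
  if (sum(counts) < depth) return(NA_real_)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  cov <- vapply(seq_len(n_draws), function(i) {
    sub <- subsample_without_replacement(counts, depth)
    1 - sum(sub == 1L) / depth
  }, 0)
  stats::median(cov)
}

#' Per-sample alpha diversity table
#'
#' Batch computation of Shannon diversity, evenness and (optionally) rarefied
#' Good's coverage for every sample of a count table.
#'
#' @param x a [taxon_count_table()].
#' @param base logarithm base for Shannon/evenness.
#' @param rarefy_depth rarefaction depth for Good's coverage; `NULL` skips
#'   coverage. Samples shallower than the depth get `NA` coverage.
#' @param n_draws,seed passed to [goods_coverage_rarefied()].
#' @return data frame with one row per sample: `sample_id`, `depth`,
#'   `shannon`, `evenness`, `goods_coverage`, `rarefaction_depth`.
#' @export
alpha_diversity <- function(x, base = 2, rarefy_depth = NULL, n_draws = 100,
                            seed = NULL) {
  stopifnot(is_taxon_count_table(x))
  m <- x$counts
  res <- data.frame(
    sample_id = rownames(m),
    depth = rowSums(m),
    shannon = apply(m, 1, shannon_alpha, base = base),
    evenness = apply(m, 1, evenness, base = base),
    row.names = NULL
  )
  if (!is.null(rarefy_depth)) {
    seeds <- if (is.null(seed)) rep(list(NULL), nrow(m))
             else as.list(seed + seq_len(nrow(m)))
    res$goods_coverage <- vapply(seq_len(nrow(m)), function(i)
      goods_coverage_rarefied(m[i, ], rarefy_depth, n_draws, seeds[[i]]), 0)
    res$rarefaction_depth <- rarefy_depth
  }
  res
}
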