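test_that("Shannon beta Hill number hits its analytic bounds", {
  ## four equal-depth samples with disjoint single-taxon support
  disjoint <- diag(4) * 1000
  hb <- shannon_beta_hill(disjoint)
  expect_equal(hb$shannon_beta_nats, log(4), tolerance = 1e-12)
  expect_equal(hb$hill, 4, tolerance = 1e-12)
  ## compositionally identical samples collapse to one community
  same <- rbind(c(500, 300, 200), c(500, 300, 200), c(500, 300, 200))
  expect_equal(shannon_beta_hill(same)$hill, 1, tolerance = 1e-12)
  ## proportional but different depth is still identical composition
  prop <- rbind(c(50, 30, 20), c(500, 300, 200))
  expect_equal(shannon_beta_hill(prop)$hill, 1, tolerance = 1e-12)
})

test_that("worked two-sample decomposition matches the gamma-minus-alpha oracle", {
  m <- rbind(c(10, 0), c(5, 5))
  hb <- shannon_beta_hill(m)
  ## oracle: pooled (gamma) Shannon minus depth-weighted mean within-sample
  ## (alpha) Shannon, in nats
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  gamma_h <- h(colSums(m) / sum(m))
  alpha_h <- sum(rowSums(m) / sum(m) * apply(m, 1, function(r) h(r / sum(r))))
  expect_equal(hb$shannon_beta_nats, gamma_h - alpha_h, tolerance = 1e-12)
  expect_equal(hb$shannon_beta_nats, 0.5 * log(4 / 3) +
                 0.5 * (0.5 * log(2 / 3) + 0.5 * log(2)),
               tolerance = 1e-12)
  expect_equal(hb$hill, exp(0.21576155433883565), tolerance = 1e-10)
  expect_equal(normalize_hill(hb$hill, 2), hb$hill - 1, tolerance = 1e-12)
})

test_that("Shannon beta equals mutual information on random fixtures", {
  for (seed in 1:60) {
    set.seed(seed)
    j <- sample(2:5, 1); k <- sample(2:12, 1)
    m <- matrix(rpois(j * k, runif(j * k, 0, 25)), j, k)
    m[, 1] <- m[, 1] + 1L
    hb <- shannon_beta_hill(m)
    expect_equal(hb$shannon_beta_nats, mutual_information_oracle(m),
                 tolerance = 1e-10)
    ## bounds: 1 <= hill <= min(j, observed taxa)
    expect_gte(hb$hill, 1)
    expect_lte(hb$hill, min(j, sum(colSums(m) > 0)) + 1e-12)
    ## taxon order is irrelevant
    expect_equal(shannon_beta_hill(m[, sample(ncol(m))])$shannon_beta_nats,
                 hb$shannon_beta_nats, tolerance = 1e-12)
  }
})

test_that("normalize_hill maps the analytic bounds to 0 and 1", {
  expect_equal(normalize_hill(4, 4), 1)
  expect_equal(normalize_hill(1, 2), 0)
  expect_equal(normalize_hill(1, 4), 0)
  expect_error(normalize_hill(1.5, 1), "fewer than 2")
})

test_that("Morisita-Horn has its defining properties", {
  expect_equal(morisita_horn(c(10, 0), c(5, 5)), 2 / 3, tolerance = 1e-12)
  expect_equal(morisita_horn(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(morisita_horn(c(5, 0, 0), c(0, 3, 9)), 0)
  expect_error(morisita_horn(c(1, 2), c(1, 2, 3)), "length")
  for (seed in 1:40) {
    set.seed(seed)
    k <- sample(3:15, 1)
    x <- rpois(k, 8); x[1] <- x[1] + 1
    y <- rpois(k, 8); y[1] <- y[1] + 1
    mh <- morisita_horn(x, y)
    expect_gte(mh, 0); expect_lte(mh, 1 + 1e-12)
    expect_equal(mh, morisita_horn(y, x), tolerance = 1e-12)      # symmetry
    expect_equal(mh, morisita_horn(13 * x, y), tolerance = 1e-12) # depth inv.
    expect_equal(mh, morisita_horn(x, 5 * y), tolerance = 1e-12)
    expect_equal(morisita_horn(x, 3 * x), 1, tolerance = 1e-12)   # 1 iff prop.
    ## cross-check against the vegan Horn-Morisita dissimilarity
    expect_equal(mh, 1 - as.numeric(vegan::vegdist(rbind(x, y),
                                                   method = "horn")),
                 tolerance = 1e-10)
  }
})

test_that("pairwise turnover enumerates all within-subject pairs", {
  s <- subject_series("A", days = c(7, 14, 21),
                      counts = rbind(c(9, 1), c(5, 5), c(2, 8)))
  tr <- pairwise_turnover(s)
  expect_equal(nrow(tr$pairwise), 3)
  expect_setequal(tr$pairwise$interval_days, c(7, 7, 14))
  expect_equal(tr$n_samples, 3)
  expect_equal(tr$hill_normalized, (tr$hill - 1) / 2, tolerance = 1e-12)

  same <- subject_series("B", days = c(3, 10),
                         counts = rbind(c(40, 60), c(40, 60)))
  tr2 <- pairwise_turnover(same)
  expect_equal(tr2$pairwise$morisita_horn, 1)
  expect_equal(tr2$hill_normalized, 0, tolerance = 1e-12)

  single <- subject_series("C", days = 7, counts = rbind(c(1, 2)))
  expect_error(pairwise_turnover(single))
})

test_that("turnover tables cover every eligible subject", {
  coh <- generate_cohort(small_cohort_config(seed = 17))
  ser <- build_subject_series(coh$table, coh$metadata)
  to <- turnover_tables(ser)
  expect_equal(nrow(to$subjects), length(ser))
  expect_equal(nrow(to$pairs),
               sum(vapply(ser, function(s) choose(length(s$days), 2), 0)))
  expect_true(all(to$subjects$hill_normalized >= 0 &
                    to$subjects$hill_normalized <= 1, na.rm = TRUE))
  expect_true(all(to$pairs$morisita_horn >= 0 & to$pairs$morisita_horn <= 1))
})
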