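test_that("beta-binomial pmf is a proper distribution with the right limits", {
  for (mu in c(0.05, 0.3, 0.7)) for (phi in c(0.01, 0.1, 0.5)) {
    for (n in c(1, 7, 40)) {
      expect_equal(sum(dbetabinom(0:n, n, mu, phi)), 1, tolerance = 1e-10)
    }
  }
  ## phi -> 0 limit is the binomial
  expect_equal(dbetabinom(0:20, 20, 0.3, 0), dbinom(0:20, 20, 0.3),
               tolerance = 1e-12)
  expect_equal(dbetabinom(0:30, 30, 0.4, 1e-7), dbinom(0:30, 30, 0.4),
               tolerance = 1e-4)
  ## out-of-support mass is zero
  expect_equal(dbetabinom(c(-1, 31, 2.5), 30, 0.4, 0.1), c(0, 0, 0))
})

test_that("Gauss-Hermite rule integrates known moments exactly", {
  gh <- airwayturnover:::gauss_hermite(21)
  expect_equal(sum(gh$weights), sqrt(pi), tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^2), sqrt(pi) / 2, tolerance = 1e-10)
  expect_equal(sum(gh$weights * gh$nodes^4), 3 * sqrt(pi) / 4,
               tolerance = 1e-9)
})

test_that("quadrature matches dense brute-force integration", {
  set.seed(300)
  for (rep in 1:5) {
    S <- 3
    nobs <- sample(2:4, S, replace = TRUE)
    subj <- rep(seq_len(S), nobs)
    m <- length(subj)
    n <- sample(50:500, m, replace = TRUE)
    eta <- rnorm(m, -1, 1)
    sigma <- runif(1, 0.3, 1.5)
    phi <- runif(1, 0.02, 0.3)
    b <- rnorm(S, 0, sigma)
    y <- rbetabinom(m, n, plogis(eta + b[subj]), phi)
    li <- betabin_marginal_loglik(y, n, eta, phi, subj, sigma)
    bg <- seq(-8 * sigma, 8 * sigma, length.out = 4001)
    for (i in seq_len(S)) {
      ll <- vapply(bg, function(bb)
        sum(dbetabinom(y[subj == i], n[subj == i],
                       plogis(eta[subj == i] + bb), phi, log = TRUE)) +
          dnorm(bb, 0, sigma, log = TRUE), 0)
      mx <- max(ll)
      l_trap <- mx + log(sum(exp(ll - mx)) * (bg[2] - bg[1]))
      expect_equal(exp(li[i]), exp(l_trap), tolerance = 1e-6)
    }
  }
})

test_that("knot selection solves the cubic derivative", {
  ## noiseless: empirical logit lies exactly on a cubic with stationary
  ## points at t = 10 and t = 30 (only 10 in range)
  cubic <- function(t) -1 + 0.01 * (t^3 / 3 - 20 * t^2 + 300 * t)
  days <- c(2, 5, 8, 11, 14, 17, 20, 23)
  n_d <- rep(1000, length(days))
  y_d <- plogis(cubic(days)) * (n_d + 1) - 0.5   # inverts the empirical logit
  k <- select_knot(days, y_d, n_d)
  expect_equal(as.numeric(k), 10, tolerance = 1e-6)
  expect_length(attr(k, "roots"), 2)
  expect_length(attr(k, "in_range"), 1)

  ## two in-range roots: tie-break to the root nearer the median day
  cubic2 <- function(t) 0.002 * (t^3 / 3 - 14 * t^2 + 160 * t)  # roots 8, 20
  days2 <- seq(2, 23, by = 3)
  n_d2 <- rep(500, length(days2))
  y_d2 <- plogis(cubic2(days2)) * (n_d2 + 1) - 0.5
  k2 <- select_knot(days2, y_d2, n_d2)
  expect_length(attr(k2, "in_range"), 2)
  expect_equal(as.numeric(k2), 8, tolerance = 1e-5)

  ## monotone trend: no stationary point, fall back with a warning
  days3 <- c(2, 6, 10, 14, 18)
  y_d3 <- plogis(-3 + 0.2 * days3) * 501 - 0.5
  expect_warning(k3 <- select_knot(days3, y_d3, rep(500, 5)), "default knot")
  expect_equal(as.numeric(k3), 10)
  expect_error(select_knot(c(1, 2, 3), c(1, 1, 1), c(9, 9, 9)),
               "4 distinct day")
})

test_that("knot recovery from simulated cohorts lands near the true day-10 kink", {
  cfg <- cohort_config(
    n_subjects = c(mild = 34, moderate = 33, severe = 33),
    staph_trajectory = list(mild = c(-2.5, 0.3, -0.6),
                            moderate = c(-2.5, 0.3, -0.6),
                            severe = c(-2.5, 0.3, -0.6)),
    seed = 1)
  ks <- vapply(1:3, function(s) {
    cfg$seed <- s
    coh <- generate_cohort(cfg)
    ser <- build_subject_series(coh$table, coh$metadata)
    long <- airwayturnover:::assemble_joinpoint_data(ser, "Staphylococcus")
    as.numeric(select_knot(long$day, long$y, long$n))
  }, 0)
  expect_true(all(abs(ks - 10) <= 2))
})

test_that("with no overdispersion and no random effect the fit matches a plain logistic join-point", {
  set.seed(41)
  S <- 120
  grp <- rep(c("a", "b"), each = S / 2)
  truth <- list(a = c(-2, 0.25, -0.45), b = c(-1.2, 0.05, -0.1))
  df <- do.call(rbind, lapply(seq_len(S), function(i) {
    days <- c(3, 7, 14, 21)
    n <- sample(500:3000, 4, replace = TRUE)
    eta <- truth[[grp[i]]][1] + truth[[grp[i]]][2] * days +
      truth[[grp[i]]][3] * pmax(days - 10, 0)
    data.frame(subject = sprintf("s%03d", i), group = grp[i], day = days,
               y = rbinom(4, n, plogis(eta)), n = n)
  }))
  ser <- lapply(split(df, df$subject), function(d)
    subject_series(d$subject[1], d$day,
                   counts = cbind(tx = d$y, other = d$n - d$y),
                   group = d$group[1]))
  fit <- fit_betabin_joinpoint(ser, "tx", knot = 10)
  glmfit <- glm(cbind(y, n - y) ~ 0 + group + group:day + group:tk,
                family = binomial(),
                data = transform(df, tk = pmax(day - 10, 0)))
  expect_equal(unname(fit$coefficients$estimate),
               unname(coef(glmfit)[c(1, 2, 3, 4, 5, 6)]), tolerance = 0.02)
  expect_lt(fit$sigma_b, 0.08)        # shrinks to the boundary
  expect_true(all(fit$phi < 0.01))
})

test_that("the join-point fit agrees with an independent TMB implementation", {
  coh <- generate_cohort(cohort_config(seed = 7))
  ser <- build_subject_series(coh$table, coh$metadata)
  fit <- fit_betabin_joinpoint(ser, "Staphylococcus")
  df <- airwayturnover:::assemble_joinpoint_data(ser, "Staphylococcus")
  df$tk <- pmax(df$day - 10, 0)
  tmb <- glmmTMB::glmmTMB(
    cbind(y, n - y) ~ 0 + group + group:day + group:tk + (1 | subject_id),
    dispformula = ~ 0 + group, family = glmmTMB::betabinomial(),
    data = df)
  fe <- glmmTMB::fixef(tmb)$cond
  ## same parameter meaning: intercepts then day slopes then knot changes
  expect_equal(unname(fit$coefficients$estimate), unname(fe),
               tolerance = 0.02)
  expect_equal(fit$sigma_b,
               sqrt(glmmTMB::VarCorr(tmb)$cond$subject_id[1, 1]),
               tolerance = 0.05)
  ## glmmTMB betabinomial dispersion: shape1+shape2 = exp(disp) = 1/phi
  expect_equal(unname(fit$phi),
               unname(1 / exp(glmmTMB::fixef(tmb)$disp)), tolerance = 0.1)
})

test_that("day-14 contrast detects a generated group difference", {
  ## defaults generate a higher mild Staphylococcus curve at day 14
  coh <- generate_cohort(cohort_config(seed = 19))
  ser <- build_subject_series(coh$table, coh$metadata)
  fit <- fit_betabin_joinpoint(ser, "Staphylococcus", contrast_days = 14)
  cs <- fit$contrasts
  ms <- cs[cs$group_a == "mild" & cs$group_b == "severe", ]
  expect_gt(ms$ra_diff_pct, 0)
  expect_lt(ms$ra_p, 0.05)
  expect_gt(ms$logit_diff, 0)
  ## fitted population curves stay inside (0, 100) percent
  expect_true(all(fit$curves$mean_ra_pct > 0 & fit$curves$mean_ra_pct < 100))
})

test_that("GEE reduces to OLS for singleton clusters and matches sandwich", {
  set.seed(55)
  n <- 90
  g <- rep(c("mild", "moderate", "severe"), each = n / 3)
  y <- exp(rnorm(n, ifelse(g == "mild", 1, 0.5), 0.4))
  fitg <- fit_gee_lognormal(y, subject_ids = paste0("s", 1:n), groups = g)
  ols <- lm(log(y) ~ 0 + g)
  expect_equal(unname(fitg$coefficients), unname(coef(ols)),
               tolerance = 1e-10)
  expect_match(fitg$note, "singleton")
  vc <- sandwich::vcovCL(ols, cluster = paste0("s", 1:n), type = "HC0",
                         cadjust = FALSE)
  expect_equal(unname(fitg$vcov_robust), unname(vc), tolerance = 1e-8)
})

test_that("GEE estimates are invariant to cluster ordering", {
  set.seed(66)
  sizes <- sample(1:4, 30, replace = TRUE)
  subj <- rep(sprintf("p%02d", 1:30), times = sizes)
  g <- rep(rep(c("a", "b", "c"), length.out = 30), times = sizes)
  re <- rep(rnorm(30, 0, 0.3), times = sizes)
  y <- exp(0.2 * (g == "a") + re + rnorm(length(subj), 0, 0.4))
  f1 <- fit_gee_lognormal(y, subj, g)
  o <- sample(length(y))
  f2 <- fit_gee_lognormal(y[o], subj[o], g[o])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$rho, f2$rho, tolerance = 1e-8)
  expect_error(fit_gee_lognormal(c(1, -2, 3), c("a", "b", "c"),
                                 c("x", "y", "x")),
               "non-positive")
})

test_that("GEE recovers a generated bacterial-load time trend", {
  coh <- generate_cohort(cohort_config(seed = 23))
  md <- coh$metadata
  fit <- fit_gee_lognormal(md$bacterial_load_log10, md$subject_id, md$group,
                           time = md$collection_day / 7,
                           values_are_log = TRUE)
  sl <- fit$time_slope
  ## truth: +1.05 log10 copies/reaction per week
  expect_lt(abs(sl$estimate - 1.05), 3 * sl$se)
  expect_lt(sl$p, 0.01)
})

test_that("zero-inflation check is calm on self-consistent data and flags structural zeros", {
  coh <- generate_cohort(cohort_config(seed = 29))
  ser <- build_subject_series(coh$table, coh$metadata)
  fit <- fit_betabin_joinpoint(ser, "Ureaplasma")
  chk <- zero_inflation_check(fit)
  filled <- chk[chk$flag != "empty", ]
  ## data generated from (essentially) the fitted model: few if any flags
  expect_lte(mean(filled$flag != "ok"), 0.25)

  ## inject structural zeros: wipe the taxon from late samples of the group
  ## where it is most abundant, and check the clean-data fit against the
  ## perturbed series (a refit could absorb the zeros into the trend)
  ser2 <- ser
  for (nm in names(ser2)) {
    s <- ser2[[nm]]
    if (identical(s$group, "severe")) {
      late <- s$days > 10
      s$counts[late, "Ureaplasma"] <- 0L
      ser2[[nm]] <- s
    }
  }
  chk2 <- zero_inflation_check(fit, series = ser2)
  hit <- chk2[chk2$group == "severe" & chk2$flag != "empty" &
                chk2$day_bin %in% c("(10,16]", "(16,24]"), ]
  expect_true(all(hit$flag == "excess"))
  ## unperturbed groups unaffected
  expect_true(mean(chk2$flag[chk2$group == "mild" &
                               chk2$flag != "empty"] == "ok") >= 0.5)
})
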