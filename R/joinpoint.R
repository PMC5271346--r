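#' Data-driven knot placement for the join-point model
#'
#' Fits a cubic polynomial in collection day to the logit of the pooled
#' per-day relative abundance (weighted by per-day total depth), sets its
#' first derivative to zero, and solves the resulting quadratic. The real
#' root inside the observed day range is returned as the knot; when two
#' in-range roots exist the one nearer the (depth-weighted) median day is
#' chosen and both are reported in the `"roots"` attribute. When no real
#' root falls in range the default knot is returned with a warning.
#'
#' Pooling is across groups by default; per-group knots can be obtained by
#' calling the function on each group's data.
#'
#' @param days collection day of each sample.
#' @param target_counts counts of the modeled taxon per sample.
#' @param totals per-sample total depths.
#' @param default_knot fallback knot day (default 10).
#' @return the knot day (numeric scalar) with attributes `roots` (all real
#'   roots of the derivative) and `in_range` (those inside the day range).
#' @export
select_knot <- function(days, target_counts, totals, default_knot = 10) {
  stopifnot(length(days) == length(target_counts),
            length(days) == length(totals))
  y_d <- rowsum(as.numeric(target_counts), days)
  n_d <- rowsum(as.numeric(totals), days)
  d <- as.numeric(rownames(y_d))
  if (length(d) < 4)
    stop("knot selection needs at least 4 distinct day values")
  lp <- stats::qlogis((y_d + 0.5) / (n_d + 1))  # empirical logit
  fit <- stats::lm(lp ~ d + I(d^2) + I(d^3), weights = as.numeric(n_d))
  a <- stats::coef(fit)  # intercept, a1, a2, a3
  # derivative: a1 + 2 a2 t + 3 a3 t^2 = 0
  roots <- if (abs(a[4]) < 1e-12) {
    if (abs(a[3]) < 1e-12) numeric(0) else -a[2] / (2 * a[3])
  } else {
    disc <- (2 * a[3])^2 - 4 * (3 * a[4]) * a[2]
    if (disc < 0) numeric(0)
    else (-2 * a[3] + c(-1, 1) * sqrt(disc)) / (2 * 3 * a[4])
  }
  roots <- unname(roots)
  rng <- range(days)
  in_range <- roots[roots >= rng[1] & roots <= rng[2]]
  if (!length(in_range)) {
    warning("no stationary point of the cubic trend inside the day range; ",
            "falling back to the default knot at day ", default_knot)
    knot <- default_knot
  } else if (length(in_range) == 1) {
    knot <- in_range
  } else {
    cw <- cumsum(n_d[order(d)]) / sum(n_d)
    med_day <- sort(d)[which(cw >= 0.5)[1]]
    knot <- in_range[which.min(abs(in_range - med_day))]
  }
  structure(knot, roots = roots, in_range = in_range)
}

## Adaptive Gauss-Hermite marginal log-likelihood, one value per subject.
## Finds the per-subject posterior mode of the random intercept b by damped
## Newton iterations (analytic first/second derivatives of the beta-binomial
## log density w.r.t. the logit mean), then integrates with the quadrature
## rule recentred and rescaled at the mode.
##
## Requires observations sorted by subject (subj non-decreasing, values
## 1..S); subject sums then reduce to a cumsum trick, and the terms of the
## beta-binomial log density that are constant across quadrature nodes
## (lchoose(n, y), lgamma(n + 1/phi), lgamma(1/phi)) are computed once.
agq_loglik <- function(y, n, eta_fix, phi_obs, subj, S, sigma, gh,
                       bstart = NULL) {
  ends <- cumsum(tabulate(subj, nbins = S))
  ssum <- function(x) {
    cs <- cumsum(x)[ends]
    c(cs[1], diff(cs))
  }
  lch <- lchoose(n, y)
  inv_phi <- 1 / phi_obs
  ll_const <- lch - lgamma(n + inv_phi) + lgamma(inv_phi)
  bb_ll <- function(eta) {
    mu <- stats::plogis(eta)
    a <- mu * inv_phi
    bb <- (1 - mu) * inv_phi
    ll_const + lgamma(y + a) + lgamma(n - y + bb) - lgamma(a) - lgamma(bb)
  }
  b <- if (is.null(bstart)) numeric(S) else bstart
  hs <- rep(-1 / sigma^2, S)
  for (it in seq_len(60)) {
    d <- bb_deriv_eta(y, n, eta_fix + b[subj], phi_obs)
    gs <- ssum(d$g) - b / sigma^2
    hs <- ssum(d$h) - 1 / sigma^2
    hs <- pmin(hs, -1e-8)
    step <- pmin(pmax(gs / hs, -2), 2)
    b <- b - step
    if (max(abs(gs)) < 1e-8) break
  }
  tau <- 1 / sqrt(-hs)
  nq <- length(gh$nodes)
  ## all nodes in one vectorized evaluation
  bq <- b + sqrt(2) * outer(tau, gh$nodes)          # S x nq
  ll_big <- bb_ll(eta_fix + bq[subj, ])             # column-recycled sum
  m <- length(y)
  lw <- matrix(0, S, nq)
  lnorm <- -0.5 * (bq / sigma)^2 - log(sigma) - 0.5 * log(2 * pi)
  for (q in seq_len(nq)) {
    lw[, q] <- log(gh$weights[q]) + gh$nodes[q]^2 +
      ssum(ll_big[(q - 1L) * m + seq_len(m)]) + lnorm[, q]
  }
  mx <- lw[, 1]
  for (q in 2:nq) mx <- pmax(mx, lw[, q])
  rs <- rowSums(exp(lw - mx))
  li <- mx + log(rs) + 0.5 * log(2) + log(tau)
  ## posterior node weights (normalized), needed for score computations
  wpost <- exp(lw - mx) / rs
  list(loglik = li, bhat = b, tau = tau, bq = bq, wpost = wpost)
}

#' Per-subject marginal log-likelihood of the beta-binomial random-intercept
#' model
#'
#' Evaluates, by adaptive Gauss-Hermite quadrature, the marginal likelihood
#' of each subject's observations under `y | b ~ BetaBinomial(n, plogis(eta +
#' b), phi)` with `b ~ Normal(0, sigma^2)` integrated out. Exposed mainly for
#' diagnostics and for verifying the quadrature against brute-force
#' integration.
#'
#' @param y,n observed successes and trials per observation.
#' @param eta fixed-effect linear predictor per observation (logit scale).
#' @param phi dispersion per observation.
#' @param subject subject index per observation (integer `1..S` or factor).
#' @param sigma random-intercept standard deviation.
#' @param nodes number of quadrature nodes (default 21).
#' @return numeric vector of per-subject log marginal likelihoods.
#' @export
betabin_marginal_loglik <- function(y, n, eta, phi, subject, sigma,
                                    nodes = 21) {
  subj <- as.integer(factor(subject))
  S <- max(subj)
  o <- order(subj)
  phi <- rep_len(phi, length(y))
  agq_loglik(y[o], n[o], eta[o], phi[o], subj[o], S, sigma,
             gauss_hermite(nodes))$loglik
}

assemble_joinpoint_data <- function(series, taxon) {
  rows <- lapply(series, function(s) {
    if (!taxon %in% colnames(s$counts))
      stop("taxon '", taxon, "' not found in the taxon index")
    data.frame(subject_id = s$subject_id, group = as.character(s$group),
               day = s$days, y = s$counts[, taxon],
               n = rowSums(s$counts), row.names = NULL)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Beta-binomial join-point mixed model of taxon relative abundance over age
#'
#' Fits, by maximum marginal likelihood, the model
#' \deqn{y_{ij} \mid b_i \sim \mathrm{BetaBin}(n_{ij},\, \mu_{ij},\, \phi_g),
#' \quad \mathrm{logit}(\mu_{ij}) = \beta_{0g} + \beta_{1g} t_{ij} +
#' \beta_{2g}(t_{ij}-\kappa)_+ + b_i, \quad b_i \sim N(0, \sigma_b^2)}
#' where `y` is the taxon's count, `n` the sample depth, `t` the collection
#' day, `g` the subject's outcome group, and `kappa` the knot (default day
#' 10; see [select_knot()]). Each group has its own intercept, pre-knot
#' slope, slope *change* at the knot, and dispersion `phi_g`; the piecewise
#' trend is continuous at the knot by construction of the truncated-line
#' basis. The subject random intercept is integrated out by adaptive
#' Gauss-Hermite quadrature (default 21 nodes). Standard errors come from
#' the observed information at the optimum; contrasts between groups in mean
#' relative abundance at requested days are reported on the logit scale
#' (exact linear combination) and on the RA scale (delta method on the
#' marginal mean) with Wald p-values.
#'
#' The optimizer starts from a binomial GLM fit; if it fails to converge, up
#' to `restarts` jittered restarts are attempted and the best objective kept.
#'
#' @param series list of [subject_series()].
#' @param taxon name of the modeled taxon (column of the shared taxon index).
#' @param knot knot day `kappa`.
#' @param contrast_days days at which pairwise group contrasts of the mean RA
#'   are evaluated (default 14).
#' @param covariates optional observation-level model matrix of extra fixed
#'   effects (e.g. ventilation days, corticosteroids), rows matching the
#'   assembled observations in series order.
#' @param nodes number of Gauss-Hermite quadrature nodes (default 21, which keeps the marginal likelihood within about 1e-7 relative error of exact integration for random-intercept SDs up to 1.5).
#' @param restarts maximum jittered restarts on non-convergence.
#' @return object of class `betabin_joinpoint`; see Details. Key elements:
#'   `coefficients` (tidy table: term, group, estimate, se, p), `sigma_b`,
#'   `phi` (per group), `loglik`, `contrasts`, `curves` (marginal mean RA%
#'   per group on a day grid), `vcov`, `convergence`.
#' @export
fit_betabin_joinpoint <- function(series, taxon, knot = 10,
                                  contrast_days = 14, covariates = NULL,
                                  nodes = 21, restarts = 3) {
  df <- assemble_joinpoint_data(series, taxon)
  df$group <- factor(df$group)
  G <- nlevels(df$group)
  if (G < 2) stop("at least 2 groups are required")
  subj <- as.integer(factor(df$subject_id))
  ord <- order(subj)          # agq_loglik needs observations sorted by subject
  df <- df[ord, ]
  subj <- subj[ord]
  g <- as.integer(df$group)
  S <- max(subj)
  t_ <- df$day
  tk <- pmax(t_ - knot, 0)
  Z <- if (!is.null(covariates)) as.matrix(covariates)[ord, , drop = FALSE]
       else NULL
  n_gamma <- if (is.null(Z)) 0L else ncol(Z)
  gh <- gauss_hermite(nodes)

  allzero <- tapply(df$y, df$group, function(v) all(v == 0))
  if (any(allzero))
    warning("group(s) with all-zero counts (boundary fit, dispersion pinned): ",
            paste(names(allzero)[allzero], collapse = ", "))

  idx <- list(b0 = 1:G, b1 = G + 1:G, b2 = 2 * G + 1:G,
              gamma = if (n_gamma) 3 * G + seq_len(n_gamma) else integer(0),
              lsig = 3 * G + n_gamma + 1L,
              lphi = 3 * G + n_gamma + 1L + 1:G)
  npar <- 4 * G + n_gamma + 1L

  eta_fun <- function(theta) {
    eta <- theta[idx$b0][g] + theta[idx$b1][g] * t_ + theta[idx$b2][g] * tk
    if (n_gamma) eta <- eta + drop(Z %*% theta[idx$gamma])
    eta
  }

  ends <- cumsum(tabulate(subj, nbins = S))
  ssum <- function(x) { cs <- cumsum(x)[ends]; c(cs[1], diff(cs)) }
  subj_group <- g[ends]                 # each subject belongs to one group
  m <- length(df$y)
  bcache <- numeric(S)
  cache <- new.env(parent = emptyenv())

  ## objective and analytic gradient sharing one AGQ pass. The gradient uses
  ## the Fisher identity d log L_i/d theta = E[ d log f(y_i, b)/d theta | y_i ]
  ## with the posterior expectation taken over the quadrature nodes (node
  ## positions treated as fixed, exact up to the quadrature error).
  agq_all <- function(theta, want_grad = FALSE) {
    if (!is.null(cache$theta) && identical(theta, cache$theta) &&
        (!want_grad || !is.null(cache$grad)))
      return(list(value = cache$value, grad = cache$grad))
    sigma <- exp(theta[idx$lsig])
    phi_obs <- exp(theta[idx$lphi])[g]
    res <- agq_loglik(df$y, df$n, eta_fun(theta), phi_obs, subj, S, sigma,
                      gh, bstart = bcache)
    bcache <<- res$bhat
    value <- -sum(res$loglik)
    if (!is.finite(value)) value <- 1e10
    grad <- if (want_grad) numeric(npar) else NULL
    if (want_grad && value < 1e10) {
      nq <- length(gh$nodes)
      c_obs <- 1 / phi_obs
      psi_nc <- digamma(df$n + c_obs)
      psi_c <- digamma(c_obs)
      eta_big <- eta_fun(theta) + res$bq[subj, ]
      mu <- stats::plogis(eta_big)
      a <- mu * c_obs
      bb <- (1 - mu) * c_obs
      dy <- digamma(df$y + a); dnb <- digamma(df$n - df$y + bb)
      da <- digamma(a); dbb <- digamma(bb)
      g_eta <- (dy - dnb - da + dbb) * c_obs * mu * (1 - mu)
      g_lphi <- -c_obs * (mu * dy + (1 - mu) * dnb - psi_nc -
                            mu * da - (1 - mu) * dbb + psi_c)
      acc <- matrix(0, S, 4 + n_gamma)  # b0, b1, b2, lphi, gammas
      acc_sig <- numeric(S)
      for (q in seq_len(nq)) {
        iq <- (q - 1L) * m + seq_len(m)
        w_q <- res$wpost[, q]
        ge <- g_eta[iq]
        acc[, 1] <- acc[, 1] + w_q * ssum(ge)
        acc[, 2] <- acc[, 2] + w_q * ssum(ge * t_)
        acc[, 3] <- acc[, 3] + w_q * ssum(ge * tk)
        acc[, 4] <- acc[, 4] + w_q * ssum(g_lphi[iq])
        if (n_gamma) for (cc in seq_len(n_gamma))
          acc[, 4 + cc] <- acc[, 4 + cc] + w_q * ssum(ge * Z[, cc])
        acc_sig <- acc_sig + w_q * (res$bq[, q]^2 / sigma^2 - 1)
      }
      grad <- numeric(npar)
      grad[idx$b0] <- rowsum(acc[, 1], subj_group)
      grad[idx$b1] <- rowsum(acc[, 2], subj_group)
      grad[idx$b2] <- rowsum(acc[, 3], subj_group)
      grad[idx$lphi] <- rowsum(acc[, 4], subj_group)
      if (n_gamma) grad[idx$gamma] <- colSums(acc[, 4 + seq_len(n_gamma),
                                                  drop = FALSE])
      grad[idx$lsig] <- sum(acc_sig)
      grad <- -grad
    }
    cache$theta <- theta; cache$value <- value; cache$grad <- grad
    list(value = value, grad = grad)
  }
  nll <- function(theta) agq_all(theta)$value
  nll_gr <- function(theta) agq_all(theta, want_grad = TRUE)$grad

  ## data-driven start: binomial GLM for the fixed effects
  start <- numeric(npar)
  glm_fit <- suppressWarnings(stats::glm(
    cbind(y, n - y) ~ 0 + group + group:day + group:tk_,
    family = stats::binomial(),
    data = transform(df, tk_ = tk)))
  cf <- stats::coef(glm_fit)
  cf[!is.finite(cf)] <- 0
  start[idx$b0] <- pmin(pmax(cf[1:G], -8), 8)
  start[idx$b1] <- pmin(pmax(cf[G + 1:G], -2), 2)
  start[idx$b2] <- pmin(pmax(cf[2 * G + 1:G], -2), 2)
  start[idx$lsig] <- log(0.7)
  start[idx$lphi] <- log(0.1)

  lower <- c(rep(-30, 3 * G), rep(-10, n_gamma), -7, rep(-9, G))
  upper <- c(rep(30, 3 * G), rep(10, n_gamma), 3, rep(3, G))
  do_fit <- function(par0) {
    stats::nlminb(par0, nll, gradient = nll_gr, lower = lower, upper = upper,
                  control = list(iter.max = 500, eval.max = 1500,
                                 rel.tol = 1e-9))
  }
  opt <- do_fit(start)
  tries <- 0
  while (opt$convergence != 0 && tries < restarts) {
    tries <- tries + 1
    jit <- start + stats::rnorm(npar, 0, 0.3)
    cand <- do_fit(pmin(pmax(jit, lower), upper))
    if (cand$objective < opt$objective || cand$convergence == 0) opt <- cand
  }
  if (opt$convergence != 0 && abs(opt$objective) < 1e9) {
    gnorm <- sqrt(sum(nll_gr(opt$par)^2))
    if (gnorm > 1e-2)
      warning(sprintf(
        "optimizer did not report convergence (message '%s', gradient norm %.3g after %d restarts)",
        opt$message, gnorm, tries))
  }
  theta <- opt$par

  ## observed information: central-difference jacobian of the analytic score
  H <- matrix(NA_real_, npar, npar)
  for (k in seq_len(npar)) {
    h <- 1e-5 * (1 + abs(theta[k]))
    e <- numeric(npar); e[k] <- h
    H[k, ] <- (nll_gr(theta + e) - nll_gr(theta - e)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, npar, npar))
  se <- sqrt(pmax(diag(V), 0))

  lev <- levels(df$group)
  coef_tab <- data.frame(
    term = rep(c("intercept", "slope_pre", "slope_change"), each = G),
    group = rep(lev, 3),
    estimate = theta[c(idx$b0, idx$b1, idx$b2)],
    se = se[c(idx$b0, idx$b1, idx$b2)], row.names = NULL)
  coef_tab$p <- 2 * stats::pnorm(-abs(coef_tab$estimate / coef_tab$se))

  sigma_b <- exp(theta[idx$lsig])
  phi_g <- exp(theta[idx$lphi]); names(phi_g) <- lev

  ## marginal (population-average) mean RA at day t for group g
  mu_marg <- function(theta, gi, d) {
    sig <- exp(theta[idx$lsig])
    eta <- theta[idx$b0][gi] + theta[idx$b1][gi] * d +
      theta[idx$b2][gi] * pmax(d - knot, 0)
    vapply(eta, function(e)
      sum(gh$weights * stats::plogis(e + sqrt(2) * sig * gh$nodes)) / sqrt(pi),
      0)
  }

  grid <- seq(floor(min(t_)), ceiling(max(t_)), by = 0.5)
  curves <- do.call(rbind, lapply(seq_len(G), function(gi)
    data.frame(group = lev[gi], day = grid,
               mean_ra_pct = 100 * mu_marg(theta, gi, grid))))

  ## pairwise contrasts at requested days
  contr <- NULL
  pairs <- utils::combn(G, 2)
  for (d in contrast_days) {
    for (pp in seq_len(ncol(pairs))) {
      g1 <- pairs[1, pp]; g2 <- pairs[2, pp]
      L <- numeric(npar)
      L[idx$b0[g1]] <- 1; L[idx$b1[g1]] <- d; L[idx$b2[g1]] <- max(d - knot, 0)
      L[idx$b0[g2]] <- -1; L[idx$b1[g2]] <- -d; L[idx$b2[g2]] <- -max(d - knot, 0)
      est_l <- sum(L * theta)
      se_l <- sqrt(max(drop(L %*% V %*% L), 0))
      cfun <- function(th) mu_marg(th, g1, d) - mu_marg(th, g2, d)
      est_r <- cfun(theta)
      gr <- vapply(seq_len(npar), function(k) {
        e <- numeric(npar); e[k] <- 1e-5
        (cfun(theta + e) - cfun(theta - e)) / 2e-5
      }, 0)
      se_r <- sqrt(max(drop(gr %*% V %*% gr), 0))
      contr <- rbind(contr, data.frame(
        day = d, group_a = lev[g1], group_b = lev[g2],
        logit_diff = est_l, logit_se = se_l,
        logit_p = 2 * stats::pnorm(-abs(est_l / se_l)),
        ra_diff_pct = 100 * est_r, ra_se_pct = 100 * se_r,
        ra_p = 2 * stats::pnorm(-abs(est_r / se_r))))
    }
  }

  structure(list(taxon = taxon, knot = knot, groups = lev,
                 coefficients = coef_tab, sigma_b = sigma_b,
                 sigma_b_se = se[idx$lsig] * sigma_b,
                 phi = phi_g, phi_se = se[idx$lphi] * phi_g,
                 loglik = -opt$objective, contrasts = contr, curves = curves,
                 theta = theta, vcov = V, index = idx, nodes = nodes,
                 convergence = opt$convergence, message = opt$message,
                 data = df, mu_marg = mu_marg),
            class = "betabin_joinpoint")
}

#' @export
print.betabin_joinpoint <- function(x, ...) {
  cat(sprintf("Beta-binomial join-point mixed model for '%s' (knot day %.3g)\n",
              x$taxon, x$knot))
  cat(sprintf("  log-likelihood %.3f; random-intercept SD %.3f (SE %.3f)\n",
              x$loglik, x$sigma_b, x$sigma_b_se))
  cat("  dispersion by group:",
      paste(sprintf("%s=%.3f", names(x$phi), x$phi), collapse = ", "), "\n")
  cat("\nFixed effects (logit scale):\n")
  print(x$coefficients, digits = 4, row.names = FALSE)
  if (!is.null(x$contrasts)) {
    cat("\nGroup contrasts of mean RA:\n")
    print(x$contrasts, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Check a fitted join-point model for excess zeros
#'
#' Compares, within group-by-day bins, the observed fraction of zero counts
#' to the marginal zero probability implied by the fitted beta-binomial
#' model (random intercept integrated out by quadrature). A bin is flagged
#' when the absolute difference exceeds `z` times the binomial standard
#' error of the predicted zero fraction. Empty bins are skipped and reported
#' as such. Structural zeros (samples where the taxon is absent for reasons
#' the model does not represent) show up as flagged bins with observed
#' fraction above predicted.
#'
#' @param fit a [fit_betabin_joinpoint()] result.
#' @param series optional list of [subject_series()] to check the fitted
#'   model against; defaults to the data the model was fitted to. Note that
#'   a refit can absorb even structural zeros into the trend or the
#'   dispersion, so perturbations are most visible when checking a
#'   clean-data fit against perturbed data.
#' @param day_breaks bin edges for collection day.
#' @param z flag threshold in standard errors (default 2).
#' @return data frame, one row per group-day bin: number of observations,
#'   observed and predicted zero fractions, standard error, and `flag`
#'   (`"ok"`, `"excess"`, `"deficit"`, or `"empty"`).
#' @export
zero_inflation_check <- function(fit, series = NULL,
                                 day_breaks = c(0, 5, 10, 16, 24), z = 2) {
  df <- if (is.null(series)) fit$data
        else assemble_joinpoint_data(series, fit$taxon)
  g <- as.integer(factor(df$group, levels = fit$groups))
  gh <- gauss_hermite(fit$nodes)
  eta <- fit$theta[fit$index$b0][g] + fit$theta[fit$index$b1][g] * df$day +
    fit$theta[fit$index$b2][g] * pmax(df$day - fit$knot, 0)
  phi <- fit$phi[g]
  p0 <- vapply(seq_len(nrow(df)), function(i) {
    b <- sqrt(2) * fit$sigma_b * gh$nodes
    sum(gh$weights * dbetabinom(0, df$n[i], stats::plogis(eta[i] + b),
                                phi[i])) / sqrt(pi)
  }, 0)
  bin <- cut(df$day, day_breaks, include.lowest = TRUE)
  out <- NULL
  for (gi in fit$groups) for (bi in levels(bin)) {
    sel <- df$group == gi & bin == bi
    m <- sum(sel)
    if (m == 0) {
      out <- rbind(out, data.frame(group = gi, day_bin = bi, n_obs = 0,
                                   observed_zero_frac = NA_real_,
                                   predicted_zero_frac = NA_real_,
                                   se = NA_real_, flag = "empty"))
      next
    }
    obs <- mean(df$y[sel] == 0)
    pred <- mean(p0[sel])
    se <- sqrt(sum(p0[sel] * (1 - p0[sel]))) / m
    flag <- if (abs(obs - pred) <= z * se) "ok"
            else if (obs > pred) "excess" else "deficit"
    out <- rbind(out, data.frame(group = gi, day_bin = bi, n_obs = m,
                                 observed_zero_frac = obs,
                                 predicted_zero_frac = pred, se = se,
                                 flag = flag))
  }
  out
}
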