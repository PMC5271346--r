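#' Beta-binomial distribution (mean/dispersion parameterization)
#'
#' Density and random generation for the beta-binomial distribution
#' parameterized by mean `mu` and a single positive dispersion `phi`, with
#' beta shape parameters `a = mu/phi`, `b = (1-mu)/phi`. As `phi -> 0` the
#' distribution converges to `Binomial(size, mu)`; larger `phi` inflates the
#' variance to `size mu (1-mu) (1 + (size-1) phi/(1+phi))`.
#'
#' @param x vector of observed successes.
#' @param size number of trials (sequencing depth).
#' @param mu mean proportion in (0,1).
#' @param phi dispersion, `>= 0`.
#' @param log return log density?
#' @return `dbetabinom`: (log) density; `rbetabinom`: integer draws.
#' @export
dbetabinom <- function(x, size, mu, phi, log = FALSE) {
  n <- max(length(x), length(size), length(mu), length(phi))
  x <- rep_len(x, n); size <- rep_len(size, n)
  mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  out <- numeric(n)
  bad <- x < 0 | x > size | x != round(x)
  x[bad] <- 0                      # placeholder; masked to zero density below
  binom <- phi < 1e-10
  if (any(binom))
    out[binom] <- stats::dbinom(x[binom], size[binom], mu[binom], log = TRUE)
  if (any(!binom)) {
    a <- mu[!binom] / phi[!binom]
    b <- (1 - mu[!binom]) / phi[!binom]
    out[!binom] <- lchoose(size[!binom], x[!binom]) +
      lbeta(x[!binom] + a, size[!binom] - x[!binom] + b) - lbeta(a, b)
  }
  out[bad] <- -Inf
  if (log) out else exp(out)
}

#' @rdname dbetabinom
#' @param n number of draws.
#' @export
rbetabinom <- function(n, size, mu, phi) {
  size <- rep_len(size, n); mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  p <- ifelse(phi < 1e-10, mu,
              stats::rbeta(n, mu / pmax(phi, 1e-10), (1 - mu) / pmax(phi, 1e-10)))
  stats::rbinom(n, size, p)
}

## Gauss-Hermite rule (physicists' weight exp(-x^2)) via Golub-Welsch.
## Nodes are eigenvalues of the symmetric tridiagonal Jacobi matrix,
## weights sqrt(pi) * v[1,]^2.
gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  o <- order(e$values)
  list(nodes = e$values[o], weights = sqrt(pi) * e$vectors[1, o]^2)
}

## derivative of the beta-binomial log density w.r.t. the logit-mean eta,
## and second derivative; vectorized. mu = plogis(eta).
bb_deriv_eta <- function(y, n, eta, phi) {
  mu <- stats::plogis(eta)
  a <- mu / phi
  b <- (1 - mu) / phi
  dldmu <- (digamma(y + a) - digamma(n - y + b) - digamma(a) + digamma(b)) / phi
  d2ldmu2 <- (trigamma(y + a) + trigamma(n - y + b) -
                trigamma(a) - trigamma(b)) / phi^2
  dmu <- mu * (1 - mu)
  list(g = dldmu * dmu,
       h = d2ldmu2 * dmu^2 + dldmu * dmu * (1 - 2 * mu))
}
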