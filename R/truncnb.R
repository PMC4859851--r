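#' Zero-truncated negative binomial distribution
#'
#' Density, distribution function and random generation for the negative
#' binomial distribution conditioned on a strictly positive outcome, the
#' count family of hurdle models for overdispersed, zero-inflated berry
#' counts. The untruncated distribution has mean `mu` and size (dispersion)
#' `theta`, so that its variance is `mu + mu^2/theta`; the truncated density
#' is the negative binomial probability renormalised by `1 - P(0)` with
#' `P(0) = (theta/(theta + mu))^theta`.
#'
#' @param x,q vector of positive integer counts.
#' @param n number of draws.
#' @param mu mean of the untruncated negative binomial, `> 0`.
#' @param theta dispersion (size) parameter, `> 0`. Large `theta` approaches
#'   a zero-truncated Poisson.
#' @param log,log.p logical; return log-probabilities?
#'
#' @return `dztnbinom` the (log-)density, zero for `x < 1`; `pztnbinom` the
#'   cumulative probability; `rztnbinom` integer draws `>= 1`.
#'
#' @examples
#' sum(dztnbinom(1:500, mu = 2, theta = 1))   # ~1
#' mean(rztnbinom(1e4, mu = 2, theta = 1))    # ~ mu / (1 - P(0))
#' @export
dztnbinom <- function(x, mu, theta, log = FALSE) {
  lp0 <- ztnb_logp0(mu, theta)
  out <- dnbinom(x, size = theta, mu = mu, log = TRUE) - log1mexp(lp0)
  out[x < 1] <- -Inf
  if (log) out else exp(out)
}

#' @rdname dztnbinom
#' @export
pztnbinom <- function(q, mu, theta, log.p = FALSE) {
  p0 <- exp(ztnb_logp0(mu, theta))
  p <- (pnbinom(q, size = theta, mu = mu) - p0) / (1 - p0)
  p <- pmin(pmax(p, 0), 1)
  p[q < 1] <- 0
  if (log.p) log(p) else p
}

#' @rdname dztnbinom
#' @export
rztnbinom <- function(n, mu, theta) {
  p0 <- exp(ztnb_logp0(mu, theta))
  ## inversion restricted to (P(0), 1]: exact truncated draws
  u <- runif(n, min = p0, max = 1)
  qnbinom(u, size = theta, mu = mu)
}

#' Log-pmf of the zero-truncated negative binomial
#'
#' Convenience wrapper used by the model engine; errors on counts outside
#' the support instead of returning zero density.
#'
#' @param k positive integer count(s).
#' @inheritParams dztnbinom
#' @return log-probability vector.
#' @export
truncnb_logpmf <- function(k, mu, theta) {
  if (any(k < 1)) stop("zero-truncated support is k >= 1")
  dztnbinom(k, mu, theta, log = TRUE)
}

## log P(0) = theta * log(theta/(theta+mu)), stable for large theta
ztnb_logp0 <- function(mu, theta) -theta * log1p(mu / theta)

## log(1 - exp(x)) for x < 0, stable near 0 and -Inf
log1mexp <- function(x) {
  ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
}

## mean of the truncated distribution: mu / (1 - P(0))
ztnb_mean <- function(mu, theta) mu / (1 - exp(ztnb_logp0(mu, theta)))
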