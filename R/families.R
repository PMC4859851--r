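## Model families for the GLMM engine.
##
## Each family is a list of vectorised functions of the linear predictor eta
## (all accept matrix eta with the response recycled column-wise):
##   loglik(y, eta, disp)  log-density
##   d1(y, eta, disp)      d loglik / d eta
##   d2(y, eta, disp)      d^2 loglik / d eta^2 (used for inner Newton modes)
##   ddisp(y, eta, disp)   d loglik / d log(disp)  (NULL if no dispersion)
##   linkinv(eta)          response scale
##   has_disp              TRUE for NB/truncated-NB (theta) and gaussian (sd)
## disp is theta for the count families and the residual SD for gaussian.

CLAMP_ETA <- 30

glmm_family <- function(name) {
  switch(name,
    binomial = fam_binomial(),
    nbinom = fam_nbinom(),
    truncnbinom = fam_truncnbinom(),
    gaussian = fam_gaussian(),
    stop("unknown family: ", name)
  )
}

## stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  i <- x < 33
  out[i] <- log1p(exp(pmax(x[i], -33)))
  out
}

fam_binomial <- function() {
  list(
    name = "binomial",
    has_disp = FALSE,
    loglik = function(y, eta, disp = NULL) y * eta - log1pexp(eta),
    d1 = function(y, eta, disp = NULL) y - plogis(eta),
    d2 = function(y, eta, disp = NULL) {
      p <- plogis(eta)
      -p * (1 - p)
    },
    ddisp = NULL,
    linkinv = plogis,
    disp_name = NULL
  )
}

fam_nbinom <- function() {
  list(
    name = "nbinom",
    has_disp = TRUE,
    disp_name = "theta",
    loglik = function(y, eta, disp) {
      mu <- exp(pmin(pmax(eta, -CLAMP_ETA), CLAMP_ETA))
      dnbinom(y, size = disp, mu = mu, log = TRUE)
    },
    d1 = function(y, eta, disp) {
      mu <- exp(pmin(pmax(eta, -CLAMP_ETA), CLAMP_ETA))
      (y - mu) * disp / (disp + mu)
    },
    d2 = function(y, eta, disp) {
      mu <- exp(pmin(pmax(eta, -CLAMP_ETA), CLAMP_ETA))
      -disp * mu * (disp + y) / (disp + mu)^2
    },
    ddisp = function(y, eta, disp) {
      ## d loglik / d log(theta)
      mu <- exp(pmin(pmax(eta, -CLAMP_ETA), CLAMP_ETA))
      disp * (digamma(y + disp) - digamma(disp) + log(disp) + 1 -
        log(disp + mu) - (y + disp) / (disp + mu))
    },
    linkinv = exp
  )
}

fam_truncnbinom <- function() {
  nb <- fam_nbinom()
  list(
    name = "truncnbinom",
    has_disp = TRUE,
    disp_name = "theta",
    loglik = function(y, eta, disp) {
      mu <- exp(pmin(pmax(eta, -CLAMP_ETA), CLAMP_ETA))
      dnbinom(y, size = disp, mu = mu, log = TRUE) -
        log1mexp(ztnb_logp0(mu, disp))
    },
    d1 = function(y, eta, disp) {
      mu <- exp(pmin(pmax(eta, -CLAMP_ETA), CLAMP_ETA))
      p0 <- exp(ztnb_logp0(mu, disp))
      nb$d1(y, eta, disp) - p0 * disp * mu / ((disp + mu) * (1 - p0))
    },
    d2 = function(y, eta, disp) {
      mu <- exp(pmin(pmax(eta, -CLAMP_ETA), CLAMP_ETA))
      p0 <- exp(ztnb_logp0(mu, disp))
      FF <- p0 * disp^2 * mu / ((disp + mu)^2 * (1 - p0))
      nb$d2(y, eta, disp) - FF * (1 - mu / (1 - p0))
    },
    ddisp = function(y, eta, disp) {
      mu <- exp(pmin(pmax(eta, -CLAMP_ETA), CLAMP_ETA))
      p0 <- exp(ztnb_logp0(mu, disp))
      dp0_dtheta <- p0 * (log(disp / (disp + mu)) + mu / (disp + mu))
      nb$ddisp(y, eta, disp) + disp * dp0_dtheta / (1 - p0)
    },
    linkinv = exp
  )
}

fam_gaussian <- function() {
  list(
    name = "gaussian",
    has_disp = TRUE,
    disp_name = "sigma",
    loglik = function(y, eta, disp) {
      r <- y - eta
      -0.5 * log(2 * pi) - log(disp) - r^2 / (2 * disp^2)
    },
    d1 = function(y, eta, disp) (y - eta) / disp^2,
    d2 = function(y, eta, disp) {
      out <- eta
      out[] <- -1 / disp^2
      out
    },
    ddisp = function(y, eta, disp) {
      ## d loglik / d log(sigma)
      r <- y - eta
      -1 + r^2 / disp^2
    },
    linkinv = identity
  )
}

## Gauss-Hermite nodes/weights (physicists' weight exp(-x^2)) via
## Golub-Welsch on the symmetric Jacobi matrix.
gauss_hermite <- function(n) {
  if (n == 1) {
    return(list(nodes = 0, weights = sqrt(pi)))
  }
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(
    nodes = e$values[ord],
    weights = (sqrt(pi) * e$vectors[1, ]^2)[ord]
  )
}
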