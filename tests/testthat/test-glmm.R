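# The mixed-model engine: backend agreement, oracle agreement with lme4,
# quadrature stability, parameter recovery, hurdle structure

sim_binom_data <- function(n = 700, G = 7, beta = c(-0.3, 0.8, -0.5),
                           sigma = 0.5) {
  d <- data.frame(x = rnorm(n), z = rnorm(n), g = factor(rep(1:G, length.out = n)))
  b <- rnorm(G, 0, sigma)
  d$y <- rbinom(n, 1, plogis(beta[1] + beta[2] * d$x + beta[3] * d$z +
    b[as.integer(d$g)]))
  d
}

test_that("compiled and reference backends agree to near machine precision", {
  set.seed(71)
  d <- sim_binom_data()
  fc <- glmm_agq(y ~ x + z + (1 | g), d, "binomial", backend = "cpp")
  fr <- glmm_agq(y ~ x + z + (1 | g), d, "binomial", backend = "R")
  expect_equal(fc$logLik, fr$logLik, tolerance = 1e-10)
  expect_equal(coef(fc), coef(fr), tolerance = 1e-8)
  d$yt <- rztnbinom(nrow(d), exp(1 + 0.4 * d$x), theta = 1.5)
  tc <- glmm_agq(yt ~ x + (1 | g), d, "truncnbinom", backend = "cpp")
  tr <- glmm_agq(yt ~ x + (1 | g), d, "truncnbinom", backend = "R")
  expect_equal(tc$logLik, tr$logLik, tolerance = 1e-9)
  expect_equal(tc$theta, tr$theta, tolerance = 1e-6)
})

test_that("binomial quadrature fit reproduces the glmer oracle", {
  skip_if_not_installed("lme4")
  set.seed(72)
  d <- sim_binom_data()
  f <- glmm_agq(y ~ x + z + (1 | g), d, "binomial", nAGQ = 10)
  m <- lme4::glmer(y ~ x + z + (1 | g), d, family = binomial, nAGQ = 10)
  expect_equal(coef(f), lme4::fixef(m), tolerance = 1e-4)
  expect_equal(f$se, sqrt(diag(as.matrix(vcov(m)))),
    tolerance = 1e-3,
    ignore_attr = TRUE
  )
  expect_equal(f$logLik, as.numeric(logLik(m)), tolerance = 1e-6)
  expect_equal(f$sigma_re, sqrt(unlist(lme4::VarCorr(m))),
    tolerance = 1e-3, ignore_attr = TRUE
  )
})

test_that("gaussian fit reproduces maximum-likelihood lmer", {
  skip_if_not_installed("lme4")
  set.seed(73)
  d <- sim_binom_data()
  d$yg <- rnorm(nrow(d), 1 + 0.5 * d$x, 0.9) +
    rnorm(7, 0, 0.6)[as.integer(d$g)]
  f <- glmm_agq(yg ~ x + (1 | g), d, "gaussian")
  m <- lme4::lmer(yg ~ x + (1 | g), d, REML = FALSE)
  expect_equal(coef(f), lme4::fixef(m), tolerance = 1e-5)
  expect_equal(f$logLik, as.numeric(logLik(m)), tolerance = 1e-6)
  expect_equal(f$sigma_resid, stats::sigma(m), tolerance = 1e-4)
})

test_that("zero-truncated fit matches an independent direct optimisation", {
  set.seed(74)
  n <- 400
  x <- rnorm(n)
  y <- rztnbinom(n, exp(1.2 + 0.5 * x), 1.4)
  d <- data.frame(x = x, y = y)
  f <- glmm_agq(y ~ x, d, "truncnbinom")
  ## independent oracle: optim on a from-scratch truncated NB log-likelihood
  nll <- function(p) {
    mu <- exp(p[1] + p[2] * x)
    th <- exp(p[3])
    -sum(dnbinom(y, size = th, mu = mu, log = TRUE) -
      log(1 - (th / (th + mu))^th))
  }
  o <- optim(c(0, 0, 0), nll, method = "BFGS")
  expect_equal(unname(coef(f)), o$par[1:2], tolerance = 1e-4)
  expect_equal(log(f$theta), o$par[3], tolerance = 1e-3)
  expect_equal(f$logLik, -o$value, tolerance = 1e-6)
})

test_that("increasing quadrature nodes leaves the optimum essentially fixed", {
  set.seed(75)
  d <- sim_binom_data(n = 400)
  f10 <- glmm_agq(y ~ x + (1 | g), d, "binomial", nAGQ = 10, hessian = FALSE)
  f20 <- glmm_agq(y ~ x + (1 | g), d, "binomial", nAGQ = 20, hessian = FALSE)
  expect_lt(abs(f10$logLik - f20$logLik), 1e-4)
  ## Laplace (1 node) is close but not identical
  f1 <- glmm_agq(y ~ x + (1 | g), d, "binomial", nAGQ = 1, hessian = FALSE)
  expect_lt(abs(f1$logLik - f20$logLik), 0.5)
})

test_that("log-likelihood at the optimum dominates the generating parameters", {
  set.seed(76)
  d <- sim_binom_data(n = 500)
  f <- glmm_agq(y ~ x + z + (1 | g), d, "binomial", hessian = FALSE)
  ## evaluate the same marginal likelihood at the generating parameters
  X <- cbind(1, d$x, d$z)
  g <- as.integer(d$g)
  o <- order(g)
  eng <- bearberry:::glmm_engine(X[o, ], d$y[o], g[o],
    bearberry:::glmm_family("binomial"), 10,
    backend = "R"
  )
  truth_ll <- -eng$negll(c(-0.3, 0.8, -0.5, log(0.5)))
  expect_gte(f$logLik + 1e-6, truth_ll)
})

test_that("binomial recovery: estimates fall within 3 SE of the truth", {
  set.seed(77)
  d <- sim_binom_data(n = 2000, G = 7, beta = c(-0.3, 0.8, -0.5), sigma = 0.45)
  f <- glmm_agq(y ~ x + z + (1 | g), d, "binomial")
  expect_true(f$converged)
  expect_true(all(abs(coef(f) - c(-0.3, 0.8, -0.5)) < 3 * f$se))
})

test_that("hurdle fit factorises and its occurrence part ignores magnitudes", {
  set.seed(78)
  n <- 600
  d <- data.frame(x = rnorm(n), g = factor(rep(1:6, length.out = n)))
  occ <- rbinom(n, 1, plogis(0.4 + 0.6 * d$x))
  d$cnt <- occ * rztnbinom(n, exp(1.5 + 0.3 * d$x), 1)
  h <- hurdle_glmm(cnt ~ x + (1 | g), cnt ~ x + (1 | g), d)
  expect_equal(h$logLik, h$occurrence$logLik + h$abundance$logLik)
  ## occurrence part depends only on the zero/positive indicator
  d2 <- d
  d2$cnt <- d2$cnt * 10L
  h2 <- hurdle_glmm(cnt ~ x + (1 | g), cnt ~ x + (1 | g), d2)
  expect_equal(coef(h2$occurrence), coef(h$occurrence), tolerance = 1e-6)
  ## too few positives refused; all-positive counts flag the occurrence part
  expect_error(
    hurdle_glmm(cnt ~ x + (1 | g), cnt ~ x + (1 | g), d[1:40, ],
      min_positive = 30
    ),
    "positive"
  )
  d3 <- d[d$cnt >= 1, ]
  expect_warning(
    h3 <- hurdle_glmm(cnt ~ x + (1 | g), cnt ~ x + (1 | g), d3),
    "degenerate"
  )
  expect_null(h3$occurrence)
})

test_that("hurdle recovery: occurrence and abundance effects within 3 SE", {
  set.seed(79)
  n <- 900
  d <- data.frame(x = rnorm(n), g = factor(rep(1:7, length.out = n)))
  b <- rnorm(7, 0, 0.45)
  occ <- rbinom(n, 1, plogis(0.3 + 0.9 * d$x + b[as.integer(d$g)]))
  d$cnt <- occ * rztnbinom(n, exp(1.2 + 0.5 * d$x + b[as.integer(d$g)]), 1.2)
  h <- hurdle_glmm(cnt ~ x + (1 | g), cnt ~ x + (1 | g), d)
  expect_true(abs(coef(h$occurrence)[["x"]] - 0.9) <
    3 * h$occurrence$se[["x"]])
  expect_true(abs(coef(h$abundance)[["x"]] - 0.5) <
    3 * h$abundance$se[["x"]])
})

test_that("prediction methods follow the link conventions", {
  set.seed(80)
  d <- sim_binom_data(n = 300)
  f <- glmm_agq(y ~ x + (1 | g), d, "binomial")
  nd <- data.frame(x = -coef(f)[["(Intercept)"]] / coef(f)[["x"]])
  expect_equal(predict(f, nd, type = "response"), 0.5, ignore_attr = TRUE)
  pp <- predict_population(f, data.frame(x = c(-1, 0, 1)))
  expect_true(all(pp$lwr <= pp$fit & pp$fit <= pp$upr))
  expect_true(all(pp$fit > 0 & pp$fit < 1))
  ## identity link: prediction is exactly c'beta
  d$yg <- rnorm(nrow(d), 2 - 0.7 * d$x, 1)
  fg <- glmm_agq(yg ~ x + (1 | g), d, "gaussian")
  nd <- data.frame(x = c(0, 2))
  expect_equal(
    unname(predict(fg, nd)),
    unname(coef(fg)[1] + coef(fg)[2] * c(0, 2))
  )
  ## unseen factor level errors
  d$h <- factor(sample(c("a", "b"), nrow(d), TRUE))
  fh <- glmm_agq(y ~ h + (1 | g), d, "binomial", hessian = FALSE)
  expect_error(predict(fh, data.frame(h = "c")), "level")
})

test_that("simulate() round-trips through the generating distribution", {
  set.seed(81)
  d <- sim_binom_data(n = 400)
  f <- glmm_agq(y ~ x + (1 | g), d, "binomial", hessian = FALSE)
  s <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(s), c(400L, 3L))
  expect_true(all(unlist(s) %in% 0:1))
  expect_identical(s, simulate(f, nsim = 3, seed = 1))
})
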