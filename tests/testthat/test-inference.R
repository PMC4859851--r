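# Inference machinery: VIF screen, LR tests, backward selection,
# single-step contrasts, population predictions, auxiliary tests

test_that("VIF: orthogonal designs score 1, duplicates blow up and drop", {
  set.seed(91)
  n <- 200
  X <- qr.Q(qr(matrix(rnorm(n * 3), n)))
  colnames(X) <- c("a", "b", "c")
  v <- vif_screen(X)
  expect_equal(unname(v$vif), rep(1, 3), tolerance = 1e-3)
  expect_length(v$dropped, 0)

  X2 <- cbind(X, d = X[, 1])
  v2 <- vif_screen(X2)
  expect_true(is.infinite(max(v2$history[[1]])))
  expect_true("a" %in% v2$dropped || "d" %in% v2$dropped)
  expect_true(all(v2$vif <= 3))
})

test_that("VIF values equal the direct 1/(1-R^2) recomputation", {
  set.seed(92)
  n <- 300
  z <- rnorm(n)
  X <- cbind(x1 = z + rnorm(n), x2 = z + rnorm(n), x3 = rnorm(n))
  v <- vif_screen(X, cutoff = 100)$vif
  for (j in 1:3) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
})

test_that("LR test: identical refits give chi-square 0, p = 1", {
  set.seed(93)
  d <- data.frame(x = rnorm(120), g = factor(rep(1:4, 30)))
  d$y <- rnorm(120, 1 + 0.5 * d$x)
  f1 <- glmm_agq(y ~ x + (1 | g), d, "gaussian", hessian = FALSE)
  f2 <- glmm_agq(y ~ x + (1 | g), d, "gaussian", hessian = FALSE)
  ## same model twice is not nested (equal df) -> compare against reduced
  red <- glmm_agq(y ~ 1 + (1 | g), d, "gaussian", hessian = FALSE)
  lt <- lr_test(f1, red)
  expect_gte(lt$chisq, 0)
  expect_equal(lt$df, 1)
  expect_error(lr_test(f1, f2), "nested")
  expect_error(lr_test(red, f1), "nested")
})

test_that("LR statistic matches the closed-form RSS ratio for linear models", {
  set.seed(94)
  n <- 150
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  d$y <- rnorm(n, 1 + 0.4 * d$x)
  full <- glmm_agq(y ~ x + z, d, "gaussian", hessian = FALSE)
  red <- glmm_agq(y ~ x, d, "gaussian", hessian = FALSE)
  lt <- lr_test(full, red)
  rss1 <- sum(residuals(lm(y ~ x + z, d))^2)
  rss0 <- sum(residuals(lm(y ~ x, d))^2)
  expect_equal(lt$chisq, n * log(rss0 / rss1), tolerance = 1e-4)
})

test_that("backward selection respects marginality and keeps real effects", {
  set.seed(95)
  n <- 400
  d <- data.frame(
    x = rnorm(n), h = factor(sample(c("A", "B"), n, TRUE)),
    g = factor(rep(1:5, length.out = n))
  )
  ## strong main effects and a strong interaction
  d$y <- rnorm(n, 1 + 1.5 * d$x + 2 * (d$h == "B") + 2 * d$x * (d$h == "B"), 1)
  f <- glmm_agq(y ~ x * h + (1 | g), d, "gaussian", hessian = FALSE)
  sel <- backward_select(f)
  kept <- attr(terms(sel$fit$fixed_formula), "term.labels")
  expect_setequal(kept, c("x", "h", "x:h"))
  ## trace never tests a main effect while its interaction is in the model
  tested_while <- subset(sel$trace, term %in% c("x", "h"))
  expect_equal(nrow(tested_while), 0)
})

test_that("a pure-noise covariate is almost always eliminated", {
  set.seed(96)
  dropped <- replicate(20, {
    n <- 250
    d <- data.frame(
      x = rnorm(n), junk = rnorm(n),
      g = factor(rep(1:5, length.out = n))
    )
    d$y <- rnorm(n, 1 + 1.2 * d$x, 1)
    f <- glmm_agq(y ~ x + junk + (1 | g), d, "gaussian", hessian = FALSE)
    sel <- backward_select(f)
    !"junk" %in% attr(terms(sel$fit$fixed_formula), "term.labels")
  })
  expect_gte(mean(dropped), 0.75)
})

make_factor_fit <- function(n = 400, means = c(0, 0, 0, 0), seed = 97) {
  set.seed(seed)
  d <- data.frame(
    f = factor(rep(c("a", "b", "c", "d"), each = n / 4)),
    g = factor(rep(1:4, length.out = n))
  )
  d$y <- rnorm(n, means[as.integer(d$f)], 1)
  glmm_agq(y ~ f + (1 | g), d, "gaussian")
}

test_that("single-step adjustment: identity for one contrast, Sidak when independent", {
  fit <- make_factor_fit()
  one <- pairwise_contrasts(fit, "f", pairs = cbind(1, 2), ndraws = 2e5)
  expect_equal(one$p_adj, one$p_raw, tolerance = 0.01)
  ## (a-b) and (c-d) are independent in a balanced one-way design
  two <- pairwise_contrasts(fit, "f",
    pairs = rbind(c(1, 2), c(3, 4)),
    ndraws = 2e5
  )
  sidak <- 1 - (1 - two$p_raw)^2
  expect_equal(two$p_adj, pmax(sidak, two$p_raw), tolerance = 0.01)
  ## self-contrast is exactly null
  self <- pairwise_contrasts(fit, "f", pairs = cbind(2, 2))
  expect_equal(self$estimate, 0)
  expect_equal(self$p_adj, 1)
})

test_that("adjusted p-values are monotone in |z| and bounded by raw ones", {
  fit <- make_factor_fit(means = c(0, 0.3, 0.8, 1.6), seed = 98)
  ctr <- pairwise_contrasts(fit, "f", which = "all")
  expect_true(all(ctr$p_adj >= ctr$p_raw - 1e-12))
  ord <- order(abs(ctr$z))
  expect_true(all(diff(ctr$p_adj[ord]) <= 1e-9))
  expect_equal(nrow(ctr), choose(4, 2))
})

test_that("contrast estimates and SEs equal direct linear algebra", {
  fit <- make_factor_fit(means = c(0, 1, 2, 3), seed = 99)
  ctr <- pairwise_contrasts(fit, "f", pairs = cbind(1, 3))
  ## cells: a vs c -> difference of dummy coefficients
  b <- coef(fit)
  V <- vcov(fit)
  cvec <- c(0, 0, -1, 0)
  expect_equal(ctr$estimate, -b[["fc"]])
  expect_equal(ctr$se, sqrt(drop(t(cvec) %*% V %*% cvec)), tolerance = 1e-10)
})

test_that("interaction contrasts restrict to within-level pairs by default", {
  set.seed(100)
  n <- 600
  d <- data.frame(
    t = factor(sample(c("R", "B"), n, TRUE), levels = c("R", "B")),
    h = factor(sample(c("x", "y", "z"), n, TRUE)),
    g = factor(rep(1:5, length.out = n))
  )
  d$y <- rnorm(n, (d$t == "B") * (1 + (d$h == "z")), 1)
  f <- glmm_agq(y ~ t * h + (1 | g), d, "gaussian")
  within <- pairwise_contrasts(f, "t:h")
  all_p <- pairwise_contrasts(f, "t:h", which = "all")
  expect_equal(nrow(all_p), choose(6, 2))
  expect_equal(nrow(within), 9) # 3 cross-type + 2*3 within-type
})

test_that("population predictions: Wald interval matches a parametric bootstrap", {
  set.seed(101)
  n <- 500
  d <- data.frame(x = rnorm(n), g = factor(rep(1:5, length.out = n)))
  d$y <- rbinom(n, 1, plogis(0.2 + 0.7 * d$x))
  f <- glmm_agq(y ~ x + (1 | g), d, "binomial")
  nd <- data.frame(x = c(-1, 0.5))
  pp <- predict_population(f, nd)
  ## bootstrap oracle: draw beta from (hat beta, vcov), quantiles of inv-logit
  B <- chol(vcov(f))
  draws <- matrix(rnorm(2e4 * 2), ncol = 2) %*% B
  for (i in seq_len(nrow(nd))) {
    eta <- coef(f)[1] + coef(f)[2] * nd$x[i] + draws %*% c(1, nd$x[i])
    qs <- quantile(plogis(eta), c(0.025, 0.975))
    expect_equal(pp$lwr[i], unname(qs[1]), tolerance = 0.015)
    expect_equal(pp$upr[i], unname(qs[2]), tolerance = 0.015)
  }
})

test_that("auxiliary tests match their textbook formulas", {
  set.seed(102)
  x <- rnorm(40)
  y <- 0.5 * x + rnorm(40)
  pc <- pearson_cor(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt(38 / (1 - r^2))
  expect_equal(pc$r, r, tolerance = 1e-12)
  expect_equal(pc$p, 2 * pt(-abs(tstat), 38), tolerance = 1e-12)
  expect_equal(pearson_cor(x, x)$r, 1)
  expect_error(pearson_cor(rep(1, 10), rnorm(10)), "variance")

  a <- rnorm(30, 1)
  b <- rnorm(25, 1.4, 2)
  wt <- welch_t(a, b)
  se <- sqrt(var(a) / 30 + var(b) / 25)
  expect_equal(wt$t, (mean(a) - mean(b)) / se, tolerance = 1e-12)
  df <- se^4 / ((var(a) / 30)^2 / 29 + (var(b) / 25)^2 / 24)
  expect_equal(wt$df, df, tolerance = 1e-9)
})
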