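#' @export
print.glmm_agq <- function(x, ...) {
  cat("GLMM (", x$family, ", adaptive Gauss-Hermite, ", x$nAGQ,
    " nodes)\n",
    sep = ""
  )
  cat("Formula:", deparse(x$formula), "\n")
  cat("n =", x$nobs, if (x$ngroups > 0) paste0("; groups = ", x$ngroups), "\n")
  cat("logLik =", format(x$logLik, digits = 6), " df =", x$df, "\n")
  print(coef(x), digits = 4)
  if (!is.null(x$theta)) cat("theta =", format(x$theta, digits = 4), "\n")
  if (!is.null(x$sigma_resid)) cat("residual SD =", format(x$sigma_resid, digits = 4), "\n")
  if (!is.null(x$sigma_re)) cat("random-intercept SD =", format(x$sigma_re, digits = 4), "\n")
  if (!x$converged) cat("** fit did not converge **\n")
  invisible(x)
}

#' @export
summary.glmm_agq <- function(object, ...) {
  b <- coef(object)
  se <- object$se
  if (is.null(se)) se <- rep(NA_real_, length(b))
  z <- b / se
  tab <- cbind(
    Estimate = b, `Std. Error` = se, `z value` = z,
    `Pr(>|z|)` = 2 * pnorm(-abs(z))
  )
  out <- list(
    coefficients = tab, family = object$family, theta = object$theta,
    sigma_re = object$sigma_re, sigma_resid = object$sigma_resid,
    logLik = object$logLik, df = object$df, nobs = object$nobs,
    ngroups = object$ngroups, converged = object$converged,
    formula = object$formula
  )
  class(out) <- "summary.glmm_agq"
  out
}

#' @export
print.summary.glmm_agq <- function(x, ...) {
  cat("GLMM (", x$family, ") ", deparse(x$formula), "\n", sep = "")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  if (!is.null(x$theta)) cat("theta =", format(x$theta, digits = 4), "\n")
  if (!is.null(x$sigma_re)) cat("random-intercept SD =", format(x$sigma_re, digits = 4), "\n")
  if (!is.null(x$sigma_resid)) cat("residual SD =", format(x$sigma_resid, digits = 4), "\n")
  cat(
    "logLik =", format(x$logLik, digits = 6), "on", x$df, "parameters;",
    "n =", x$nobs, "\n"
  )
  if (!x$converged) cat("** fit did not converge **\n")
  invisible(x)
}

#' @export
coef.glmm_agq <- function(object, ...) object$coefficients

#' Fixed effects of a fitted mixed model
#' @param object a `glmm_agq` fit.
#' @param ... unused.
#' @return named coefficient vector.
#' @export
fixef <- function(object, ...) UseMethod("fixef")

#' @rdname fixef
#' @export
fixef.glmm_agq <- function(object, ...) object$coefficients

#' @export
vcov.glmm_agq <- function(object, full = FALSE, ...) {
  if (full) object$vcov_full else object$vcov
}

#' @export
logLik.glmm_agq <- function(object, ...) {
  structure(object$logLik,
    df = object$df, nobs = object$nobs,
    class = "logLik"
  )
}

#' @export
nobs.glmm_agq <- function(object, ...) object$nobs

## design matrix for new data using the stored terms/levels
design_for <- function(object, newdata) {
  tt <- delete.response(object$terms)
  m <- model.frame(tt, newdata, xlev = object$xlevels, na.action = na.pass)
  model.matrix(tt, m, contrasts.arg = object$contrasts)
}

#' @param object fitted `glmm_agq` model.
#' @param newdata data frame of covariates; `NULL` uses the training data.
#' @param type `"link"` or `"response"` scale.
#' @param se.fit also return standard errors (link scale, delta-method on
#'   response scale).
#' @param re `"zero"` for population-level predictions (random intercept set
#'   to 0) or `"modes"` to add each group's posterior modal intercept.
#' @param ... unused.
#' @rdname glmm_agq
#' @export
predict.glmm_agq <- function(object, newdata = NULL,
                             type = c("link", "response"),
                             se.fit = FALSE, re = c("zero", "modes"), ...) {
  type <- match.arg(type)
  re <- match.arg(re)
  if (is.null(newdata)) newdata <- object$data_used
  X <- design_for(object, newdata)
  eta <- drop(X %*% coef(object))
  if (re == "modes" && !is.null(object$ranef)) {
    g <- as.character(newdata[[object$group_var]])
    eta <- eta + object$ranef[g]
  }
  fam <- glmm_family(object$family)
  if (!se.fit) {
    return(if (type == "response") fam$linkinv(eta) else eta)
  }
  if (is.null(object$vcov)) stop("fit has no covariance matrix (hessian = FALSE?)")
  se <- sqrt(pmax(rowSums((X %*% object$vcov) * X), 0))
  if (type == "link") {
    return(list(fit = eta, se.fit = se))
  }
  mu <- fam$linkinv(eta)
  dmu <- switch(object$family,
    binomial = mu * (1 - mu),
    gaussian = rep(1, length(mu)),
    mu
  )
  list(fit = mu, se.fit = se * dmu)
}

#' Population-level predictions with Wald confidence intervals
#'
#' Response-scale predictions for the population mean (random intercept set
#' to zero), with a symmetric Wald interval computed on the link scale and
#' back-transformed, the convention used for prediction curves over the
#' berry season.
#'
#' @param fit a `glmm_agq` model.
#' @param newdata covariate data frame to predict at.
#' @param level confidence level (default 0.95).
#' @return `newdata` with columns `fit`, `lwr`, `upr` appended.
#' @export
predict_population <- function(fit, newdata, level = 0.95) {
  pr <- predict(fit, newdata, type = "link", se.fit = TRUE, re = "zero")
  zc <- qnorm(1 - (1 - level) / 2)
  fam <- glmm_family(fit$family)
  out <- newdata
  out$fit <- fam$linkinv(pr$fit)
  out$lwr <- fam$linkinv(pr$fit - zc * pr$se.fit)
  out$upr <- fam$linkinv(pr$fit + zc * pr$se.fit)
  out
}

#' @export
simulate.glmm_agq <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                              re = c("draw", "zero"), ...) {
  re <- match.arg(re)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) newdata <- object$data_used
  X <- design_for(object, newdata)
  eta0 <- drop(X %*% coef(object))
  n <- length(eta0)
  fam <- glmm_family(object$family)
  out <- matrix(NA_real_, n, nsim)
  g <- if (!is.null(object$group_var)) factor(newdata[[object$group_var]]) else NULL
  for (s in seq_len(nsim)) {
    eta <- eta0
    if (re == "draw" && !is.null(g) && !is.null(object$sigma_re)) {
      b <- rnorm(nlevels(g), 0, object$sigma_re)
      eta <- eta + b[as.integer(g)]
    }
    out[, s] <- switch(object$family,
      binomial = rbinom(n, 1, plogis(eta)),
      nbinom = stats::rnbinom(n, size = object$theta, mu = exp(eta)),
      truncnbinom = rztnbinom(n, mu = exp(eta), theta = object$theta),
      gaussian = rnorm(n, eta, object$sigma_resid)
    )
  }
  as.data.frame(out)
}

#' @export
residuals.glmm_agq <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- predict(object, type = "response", re = "modes")
  r <- object$y - mu
  if (type == "response") {
    return(r)
  }
  v <- switch(object$family,
    binomial = mu * (1 - mu),
    nbinom = mu + mu^2 / object$theta,
    truncnbinom = mu + mu^2 / object$theta, # untruncated approximation
    gaussian = rep(object$sigma_resid^2, length(mu))
  )
  r / sqrt(v)
}

#' Hurdle mixed model: occurrence and zero-truncated abundance
#'
#' Fits the two independent parts of a hurdle model for zero-inflated,
#' overdispersed counts: a binomial (logit) model for occurrence
#' (`count >= 1`) over all rows, and a zero-truncated negative binomial
#' (log) model for abundance over the rows with positive counts. The hurdle
#' likelihood factorises, so the total log-likelihood is the sum of the two
#' parts.
#'
#' @param occurrence formula for the occurrence part; the response is the
#'   raw count variable and is converted internally to the `>= 1` indicator.
#' @param abundance formula for the abundance part (response = same count).
#' @param data data frame with non-negative integer counts.
#' @param min_positive minimum number of positive rows required to attempt
#'   the abundance fit (default 30).
#' @param ... passed to [glmm_agq()] (e.g. `nAGQ`, `hessian`).
#' @return object of class `"hurdle_glmm"` with elements `occurrence` and
#'   `abundance` (each a `glmm_agq` fit, occurrence `NULL` with a note when
#'   degenerate), and `logLik` their sum.
#' @export
hurdle_glmm <- function(occurrence, abundance, data, min_positive = 30, ...) {
  resp <- all.vars(occurrence)[1]
  cnt <- data[[resp]]
  if (is.null(cnt)) stop("response '", resp, "' not found")
  if (any(cnt < 0, na.rm = TRUE)) stop("hurdle counts must be non-negative")

  occ_fit <- NULL
  note <- NULL
  ind <- as.numeric(cnt >= 1)
  if (length(unique(ind[!is.na(ind)])) < 2) {
    note <- "occurrence part degenerate: response all-positive or all-zero"
    warning(note)
  } else {
    d_occ <- data
    d_occ[[resp]] <- ind
    occ_fit <- glmm_agq(occurrence, d_occ, family = "binomial", ...)
  }

  pos <- data[!is.na(cnt) & cnt >= 1, , drop = FALSE]
  if (nrow(pos) < min_positive) {
    stop(
      "only ", nrow(pos), " positive counts; >= ", min_positive,
      " required for the zero-truncated abundance fit"
    )
  }
  abn_fit <- glmm_agq(abundance, pos, family = "truncnbinom", ...)

  out <- list(
    occurrence = occ_fit, abundance = abn_fit, note = note,
    logLik = (if (is.null(occ_fit)) 0 else occ_fit$logLik) + abn_fit$logLik,
    call = match.call()
  )
  class(out) <- "hurdle_glmm"
  out
}

#' @export
print.hurdle_glmm <- function(x, ...) {
  cat("Hurdle mixed model\n")
  if (!is.null(x$note)) cat("[", x$note, "]\n")
  if (!is.null(x$occurrence)) {
    cat("\n-- Occurrence (binomial, logit) --\n")
    print(x$occurrence)
  }
  cat("\n-- Abundance (zero-truncated NB, log) --\n")
  print(x$abundance)
  cat("\nTotal logLik =", format(x$logLik, digits = 6), "\n")
  invisible(x)
}

#' @export
logLik.hurdle_glmm <- function(object, ...) {
  df <- object$abundance$df + (if (is.null(object$occurrence)) 0 else object$occurrence$df)
  structure(object$logLik, df = df, class = "logLik")
}
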