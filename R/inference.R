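#' Variance-inflation-factor screen
#'
#' Computes VIF_j = 1/(1 - R^2_j) from regressing each numeric predictor on
#' all others and iteratively drops the predictor with the largest VIF above
#' the cut-off until all remaining values are at or below it. A cut-off of 3
#' is the conventional collinearity screen applied before model fitting.
#'
#' @param predictors data frame or matrix of numeric predictors (no missing
#'   values).
#' @param cutoff drop threshold (default 3).
#' @return list with `vif` (final named vector), `retained`, `dropped`
#'   (in drop order) and `history` (VIF vectors per iteration).
#' @export
vif_screen <- function(predictors, cutoff = 3) {
  X <- as.matrix(predictors)
  if (!is.numeric(X)) stop("predictors must be numeric")
  if (anyNA(X)) stop("predictors must not contain missing values")
  if (ncol(X) < 2) stop("need >= 2 predictors")

  vif_of <- function(M) {
    vapply(seq_len(ncol(M)), function(j) {
      yj <- M[, j]
      Z <- cbind(1, M[, -j, drop = FALSE])
      fit <- lm.fit(Z, yj)
      rss <- sum(fit$residuals^2)
      tss <- sum((yj - mean(yj))^2)
      if (tss <= 0) {
        return(1)
      }
      r2 <- 1 - rss / tss
      if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }

  keep <- colnames(X)
  if (is.null(keep)) keep <- paste0("x", seq_len(ncol(X)))
  colnames(X) <- keep
  dropped <- character(0)
  history <- list()
  repeat {
    v <- setNames(vif_of(X[, keep, drop = FALSE]), keep)
    history[[length(history) + 1]] <- v
    if (length(keep) < 2 || max(v) <= cutoff) break
    worst <- names(which.max(v))
    dropped <- c(dropped, worst)
    keep <- setdiff(keep, worst)
  }
  list(
    vif = history[[length(history)]], retained = keep, dropped = dropped,
    history = history
  )
}

#' Likelihood-ratio test between nested fits
#'
#' Compares a full and a reduced maximum-likelihood fit on the same rows:
#' chi-square = 2 (logLik_full - logLik_reduced) with degrees of freedom the
#' difference in parameter counts. A (numerically) negative statistic is
#' clamped to zero with a warning.
#'
#' @param full,reduced `glmm_agq` fits; `reduced` must be nested in `full`
#'   and fitted to the same data rows.
#' @return list of class `"lr_test"` with `chisq`, `df`, `p`.
#' @export
lr_test <- function(full, reduced) {
  if (full$nobs != reduced$nobs) stop("fits use different numbers of rows")
  if (full$family != reduced$family) stop("fits use different families")
  t_full <- attr(terms(full$fixed_formula), "term.labels")
  t_red <- attr(terms(reduced$fixed_formula), "term.labels")
  if (!all(t_red %in% t_full) || full$df <= reduced$df) {
    stop("'reduced' is not nested in 'full'")
  }
  chisq <- 2 * (full$logLik - reduced$logLik)
  if (chisq < 0) {
    if (chisq < -1e-4) warning("negative LR statistic clamped to 0")
    chisq <- 0
  }
  df <- full$df - reduced$df
  out <- list(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE))
  class(out) <- "lr_test"
  out
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf(
    "LR chi-square = %.3f, df = %d, p = %.4g\n", x$chisq, x$df,
    x$p
  ))
  invisible(x)
}

## refit a glmm_agq with a new fixed-effects term set, warm-started
refit_glmm <- function(fit, keep_terms, hessian = FALSE) {
  resp <- deparse(fit$fixed_formula[[2]])
  rhs <- c(keep_terms, if (!is.null(fit$group_var)) paste0("(1 | ", fit$group_var, ")"))
  f <- if (length(rhs)) {
    reformulate(rhs, response = resp)
  } else {
    as.formula(paste(resp, "~ 1"))
  }
  start <- list(
    beta = coef(fit),
    log_disp = if (!is.null(fit$theta)) {
      log(fit$theta)
    } else if (!is.null(fit$sigma_resid)) log(fit$sigma_resid),
    log_sigma_re = if (!is.null(fit$sigma_re)) log(fit$sigma_re)
  )
  glmm_agq(f, fit$data_used,
    family = fit$family, nAGQ = fit$nAGQ,
    start = start, hessian = hessian
  )
}

#' Stepwise backward model selection by likelihood-ratio tests
#'
#' Starting from a fitted full model, repeatedly tests every currently
#' droppable term (respecting marginality: interactions are droppable before
#' the main effects they contain) with a likelihood-ratio test against the
#' refitted reduced model, and removes the single least significant term
#' whose p-value exceeds `alpha`. Iterates until every remaining term is
#' significant at `alpha`; may reduce to the intercept-only model.
#'
#' @param fit a converged `glmm_agq` full-model fit.
#' @param alpha significance threshold for retaining a term (default 0.05).
#' @param verbose print each drop as it happens.
#' @return list of class `"backward_select"` with `fit` (final model,
#'   refitted with standard errors) and `trace` (data frame of every test:
#'   round, term, chisq, df, p, dropped flag).
#' @export
backward_select <- function(fit, alpha = 0.05, verbose = FALSE) {
  current <- fit
  trace <- list()
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    scope <- drop.scope(current$fixed_formula)
    if (!length(scope)) break
    tests <- lapply(scope, function(tm) {
      keep <- setdiff(attr(terms(current$fixed_formula), "term.labels"), tm)
      red <- refit_glmm(current, keep, hessian = FALSE)
      list(term = tm, keep = keep, lrt = lr_test(current, red), red = red)
    })
    ps <- vapply(tests, function(t) t$lrt$p, numeric(1))
    worst <- which.max(ps)
    for (i in seq_along(tests)) {
      trace[[length(trace) + 1]] <- data.frame(
        round = round_i, term = tests[[i]]$term,
        chisq = tests[[i]]$lrt$chisq, df = tests[[i]]$lrt$df,
        p = ps[i], dropped = i == worst && ps[i] > alpha
      )
    }
    if (ps[worst] <= alpha) break
    if (verbose) {
      message(sprintf(
        "dropping %s (p = %.3f)", tests[[worst]]$term,
        ps[worst]
      ))
    }
    current <- tests[[worst]]$red
  }
  if (is.null(current$vcov)) {
    current <- refit_glmm(
      current,
      attr(terms(current$fixed_formula), "term.labels"),
      hessian = TRUE
    )
  }
  out <- list(fit = current, trace = do.call(rbind, trace))
  class(out) <- "backward_select"
  out
}

#' @export
print.backward_select <- function(x, ...) {
  dropped <- x$trace$term[x$trace$dropped]
  cat(
    "Backward selection:",
    if (length(dropped)) paste("dropped", paste(dropped, collapse = ", ")) else "nothing dropped",
    "\n"
  )
  cat("Final model:", deparse(x$fit$formula), "\n")
  invisible(x)
}

#' Pairwise contrasts with single-step multiplicity adjustment
#'
#' All pairwise comparisons of the cell means of a factor (or of the cells
#' of a factor-by-factor interaction) on the link scale, with familywise
#' single-step adjusted p-values. Each contrast is a linear combination
#' c'beta with SE sqrt(c'Vc); adjusted p-values are tail probabilities of
#' max|z| under the joint normal with the correlation implied by the
#' coefficient covariance, evaluated by seeded Monte-Carlo sampling.
#'
#' Remaining numeric covariates are held at their training means and
#' uninvolved factors at their reference level (they cancel from every
#' contrast).
#'
#' @param fit a `glmm_agq` fit with a covariance matrix.
#' @param term a factor name (e.g. `"habitat"`) or interaction label
#'   (e.g. `"plot_type:habitat"`) present in the model.
#' @param which `"within"` (default) compares only cells sharing the level
#'   of all but one involved factor, the conventional set for a two-factor
#'   interaction; `"all"` compares every cell pair.
#' @param pairs optional two-column matrix of cell indices overriding the
#'   automatic pair set (cells ordered as `expand.grid` of the involved
#'   factor levels).
#' @param ndraws Monte-Carlo draws for the adjustment (default 1e5).
#' @param seed RNG seed for the adjustment draws (default 1); the caller's
#'   RNG state is restored afterwards.
#' @return data frame of class `"contrast_result"`: `label`, `estimate`,
#'   `se`, `z`, `p_raw`, `p_adj`.
#' @export
pairwise_contrasts <- function(fit, term, which = c("within", "all"),
                               pairs = NULL, ndraws = 1e5, seed = 1) {
  which <- match.arg(which)
  if (is.null(fit$vcov)) stop("fit has no covariance matrix")
  facs <- strsplit(term, ":", fixed = TRUE)[[1]]
  bad <- setdiff(facs, names(fit$xlevels))
  if (length(bad)) stop("not factors in the model: ", paste(bad, collapse = ", "))

  grid <- expand.grid(fit$xlevels[facs],
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  ## baseline for everything else
  other <- setdiff(all.vars(delete.response(fit$terms)), facs)
  for (v in other) {
    grid[[v]] <- if (v %in% names(fit$xlevels)) {
      fit$xlevels[[v]][1]
    } else {
      mean(fit$data_used[[v]])
    }
  }
  Xc <- design_for(fit, grid)
  labs <- apply(grid[, facs, drop = FALSE], 1, paste, collapse = " x ")

  if (is.null(pairs)) {
    pairs <- t(utils::combn(nrow(grid), 2))
    if (which == "within" && length(facs) > 1) {
      share <- apply(pairs, 1, function(pr) {
        sum(grid[pr[1], facs] == grid[pr[2], facs]) == length(facs) - 1
      })
      pairs <- pairs[share, , drop = FALSE]
    }
  }
  C <- Xc[pairs[, 1], , drop = FALSE] - Xc[pairs[, 2], , drop = FALSE]
  est <- drop(C %*% coef(fit))
  V <- C %*% fit$vcov %*% t(C)
  se <- sqrt(pmax(diag(V), 0))
  z <- ifelse(se > 0, est / se, 0)
  p_raw <- ifelse(se > 0, 2 * pnorm(-abs(z)), 1)

  ## single-step max-|z| adjustment under the joint normal
  m <- length(z)
  live <- se > 0
  p_adj <- rep(1, m)
  if (any(live)) {
    R <- cov2cor(V[live, live, drop = FALSE] +
      diag(1e-10, sum(live)))
    U <- chol(R + diag(1e-8, nrow(R)))
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(seed)
    D <- matrix(rnorm(ndraws * nrow(R)), ndraws) %*% U
    maxab <- abs(D[, 1])
    for (j in seq_len(ncol(D))[-1]) maxab <- pmax(maxab, abs(D[, j]))
    p_adj[live] <- vapply(abs(z[live]), function(a) mean(maxab >= a), numeric(1))
  }
  p_adj <- pmax(p_adj, p_raw)

  out <- data.frame(
    label = paste(labs[pairs[, 1]], "-", labs[pairs[, 2]]),
    estimate = est, se = se, z = z, p_raw = p_raw, p_adj = p_adj,
    stringsAsFactors = FALSE
  )
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Pearson correlation and Welch two-sample t-test
#'
#' Thin wrappers around [stats::cor.test()] and [stats::t.test()] (Welch,
#' Satterthwaite degrees of freedom) returning flat result lists, used for
#' the small auxiliary comparisons (cross-species count correlation, sugar
#' content between species).
#'
#' @param x,y numeric vectors (paired for `pearson_cor`; the two groups for
#'   `welch_t`).
#' @return `pearson_cor`: list `r`, `p`, `df`; `welch_t`: list `t`, `df`,
#'   `p`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) stop("need >= 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(
    r = unname(ct$estimate), p = ct$p.value,
    df = unname(ct$parameter)
  )
}

#' @rdname pearson_cor
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per group")
  if (sd(x) == 0 && sd(y) == 0) stop("zero variance")
  tt <- t.test(x, y, var.equal = FALSE)
  list(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value
  )
}
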