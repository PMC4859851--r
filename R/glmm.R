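#' Fit a GLMM with one random intercept by adaptive Gauss-Hermite quadrature
#'
#' Maximum-likelihood fit of a generalised linear mixed model with a single
#' random intercept, the model class used throughout used-versus-available
#' berry analyses: binomial (logit) occurrence models, negative binomial and
#' zero-truncated negative binomial (log) count models, and Gaussian
#' (identity) sugar-content models. The marginal likelihood integrates the
#' random intercept per group by adaptive Gauss-Hermite quadrature; one
#' quadrature node is the Laplace approximation.
#'
#' The random intercept is written in the formula as `(1 | group)`, e.g.
#' `count ~ plot_type + habitat + elevation + (1 | bear_id)`. A formula
#' without a `(1 | group)` term fits the corresponding fixed-effects model
#' by maximum likelihood with the same machinery.
#'
#' Standard errors come from the inverse of the observed information
#' (numerically differentiated at the optimum). Dispersion (`theta` for the
#' count families, residual SD for Gaussian) and the random-intercept SD are
#' estimated jointly on the log scale.
#'
#' @param formula model formula with at most one `(1 | group)` term.
#' @param data data frame containing all model variables.
#' @param family one of `"binomial"`, `"nbinom"`, `"truncnbinom"`,
#'   `"gaussian"`.
#' @param nAGQ number of quadrature nodes (default 10; 1 = Laplace).
#' @param start optional named list with elements `beta` (named vector,
#'   matched by coefficient name), `log_disp`, `log_sigma_re` used as
#'   starting values (as produced by a previous fit; used for warm starts).
#' @param hessian compute the observed-information covariance matrix
#'   (default `TRUE`; backward selection switches it off for speed since
#'   only the log-likelihood is needed).
#' @param control list passed to [stats::nlminb()] control.
#' @param backend `"cpp"` (compiled quadrature kernel, default) or `"R"`
#'   (pure-R reference implementation of the same likelihood; the two agree
#'   to near machine precision and the R path is kept as an independent
#'   check).
#'
#' @return An object of class `"glmm_agq"` with components `coefficients`,
#'   `se`, `vcov`, `theta`, `sigma_re`, `sigma_resid`, `logLik`, `df`,
#'   `converged`, `ranef` (posterior modes), `nobs`, `ngroups`, plus the
#'   formula/terms/data bookkeeping used by the methods.
#'
#' @seealso [hurdle_glmm()], [lr_test()], [backward_select()],
#'   [predict_population()]
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(200), g = rep(letters[1:5], each = 40))
#' b <- rnorm(5, sd = 0.5)
#' d$y <- rbinom(200, 1, plogis(0.3 + 0.8 * d$x + b[as.integer(factor(d$g))]))
#' fit <- glmm_agq(y ~ x + (1 | g), d, family = "binomial")
#' coef(fit)
#' @export
glmm_agq <- function(formula, data, family = c(
                       "binomial", "nbinom",
                       "truncnbinom", "gaussian"
                     ),
                     nAGQ = 10, start = NULL, hessian = TRUE,
                     control = list(), backend = c("cpp", "R")) {
  family <- match.arg(family)
  backend <- match.arg(backend)
  fam <- glmm_family(family)
  pf <- parse_mixed_formula(formula)

  vars <- unique(c(all.vars(pf$fixed), pf$group))
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("variables not found in data: ", paste(miss, collapse = ", "))
  dat <- data[, vars, drop = FALSE]
  cc <- complete.cases(dat)
  if (!all(cc)) {
    warning(sum(!cc), " rows with missing values dropped")
    dat <- dat[cc, , drop = FALSE]
  }

  mf <- model.frame(pf$fixed, dat)
  tt <- attr(mf, "terms")
  y <- model.response(mf)
  if (family == "binomial") {
    if (is.logical(y)) y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) stop("binomial response must be 0/1")
    if (length(unique(y)) < 2) stop("binomial response is degenerate (all ", y[1], ")")
  }
  if (family == "truncnbinom" && any(y < 1)) {
    stop("zero-truncated family requires counts >= 1")
  }
  X <- model.matrix(tt, mf)
  n <- nrow(X)
  p <- ncol(X)

  group <- NULL
  G <- 0L
  if (!is.null(pf$group)) {
    gf <- factor(dat[[pf$group]])
    if (nlevels(gf) < 2) stop("grouping variable needs >= 2 levels")
    ## sort rows by group so per-group reductions are contiguous
    ord <- order(as.integer(gf))
    X <- X[ord, , drop = FALSE]
    y <- y[ord]
    dat <- dat[ord, , drop = FALSE]
    gf <- gf[ord]
    group <- as.integer(gf)
    G <- nlevels(gf)
  }

  ## standardise non-intercept columns for a well-conditioned optimisation
  std <- standardize_design(X)
  Xs <- std$Xs

  eng <- glmm_engine(Xs, y, group, fam, nAGQ, backend)
  par0 <- glmm_start(Xs, y, fam, group, start, std)
  opt <- nlminb(par0, eng$negll, gradient = eng$neggrad,
    control = modifyList(list(iter.max = 500, eval.max = 700), control)
  )
  if (opt$convergence != 0 &&
    !grepl("relative convergence|X convergence|singular convergence", opt$message)) {
    ## one retry from a jittered start with more iterations
    opt2 <- nlminb(opt$par + rnorm(length(opt$par), 0, 0.05), eng$negll,
      gradient = eng$neggrad, control = list(iter.max = 800, eval.max = 1000)
    )
    if (opt2$objective < opt$objective) opt <- opt2
  }
  converged <- opt$convergence == 0 ||
    grepl("relative convergence|X convergence", opt$message)

  par_int <- unname(opt$par)
  beta_int <- par_int[seq_len(p)]
  extras <- par_int[-seq_len(p)]
  beta <- drop(std$A %*% beta_int)
  names(beta) <- colnames(X)

  theta <- sigma_resid <- sigma_re <- NULL
  k <- p
  if (fam$has_disp) {
    k <- k + 1L
    if (fam$disp_name == "theta") theta <- exp(par_int[k]) else sigma_resid <- exp(par_int[k])
  }
  if (!is.null(group)) {
    k <- k + 1L
    sigma_re <- exp(par_int[k])
  }

  vc_full <- vc_beta <- se <- NULL
  if (hessian) {
    H <- num_hessian(eng$neggrad, par_int)
    Af <- diag(length(par_int))
    Af[seq_len(p), seq_len(p)] <- std$A
    Vint <- try(solve(H), silent = TRUE)
    if (inherits(Vint, "try-error") || any(!is.finite(Vint)) ||
      any(diag(Vint) <= 0)) {
      converged <- FALSE
      warning("observed information not positive definite; SEs unavailable")
    } else {
      vc_full <- Af %*% Vint %*% t(Af)
      nm <- c(colnames(X), if (fam$has_disp) paste0("log_", fam$disp_name),
        if (!is.null(group)) "log_sigma_re")
      dimnames(vc_full) <- list(nm, nm)
      vc_beta <- vc_full[seq_len(p), seq_len(p), drop = FALSE]
      se <- sqrt(diag(vc_beta))
    }
  }

  separation <- family == "binomial" && !is.null(se) &&
    any(abs(beta) > 12 & se > 10)
  if (separation) warning("possible complete separation in binomial fit")

  ranef <- NULL
  if (!is.null(group)) {
    ranef <- setNames(eng$last_modes(par_int), levels(gf))
  }

  out <- list(
    coefficients = beta, se = se, vcov = vc_beta, vcov_full = vc_full,
    theta = theta, sigma_re = sigma_re, sigma_resid = sigma_resid,
    logLik = -opt$objective, df = length(par_int), nobs = n, ngroups = G,
    converged = converged, separation = separation, opt = opt,
    family = family, nAGQ = nAGQ,
    formula = formula, fixed_formula = pf$fixed, group_var = pf$group,
    terms = tt, xlevels = stats::.getXlevels(tt, mf),
    contrasts = attr(X, "contrasts"),
    data_used = dat, y = y, ranef = ranef,
    call = match.call()
  )
  class(out) <- "glmm_agq"
  out
}

## ---- formula handling -----------------------------------------------------

## split a formula into its fixed part and the (single) "1 | g" term
parse_mixed_formula <- function(formula) {
  tl <- attr(terms(formula, keep.order = TRUE), "term.labels")
  bars <- grep("\\|", tl, value = TRUE)
  if (length(bars) > 1) stop("only a single random-intercept term is supported")
  group <- NULL
  if (length(bars) == 1) {
    parts <- strsplit(bars, "\\|")[[1]]
    if (trimws(parts[1]) != "1") {
      stop("only random intercepts '(1 | group)' are supported")
    }
    group <- trimws(parts[2])
  }
  fixed_terms <- setdiff(tl, bars)
  resp <- deparse(formula[[2]])
  fixed <- if (length(fixed_terms)) {
    reformulate(fixed_terms, response = resp)
  } else {
    as.formula(paste(resp, "~ 1"))
  }
  environment(fixed) <- environment(formula)
  list(fixed = fixed, group = group)
}

## ---- design standardisation ----------------------------------------------

standardize_design <- function(X) {
  p <- ncol(X)
  m <- colMeans(X)
  s <- apply(X, 2, sd)
  icpt <- which(colnames(X) == "(Intercept)")
  scale_cols <- which(s > 0 & seq_len(p) != if (length(icpt)) icpt else 0L)
  m[setdiff(seq_len(p), scale_cols)] <- 0
  s[setdiff(seq_len(p), scale_cols)] <- 1
  Xs <- sweep(sweep(X, 2, m, "-"), 2, s, "/")
  ## beta_orig = A %*% beta_internal
  A <- diag(1 / s, p)
  if (length(icpt)) A[icpt, scale_cols] <- -m[scale_cols] / s[scale_cols]
  list(Xs = Xs, A = A, m = m, s = s)
}

## ---- starting values ------------------------------------------------------

glmm_start <- function(Xs, y, fam, group, start, std) {
  p <- ncol(Xs)
  beta0 <- rep(0, p)
  base_fam <- switch(fam$name,
    binomial = binomial(),
    gaussian = gaussian(),
    poisson()
  )
  g0 <- suppressWarnings(try(glm.fit(Xs, y, family = base_fam), silent = TRUE))
  if (!inherits(g0, "try-error")) {
    b <- coef(g0)
    b[!is.finite(b)] <- 0
    beta0 <- b
  }
  extras <- numeric(0)
  if (fam$has_disp) {
    extras <- c(extras, if (fam$name == "gaussian") {
      log(max(sd(y - drop(Xs %*% beta0)), 1e-3))
    } else {
      0 # theta = 1
    })
  }
  if (!is.null(group)) extras <- c(extras, log(0.3))
  par0 <- c(beta0, extras)
  if (!is.null(start)) {
    ## map a previous fit's coefficients (original scale) into internal scale
    if (!is.null(start$beta)) {
      b_orig <- rep(0, p)
      nm <- colnames(Xs)
      hit <- intersect(names(start$beta), nm)
      b_orig[match(hit, nm)] <- start$beta[hit]
      ## invert beta = A b_int  =>  b_int = solve(A) beta
      par0[seq_len(p)] <- drop(solve(std$A, b_orig))
    }
    k <- p
    if (fam$has_disp) {
      k <- k + 1L
      if (!is.null(start$log_disp)) par0[k] <- start$log_disp
    }
    if (!is.null(group) && !is.null(start$log_sigma_re)) par0[k + 1L] <- start$log_sigma_re
  }
  par0
}

## ---- likelihood engine ----------------------------------------------------

## Builds negative log-likelihood and gradient closures. The gradient uses
## the posterior-weighted score at the quadrature nodes (exact as the
## quadrature error vanishes); inner random-intercept modes are found by a
## Newton iteration per group and warm-started between calls. The compiled
## backend evaluates value and gradient in one pass (memoised on the
## parameter vector); the R backend is the vectorised reference.
glmm_engine <- function(Xs, y, group, fam, nAGQ, backend = "cpp") {
  if (backend == "cpp" && !is.null(group)) {
    return(glmm_engine_cpp(Xs, y, group, fam, nAGQ))
  }
  glmm_engine_r(Xs, y, group, fam, nAGQ)
}

glmm_engine_cpp <- function(Xs, y, group, fam, nAGQ) {
  gh <- gauss_hermite(nAGQ)
  lwk <- log(gh$weights) + gh$nodes^2
  G <- max(group)
  gstart <- c(0L, cumsum(tabulate(group, G)))
  famcode <- match(fam$name, c("binomial", "nbinom", "truncnbinom", "gaussian")) - 1L
  env <- new.env(parent = emptyenv())
  env$b <- rep(0, G)
  env$par <- NULL
  storage.mode(Xs) <- "double"
  y <- as.double(y)

  eval_at <- function(par) {
    if (!is.null(env$par) && identical(par, env$par)) {
      return(env$res)
    }
    res <- .agq_core_cpp(Xs, y, gstart, famcode, gh$nodes, lwk, par, env$b, TRUE)
    if (is.finite(res$ll)) env$b <- res$b
    env$par <- par
    env$res <- res
    res
  }
  list(
    negll = function(par) {
      r <- eval_at(par)
      if (!is.finite(r$ll)) {
        return(1e10)
      }
      -r$ll
    },
    neggrad = function(par) {
      r <- eval_at(par)
      if (!is.finite(r$ll) || any(!is.finite(r$grad))) {
        return(rep(0, length(par)))
      }
      -r$grad
    },
    last_modes = function(par) eval_at(par)$b
  )
}

glmm_engine_r <- function(Xs, y, group, fam, nAGQ) {
  n <- nrow(Xs)
  p <- ncol(Xs)
  gh <- gauss_hermite(nAGQ)
  zk <- gh$nodes
  lwk <- log(gh$weights) + zk^2
  K <- nAGQ
  G <- if (is.null(group)) 0L else max(group)
  env <- new.env(parent = emptyenv())
  env$b <- rep(0, G)

  unpack <- function(par) {
    beta <- par[seq_len(p)]
    k <- p
    disp <- NULL
    if (fam$has_disp) {
      k <- k + 1L
      disp <- exp(par[k])
    }
    sig <- NULL
    if (G > 0) {
      k <- k + 1L
      sig <- exp(par[k])
    }
    list(beta = beta, disp = disp, sig = sig)
  }

  find_modes <- function(eta0, disp, sig) {
    b <- env$b
    for (it in 1:30) {
      d1 <- fam$d1(y, eta0 + b[group], disp)
      d2 <- fam$d2(y, eta0 + b[group], disp)
      hp <- as.vector(rowsum(d1, group)) - b / sig^2
      hpp <- as.vector(rowsum(d2, group)) - 1 / sig^2
      step <- hp / hpp
      step <- pmin(pmax(step, -4), 4)
      b <- b - step
      if (max(abs(step)) < 1e-8) break
    }
    env$b <- b
    d2 <- fam$d2(y, eta0 + b[group], disp)
    hpp <- as.vector(rowsum(d2, group)) - 1 / sig^2
    list(b = b, tau = 1 / sqrt(-hpp))
  }

  ## per-(group,node) pieces shared by value and gradient
  core <- function(par) {
    u <- unpack(par)
    eta0 <- drop(Xs %*% u$beta)
    if (G == 0) {
      return(list(u = u, eta0 = eta0, ll = sum(fam$loglik(y, eta0, u$disp))))
    }
    md <- find_modes(eta0, u$disp, u$sig)
    B <- outer(md$tau * sqrt(2), zk) + md$b # G x K
    ETA <- eta0 + B[group, , drop = FALSE] # n x K
    LF <- matrix(fam$loglik(y, as.vector(ETA), u$disp), n, K)
    H <- rowsum(LF, group) - B^2 / (2 * u$sig^2) -
      log(u$sig) - 0.5 * log(2 * pi) # G x K
    S <- sweep(H, 2, lwk, "+")
    amax <- apply(S, 1, max)
    lse <- amax + log(rowSums(exp(S - amax)))
    ll <- sum(log(sqrt(2) * md$tau) + lse)
    P <- exp(S - lse) # posterior node weights, G x K
    list(u = u, eta0 = eta0, ll = ll, B = B, ETA = ETA, P = P)
  }

  negll <- function(par) {
    v <- try(core(par)$ll, silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) {
      return(1e10)
    }
    -v
  }

  neggrad <- function(par) {
    cr <- try(core(par), silent = TRUE)
    if (inherits(cr, "try-error") || !is.finite(cr$ll)) {
      return(rep(0, length(par)))
    }
    u <- cr$u
    if (G == 0) {
      d1 <- fam$d1(y, cr$eta0, u$disp)
      g <- drop(crossprod(Xs, d1))
      if (fam$has_disp) g <- c(g, sum(fam$ddisp(y, cr$eta0, u$disp)))
      return(-g)
    }
    PR <- cr$P[group, , drop = FALSE] # n x K
    D1 <- matrix(fam$d1(y, as.vector(cr$ETA), u$disp), n, K)
    g <- drop(crossprod(Xs, rowSums(D1 * PR)))
    if (fam$has_disp) {
      DD <- matrix(fam$ddisp(y, as.vector(cr$ETA), u$disp), n, K)
      g <- c(g, sum(DD * PR))
    }
    g <- c(g, sum(cr$P * (cr$B^2 / u$sig^2 - 1)))
    -g
  }

  last_modes <- function(par) {
    u <- unpack(par)
    if (G == 0) {
      return(NULL)
    }
    find_modes(drop(Xs %*% u$beta), u$disp, u$sig)$b
  }

  list(negll = negll, neggrad = neggrad, last_modes = last_modes)
}

## central-difference Hessian from an analytic gradient
num_hessian <- function(grad, par) {
  q <- length(par)
  H <- matrix(0, q, q)
  h <- 1e-5 * pmax(abs(par), 1)
  for (j in seq_len(q)) {
    up <- dn <- par
    up[j] <- par[j] + h[j]
    dn[j] <- par[j] - h[j]
    H[, j] <- (grad(up) - grad(dn)) / (2 * h[j])
  }
  (H + t(H)) / 2
}
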