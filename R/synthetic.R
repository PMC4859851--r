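## Synthetic study generator: patchy landscape layers, species-specific
## hurdle berry fields with a bear-level random intercept, sugar content,
## and 3-state bear movement at 30-min fixes, all with recorded ground
## truth so every pipeline stage can be validated end to end.

## ---- smooth random fields -------------------------------------------------

## bilinear interpolation of a coarse lattice V onto an nr x nc grid
bilinear_lattice <- function(V, nr, nc) {
  k <- nrow(V)
  l <- ncol(V)
  u <- seq(1, k, length.out = nr)
  v <- seq(1, l, length.out = nc)
  i0 <- pmin(floor(u), k - 1)
  j0 <- pmin(floor(v), l - 1)
  A <- matrix(u - i0, nr, nc)
  B <- matrix(v - j0, nr, nc, byrow = TRUE)
  V[i0, j0] * (1 - A) * (1 - B) + V[i0 + 1, j0] * A * (1 - B) +
    V[i0, j0 + 1] * (1 - A) * B + V[i0 + 1, j0 + 1] * A * B
}

## standardised sum of bilinearly interpolated white-noise octaves
smooth_field <- function(nr, nc, scales = c(10, 4), weights = c(1, 0.35)) {
  f <- matrix(0, nr, nc)
  for (i in seq_along(scales)) {
    k <- max(2, scales[i])
    f <- f + weights[i] * bilinear_lattice(matrix(rnorm(k * k), k, k), nr, nc)
  }
  (f - mean(f)) / sd(f)
}

## mean filter with half-width hw (edge-replicated)
box_blur <- function(m, hw = 2) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0, nr, nc)
  cnt <- 0
  for (dr in -hw:hw) {
    for (dc in -hw:hw) {
      r <- pmin(pmax(seq_len(nr) + dr, 1), nr)
      c <- pmin(pmax(seq_len(nc) + dc, 1), nc)
      out <- out + m[r, c]
      cnt <- cnt + 1
    }
  }
  out / cnt
}

## ---- landscape ------------------------------------------------------------

#' Generate a synthetic boreal forest landscape
#'
#' Produces co-registered layers emulating a managed boreal forest:
#' a patchy categorical habitat map with configurable class shares (default
#' 10 % bog, 8 % clearcut, 42 % young forest, 40 % mature forest, the
#' composition of the commercial forest landscape emulated here), a smooth
#' elevation field spanning 200-600 m, slope (degrees) and cardinal aspect
#' derived from the elevation gradient, and NDVI in [-1, 0.86] positively
#' associated with local young-forest density (dense regrowth has the
#' highest vegetation index).
#'
#' Habitat patches come from thresholding two independent smooth random
#' fields ("wetness" for bog/other, "stand age" for the forest classes) at
#' the share quantiles, so realised shares match the targets up to grid
#' granularity. All randomness uses the current RNG stream.
#'
#' @param nrow,ncol grid size in cells (default 140 x 140).
#' @param cell cell size in metres (default 25).
#' @param x0,y0 lower-left corner coordinates (default 500000, 6740000,
#'   i.e. plausible projected metres).
#' @param shares named habitat shares summing to 1; may include `other`.
#' @return a [landscape_grid()] with layers `habitat`, `elevation`,
#'   `slope`, `aspect`, `ndvi`.
#' @export
gen_landscape <- function(nrow = 140, ncol = 140, cell = 25,
                          x0 = 500000, y0 = 6740000,
                          shares = c(
                            bog = 0.10, clearcut = 0.08,
                            young_forest = 0.42, mature_forest = 0.40
                          )) {
  if (!isTRUE(all.equal(sum(shares), 1))) stop("habitat shares must sum to 1")
  bad <- setdiff(names(shares), HABITAT_LEVELS)
  if (length(bad)) stop("unknown habitat classes: ", paste(bad, collapse = ", "))

  wet <- smooth_field(nrow, ncol, scales = c(7, 3))
  age <- smooth_field(nrow, ncol, scales = c(9, 4))

  habitat <- matrix(NA_character_, nrow, ncol)
  s_bog <- if ("bog" %in% names(shares)) shares[["bog"]] else 0
  s_oth <- if ("other" %in% names(shares)) shares[["other"]] else 0
  if (s_bog > 0) habitat[wet <= quantile(wet, s_bog)] <- "bog"
  if (s_oth > 0) habitat[wet >= quantile(wet, 1 - s_oth)] <- "other"
  forest <- is.na(habitat)
  s_for <- 1 - s_bog - s_oth
  fa <- age[forest]
  s_cc <- if ("clearcut" %in% names(shares)) shares[["clearcut"]] / s_for else 0
  s_mf <- if ("mature_forest" %in% names(shares)) shares[["mature_forest"]] / s_for else 0
  qs <- quantile(fa, c(s_cc, 1 - s_mf))
  hf <- ifelse(fa <= qs[1], "clearcut",
    ifelse(fa > qs[2], "mature_forest", "young_forest")
  )
  habitat[forest] <- hf

  base <- smooth_field(nrow, ncol, scales = c(5, 2), weights = c(1, 0.2))
  rough <- smooth_field(nrow, ncol, scales = c(35, 70), weights = c(1, 0.6))
  elev <- base + 0.12 * rough
  elev <- 200 + 400 * (elev - min(elev)) / (max(elev) - min(elev))

  gx <- (elev[, pmin(seq_len(ncol) + 1, ncol)] -
    elev[, pmax(seq_len(ncol) - 1, 1)]) / (2 * cell)
  gy <- (elev[pmax(seq_len(nrow) - 1, 1), ] -
    elev[pmin(seq_len(nrow) + 1, nrow), ]) / (2 * cell) # northward uphill
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  ## cardinal aspect = direction of steepest descent; flat cells face N
  aspect <- ifelse(abs(gy) >= abs(gx),
    ifelse(gy >= 0, "S", "N"),
    ifelse(gx >= 0, "W", "E")
  )

  young <- box_blur((habitat == "young_forest") * 1, hw = 2)
  ndvi <- 0.30 + 0.45 * young + 0.12 * smooth_field(nrow, ncol) -
    0.20 * (habitat == "bog")
  ndvi <- pmin(pmax(ndvi, -1), 0.86)

  landscape_grid(x0, y0, cell, list(
    habitat = habitat, elevation = elev, slope = slope,
    aspect = aspect, ndvi = ndvi
  ))
}

## ---- berry field ----------------------------------------------------------

#' Default generating coefficients of the synthetic berry field
#'
#' Hurdle coefficients per species (logit occurrence, log abundance),
#' negative binomial dispersion `theta`, and the SD of the unmodelled
#' spatial patchiness field. Covariates enter uncentred (elevation in m,
#' day of year, NDVI); habitat effects are relative to bog. The defaults
#' reproduce the qualitative seasonal pattern of a boreal berry season:
#' bilberry occurrence/abundance declining and lingonberry rising over a
#' ~32-day window, forestry classes driving occurrence, and a rare, highly
#' zero-inflated crowberry that is generated but never modelled.
#'
#' @return nested named list of species parameters.
#' @export
berry_field_params <- function() {
  list(
    bilberry = list(
      occ = list(
        intercept = 2.6,
        habitat = c(bog = 0, clearcut = 1.469, mature_forest = 2.59, young_forest = 1.313, other = -1),
        elevation = 0.003, ordinal_day = -0.022, ndvi = 0, plot_type = 0
      ),
      abn = list(
        intercept = 3.9,
        habitat = c(bog = 0, clearcut = 0.637, mature_forest = 0.574, young_forest = 0.575, other = -1),
        elevation = 0, ordinal_day = -0.008, ndvi = 0, plot_type = 0.828
      ),
      theta = 1.2, patch_sd_occ = 1.1, patch_sd_abn = 0
    ),
    lingonberry = list(
      occ = list(
        intercept = -19.2,
        habitat = c(bog = 0, clearcut = 2.706, mature_forest = 1.466, young_forest = 1.644, other = -1),
        elevation = 0.004, ordinal_day = 0.07, ndvi = 0, plot_type = 0
      ),
      abn = list(
        intercept = -3.0,
        habitat = c(bog = 0, clearcut = 1.5, mature_forest = 0.4, young_forest = 0.9, other = -1),
        elevation = 0, ordinal_day = 0.028, ndvi = -2.304, plot_type = 0
      ),
      theta = 0.9, patch_sd_occ = 1.1, patch_sd_abn = 0
    ),
    crowberry = list(
      occ = list(
        intercept = -2.2,
        habitat = c(bog = 0.5, clearcut = 0, mature_forest = 0, young_forest = 0, other = -1),
        elevation = 0, ordinal_day = 0, ndvi = 0, plot_type = 0
      ),
      abn = list(
        intercept = 2.0,
        habitat = c(bog = 0, clearcut = 0, mature_forest = 0, young_forest = 0, other = 0),
        elevation = 0, ordinal_day = 0, ndvi = 0, plot_type = 0
      ),
      theta = 0.4, patch_sd_occ = 0.5, patch_sd_abn = 0
    )
  )
}

#' Default generating coefficients of the sugar-content model
#'
#' Gaussian total-soluble-solids (%Brix) models per species around the
#' species mean, with covariates (and the aspect contrasts) centred at
#' reference values (elevation 400 m, NDVI 0.44, day 233) so the marginal
#' species means stay near their defaults (8.48 for bilberry, 12.04 for
#' lingonberry, 5.57 for crowberry). The covariate effect sizes (negative
#' NDVI and elevation effects, opposite seasonal trends) are scaled to the
#' synthetic landscape's covariate variability so that the TOTAL marginal
#' SD, covariate variation included, lands near the reported empirical
#' spreads (about 1.4). A plot-type (used vs available) effect applies to
#' lingonberry only.
#'
#' @return nested named list of sugar parameters.
#' @export
sugar_params <- function() {
  list(
    centers = c(elevation = 400, ndvi = 0.44, ordinal_day = 233),
    bilberry = list(
      mean = 8.48, sd = 1.1, plot_type = 0,
      ndvi = -2.5, elevation = -0.003, ordinal_day = -0.049,
      ## aspect contrasts centred so they do not shift the species mean
      aspect = c(N = -0.3495, E = 0.0345, S = 0.2155, W = 0.0995)
    ),
    lingonberry = list(
      mean = 12.04, sd = 1.2, plot_type = 0.579,
      ndvi = -2.0, elevation = 0, ordinal_day = 0.028,
      aspect = c(N = 0, E = 0, S = 0, W = 0)
    ),
    crowberry = list(
      mean = 5.57, sd = 0.9, plot_type = 0,
      ndvi = 0, elevation = 0, ordinal_day = 0,
      aspect = c(N = 0, E = 0, S = 0, W = 0)
    ),
    re_sd = 0.3
  )
}

## linear predictor from a named coefficient list over plot covariates
berry_lp <- function(df, coefs, offset = 0) {
  lp <- coefs$intercept +
    coefs$habitat[as.character(df$habitat)] +
    coefs$elevation * df$elevation +
    coefs$ordinal_day * df$ordinal_day +
    coefs$ndvi * df$ndvi +
    offset
  if (!is.null(df$plot_type) && !is.null(coefs$plot_type)) {
    lp <- lp + coefs$plot_type * (as.character(df$plot_type) == "Bear")
  }
  unname(lp)
}

#' Draw per-plot berry counts from the hurdle berry field
#'
#' Occurrence is Bernoulli with inverse-logit probability of the occurrence
#' linear predictor; given occurrence, the count is zero-truncated negative
#' binomial with log-link mean from the abundance predictor. Species draw
#' independently (berry counts of different species are uncorrelated).
#'
#' @param df plot covariate data frame (`habitat`, `elevation`, `ndvi`,
#'   `ordinal_day`, optional `plot_type`).
#' @param params species parameter list as from [berry_field_params()].
#' @param re_occ,re_abn per-row random-intercept offsets (e.g. the assigned
#'   bear's effect), recycled; default 0.
#' @param offset_occ,offset_abn additional per-row offsets (e.g. the
#'   unmodelled patchiness field), recycled; default 0.
#' @return data frame of integer counts, one column per species in
#'   `params`.
#' @export
sample_plot_counts <- function(df, params, re_occ = 0, re_abn = 0,
                               offset_occ = 0, offset_abn = 0) {
  n <- nrow(df)
  out <- list()
  for (sp in setdiff(names(params), "centers")) {
    pp <- params[[sp]]
    p_occ <- plogis(berry_lp(df, pp$occ, rep_len(re_occ, n) + rep_len(offset_occ, n)))
    mu <- exp(pmin(berry_lp(df, pp$abn, rep_len(re_abn, n) + rep_len(offset_abn, n)), 12))
    occ <- rbinom(n, 1, p_occ)
    cnt <- integer(n)
    if (any(occ == 1)) {
      cnt[occ == 1] <- rztnbinom(sum(occ == 1), mu = mu[occ == 1], theta = pp$theta)
    }
    out[[paste0("count_", sp)]] <- cnt
  }
  as.data.frame(out)
}

#' Draw sugar content (TSS, %Brix) for plots where a species is present
#'
#' Gaussian around the species linear predictor; `NA` where the species
#' count is zero (sugar can only be measured on ripe berries that are
#' present).
#'
#' @param df plot covariates (needs `ndvi`, `elevation`, `ordinal_day`,
#'   `aspect`, optional `plot_type`).
#' @param counts integer vector of the species' berry counts.
#' @param sp_sugar the species entry of [sugar_params()].
#' @param centers covariate centring values (`sugar_params()$centers`).
#' @param re per-row random-intercept offset, recycled (default 0).
#' @param sd_override replace the residual SD (e.g. 0 for a noise-free
#'   check); default `NULL`.
#' @return numeric TSS vector with `NA` where `counts == 0`.
#' @export
gen_sugar <- function(df, counts, sp_sugar, centers = sugar_params()$centers,
                      re = 0, sd_override = NULL) {
  n <- nrow(df)
  lp <- sp_sugar$mean +
    sp_sugar$ndvi * (df$ndvi - centers[["ndvi"]]) +
    sp_sugar$elevation * (df$elevation - centers[["elevation"]]) +
    sp_sugar$ordinal_day * (df$ordinal_day - centers[["ordinal_day"]]) +
    sp_sugar$aspect[as.character(df$aspect)] +
    rep_len(re, n)
  if (!is.null(df$plot_type)) {
    lp <- lp + sp_sugar$plot_type * (as.character(df$plot_type) == "Bear")
  }
  sdv <- if (is.null(sd_override)) sp_sugar$sd else sd_override
  tss <- lp + rnorm(n, 0, sdv)
  tss[counts == 0] <- NA_real_
  unname(tss)
}

## ---- movement -------------------------------------------------------------

#' Default 3-state movement parameters
#'
#' A pragmatic rest/forage/travel switching walk at 30-min fixes: state
#' transition matrix, per-state step-length ranges (rest < 25 m, forage
#' within the 25-300 m classifier band, travel > 300 m), a berry-attraction
#' weight `w` steering forage steps toward cells of high expected bilberry
#' count, and an i.i.d. fix-failure probability (default 0.08, i.e. ~92 %
#' fix success). The transition matrix is tuned to yield on the order of
#' 2 foraging bouts of >= 3 fixes per bear-day.
#'
#' @return named list of movement parameters.
#' @export
movement_params <- function() {
  list(
    transition = matrix(
      c(
        0.86, 0.07, 0.07, # from rest
        0.17, 0.73, 0.10, # from forage
        0.25, 0.10, 0.65 # from travel
      ),
      3, 3,
      byrow = TRUE,
      dimnames = list(c("rest", "forage", "travel"), c("rest", "forage", "travel"))
    ),
    rest_step = c(0, 20), forage_step = c(30, 280), travel_step = c(320, 800),
    w = 2.5, n_candidates = 8, fail_prob = 0.08
  )
}

#' Simulate one bear's GPS track
#'
#' Discrete-time 30-min state-switching walk over the landscape. Forage
#' steps draw `n_candidates` candidate headings and choose among them with
#' probability proportional to `exp(w * a)` where `a` is the standardised
#' expected bilberry count at the candidate endpoint; rest and travel
#' headings are uniform. Endpoints are reflected into the grid extent. Fix
#' failures are applied afterwards as i.i.d. Bernoulli events; failed fixes
#' keep their row with `NA` coordinates.
#'
#' @param grid a `landscape_grid`.
#' @param attract matrix (grid-shaped) of standardised expected bilberry
#'   counts; `NULL` disables attraction.
#' @param mp movement parameters ([movement_params()]).
#' @param bear_id track identifier.
#' @param start_day first ordinal day (default 219, i.e. 7 August).
#' @param n_days days of monitoring at 48 fixes/day (default 28).
#' @param year calendar year for the timestamps (default 2014).
#' @return a [as_track()] data frame.
#' @export
simulate_bear <- function(grid, attract, mp = movement_params(), bear_id = "B1",
                          start_day = 219, n_days = 28, year = 2014) {
  n <- n_days * 48L
  xmin <- grid$x0
  xmax <- grid$x0 + grid$ncol * grid$cell
  ymin <- grid$y0
  ymax <- grid$y0 + grid$nrow * grid$cell
  reflect <- function(v, lo, hi) {
    span <- hi - lo
    v <- (v - lo) %% (2 * span)
    lo + ifelse(v > span, 2 * span - v, v)
  }
  x <- numeric(n)
  y <- numeric(n)
  x[1] <- runif(1, xmin + 0.1 * (xmax - xmin), xmax - 0.1 * (xmax - xmin))
  y[1] <- runif(1, ymin + 0.1 * (ymax - ymin), ymax - 0.1 * (ymax - ymin))
  state <- sample(1:3, 1)
  states <- integer(n)
  states[1] <- state
  for (t in 2:n) {
    state <- sample(1:3, 1, prob = mp$transition[state, ])
    states[t] <- state
    rng <- switch(state,
      mp$rest_step,
      mp$forage_step,
      mp$travel_step
    )
    len <- runif(1, rng[1], rng[2])
    if (state == 2 && !is.null(attract) && mp$w > 0) {
      ang <- runif(mp$n_candidates, 0, 2 * pi)
      cx <- reflect(x[t - 1] + len * cos(ang), xmin, xmax)
      cy <- reflect(y[t - 1] + len * sin(ang), ymin, ymax)
      rc <- cell_at(grid, cx, cy)
      a <- attract[cbind(rc$row, rc$col)]
      pick <- sample.int(mp$n_candidates, 1, prob = exp(mp$w * (a - max(a))))
      x[t] <- cx[pick]
      y[t] <- cy[pick]
    } else {
      ang <- runif(1, 0, 2 * pi)
      x[t] <- reflect(x[t - 1] + len * cos(ang), xmin, xmax)
      y[t] <- reflect(y[t - 1] + len * sin(ang), ymin, ymax)
    }
  }
  valid <- runif(n) >= mp$fail_prob
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_
  t0 <- as.POSIXct(paste0(year, "-01-01 00:00:00"), tz = "UTC") +
    (start_day - 1) * 86400
  as_track(data.frame(
    bear_id = bear_id,
    timestamp = t0 + (seq_len(n) - 1) * 1800,
    x = x, y = y, valid = valid
  ))
}

#' Expected bilberry surface used for foraging attraction
#'
#' Per-cell expected count: occurrence probability times the zero-truncated
#' negative binomial mean, evaluated at a reference day, including the
#' unmodelled patchiness field. Returned standardised (mean 0, SD 1).
#'
#' @param grid a `landscape_grid`.
#' @param sp one species' entry of [berry_field_params()].
#' @param patch grid-shaped patchiness (standardised): a single matrix
#'   shared by both hurdle parts, a list with elements `occ` and `abn`, or
#'   0 for none.
#' @param day reference ordinal day (default 233, mid-season).
#' @return grid-shaped standardised matrix.
#' @export
berry_expectation <- function(grid, sp, patch = 0, day = 233) {
  df <- data.frame(
    habitat = as.vector(grid$layers$habitat),
    elevation = as.vector(grid$layers$elevation),
    ndvi = as.vector(grid$layers$ndvi),
    ordinal_day = day
  )
  if (!is.list(patch)) patch <- list(occ = patch, abn = patch)
  p_occ <- plogis(berry_lp(df, sp$occ) + sp$patch_sd_occ * as.vector(patch$occ))
  mu <- exp(pmin(berry_lp(df, sp$abn) + sp$patch_sd_abn * as.vector(patch$abn), 12))
  ev <- p_occ * ztnb_mean(mu, sp$theta)
  m <- matrix(ev, grid$nrow, grid$ncol)
  (m - mean(m)) / sd(m)
}
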