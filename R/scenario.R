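## Scenario assembly: one self-contained synthetic study (landscape +
## berry fields + bears + plots) with every generating coefficient
## recorded, reproducible from (config, seed).

#' Default scenario configuration
#'
#' The study conditions emulated by default: seven GPS-collared bears
#' (four males, three females) monitored for 28 days from ordinal day 219
#' (7 August) at 48 fixes/day, 375 random plots, ~92 % fix success, a
#' 140 x 140-cell landscape of 25-m cells with a small `other` habitat
#' share so the habitat filter is exercised, species-specific hurdle berry
#' fields and sugar models, and a bear-level random intercept (variance
#' 0.2) on the berry linear predictors.
#'
#' @return nested configuration list; edit fields and pass to
#'   [make_scenario()].
#' @export
scenario_config <- function() {
  list(
    landscape = list(
      nrow = 140, ncol = 140, cell = 25, x0 = 500000, y0 = 6740000,
      shares = c(
        bog = 0.09, clearcut = 0.08, young_forest = 0.41,
        mature_forest = 0.39, other = 0.03
      )
    ),
    berry = berry_field_params(),
    sugar = sugar_params(),
    movement = movement_params(),
    bears = data.frame(
      bear_id = paste0("B", 1:7),
      sex = c("M", "M", "M", "M", "F", "F", "F")
    ),
    start_day = 219, n_days = 28, year = 2014,
    n_random = 375,
    re_sd_occ = sqrt(0.2), re_sd_abn = sqrt(0.2),
    p_signs = 0.7,
    classifier = list(
      d_min = 25, d_max = 300, min_fixes = 3, long_run = 7,
      buffer = 200
    ),
    exclusion_sites = NULL,
    patch_scales = c(140)
  )
}

#' Generate a complete synthetic study scenario
#'
#' Runs the full generator: landscape, per-species patchiness fields,
#' bear-level random intercepts, movement tracks (forage steps attracted to
#' the expected-bilberry surface), trajectory classification, the field
#' plot protocol (digit offset, sign-based relocation), random plots, berry
#' counts, and sugar content. If `dir` is given, writes all pipeline inputs
#' as plain text (`telemetry.csv`, `grid/*.asc`, `plots.csv`,
#' `ground_truth.json`) so the scenario round-trips through the readers.
#'
#' @param config configuration list from [scenario_config()].
#' @param dir output directory, or `NULL` to skip writing.
#' @param seed master seed; the whole scenario is reproducible from
#'   `(config, seed)`.
#' @return (invisibly) list with `grid`, `patch`, `tracks`, `segments`,
#'   `positions`, `plots`, `truth`, `config`, `seed`.
#' @export
make_scenario <- function(config = scenario_config(), dir = NULL, seed = 1) {
  set.seed(seed)
  grid <- do.call(gen_landscape, config$landscape)
  species <- setdiff(names(config$berry), "centers")
  ## independent patchiness per hurdle part keeps the generated counts a
  ## true hurdle process (occurrence and positive counts independent given
  ## the modelled covariates)
  patch <- lapply(setNames(species, species), function(sp) {
    list(
      occ = smooth_field(grid$nrow, grid$ncol, scales = config$patch_scales),
      abn = smooth_field(grid$nrow, grid$ncol, scales = config$patch_scales)
    )
  })

  bears <- config$bears
  nb <- nrow(bears)
  re <- list(
    occ = lapply(setNames(species, species), function(sp) {
      setNames(rnorm(nb, 0, config$re_sd_occ), bears$bear_id)
    }),
    abn = lapply(setNames(species, species), function(sp) {
      setNames(rnorm(nb, 0, config$re_sd_abn), bears$bear_id)
    }),
    sugar = setNames(rnorm(nb, 0, config$sugar$re_sd), bears$bear_id)
  )

  attract <- berry_expectation(grid, config$berry$bilberry,
    patch$bilberry,
    day = config$start_day + config$n_days %/% 2
  )

  cls <- config$classifier
  tracks <- list()
  segments <- list()
  positions <- list()
  for (i in seq_len(nb)) {
    tr <- simulate_bear(grid, attract, config$movement,
      bear_id = bears$bear_id[i], start_day = config$start_day,
      n_days = config$n_days, year = config$year
    )
    seg <- find_foraging_segments(tr,
      d_min = cls$d_min, d_max = cls$d_max,
      min_fixes = cls$min_fixes
    )
    seg <- exclude_near_sites(seg, tr, config$exclusion_sites, radius = cls$buffer)
    tracks[[i]] <- tr
    segments[[i]] <- seg
    positions[[i]] <- choose_sample_positions(seg, tr, long_run = cls$long_run)
  }
  names(tracks) <- names(segments) <- bears$bear_id
  pos <- do.call(rbind, positions)

  ## field protocol at each sampled position
  off <- offset_plot_location(pos$x, pos$y)
  signs <- runif(nrow(pos)) < config$p_signs
  ctr <- relocate_if_signs(off$x, off$y, pos$x, pos$y, signs)
  eps <- 1e-6
  ctr$x <- pmin(pmax(ctr$x, grid$x0 + eps), grid$x0 + grid$ncol * grid$cell - eps)
  ctr$y <- pmin(pmax(ctr$y, grid$y0 + eps), grid$y0 + grid$nrow * grid$cell - eps)
  forage <- annotate_plots(ctr, grid, "Bear", pos$ordinal_day)
  forage$bear_id <- pos$bear_id
  forage$foraging_signs <- signs

  rnd <- draw_random_plots(config$n_random, grid)
  rnd_days <- sample(config$start_day:(config$start_day + config$n_days - 1),
    config$n_random,
    replace = TRUE
  )
  random <- annotate_plots(rnd, grid, "Random", rnd_days)
  ## random plots are pre-assigned to bears so the generator carries the
  ## same bear-level grouping structure the mixed models assume on both
  ## arms of the design
  random$bear_id <- sample(bears$bear_id, config$n_random, replace = TRUE)
  random$foraging_signs <- FALSE

  plots <- rbind(forage, random)
  plots$plot_id <- sprintf("P%04d", seq_len(nrow(plots)))

  rc <- cell_at(grid, plots$x, plots$y)
  for (sp in species) {
    pv_o <- patch[[sp]]$occ[cbind(rc$row, rc$col)]
    pv_a <- patch[[sp]]$abn[cbind(rc$row, rc$col)]
    spp <- config$berry[[sp]]
    cnt <- sample_plot_counts(
      plots, config$berry[sp],
      re_occ = re$occ[[sp]][plots$bear_id],
      re_abn = re$abn[[sp]][plots$bear_id],
      offset_occ = spp$patch_sd_occ * pv_o, offset_abn = spp$patch_sd_abn * pv_a
    )
    plots[[paste0("count_", sp)]] <- cnt[[1]]
    plots[[paste0("tss_", sp)]] <- round(gen_sugar(
      plots, cnt[[1]],
      config$sugar[[sp]], config$sugar$centers,
      re = re$sugar[plots$bear_id]
    ), 2)
  }

  truth <- list(
    seed = seed, berry = config$berry, sugar = config$sugar,
    movement = config$movement[c("w", "fail_prob")],
    re = re, re_sd_occ = config$re_sd_occ, re_sd_abn = config$re_sd_abn
  )

  out <- list(
    grid = grid, patch = patch, tracks = tracks, segments = segments,
    positions = pos, plots = plots, truth = truth, config = config,
    seed = seed
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_telemetry(tracks, file.path(dir, "telemetry.csv"))
    write_landscape(grid, file.path(dir, "grid"))
    write_plots(plots, file.path(dir, "plots.csv"))
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    out$paths <- list(
      telemetry = file.path(dir, "telemetry.csv"),
      grid = file.path(dir, "grid"), plots = file.path(dir, "plots.csv"),
      truth = file.path(dir, "ground_truth.json")
    )
  }
  invisible(out)
}

#' Generate a used-versus-available plot dataset from known coefficients
#'
#' The direct route for parameter-recovery studies: plot locations are
#' drawn uniformly over a landscape, annotated, assigned to bears, and
#' berry counts are drawn from hurdle coefficients that include an explicit
#' plot-type effect. The generating model coincides with the fitted model
#' (same covariates, bear-level random intercept on both parts), so
#' recovery is well-posed.
#'
#' @param params species parameter list (as [berry_field_params()], with
#'   `plot_type` coefficients set as desired).
#' @param n_bear,n_random numbers of used and available plots (defaults
#'   350 and 375).
#' @param bears bear identifiers (default 7 bears).
#' @param re_sd_occ,re_sd_abn random-intercept SDs of the generator.
#' @param grid landscape to draw covariates from; generated if `NULL`.
#' @param window ordinal-day window plots are spread over.
#' @return list with `data` (analysis-ready table), `re` (the drawn bear
#'   effects) and `grid`.
#' @export
gen_plot_dataset <- function(params = berry_field_params(),
                             n_bear = 350, n_random = 375,
                             bears = paste0("B", 1:7),
                             re_sd_occ = sqrt(0.2), re_sd_abn = sqrt(0.2),
                             grid = NULL, window = 219:247) {
  if (is.null(grid)) grid <- gen_landscape(nrow = 80, ncol = 80)
  n <- n_bear + n_random
  xy <- draw_random_plots(n, grid)
  days <- sample(window, n, replace = TRUE)
  ptype <- rep(c("Bear", "Random"), c(n_bear, n_random))
  dat <- annotate_plots(xy, grid, ptype, days)
  dat$bear_id <- sample(bears, n, replace = TRUE)

  species <- setdiff(names(params), "centers")
  re <- list(
    occ = lapply(setNames(species, species), function(sp) {
      setNames(rnorm(length(bears), 0, re_sd_occ), bears)
    }),
    abn = lapply(setNames(species, species), function(sp) {
      setNames(rnorm(length(bears), 0, re_sd_abn), bears)
    })
  )
  for (sp in species) {
    cnt <- sample_plot_counts(dat, params[sp],
      re_occ = re$occ[[sp]][dat$bear_id],
      re_abn = re$abn[[sp]][dat$bear_id]
    )
    dat[[paste0("count_", sp)]] <- cnt[[1]]
  }
  dat$plot_type <- factor(dat$plot_type, levels = c("Random", "Bear"))
  dat$habitat <- factor(dat$habitat,
    levels = intersect(HABITAT_LEVELS, unique(dat$habitat))
  )
  dat$aspect <- factor(dat$aspect, levels = ASPECT_LEVELS)
  dat$bear_id <- factor(dat$bear_id)
  list(data = dat, re = re, grid = grid)
}

#' Generating coefficients as a named vector matching model coefficients
#'
#' Maps one part of a species' generator parameters to the coefficient
#' names of the fitted model (`(Intercept)`, `plot_typeBear`,
#' `habitat<level>`, numeric covariates), for parameter-recovery
#' comparisons.
#'
#' @param sp_part `params$<species>$occ` or `params$<species>$abn`.
#' @param habitat_levels habitat factor levels of the fitted data (first =
#'   reference).
#' @return named numeric vector of true coefficients.
#' @export
truth_coefs <- function(sp_part, habitat_levels = c(
                          "bog", "clearcut",
                          "mature_forest", "young_forest"
                        )) {
  hab <- sp_part$habitat[habitat_levels[-1]] - sp_part$habitat[habitat_levels[1]]
  c(
    `(Intercept)` = sp_part$intercept + unname(sp_part$habitat[habitat_levels[1]]),
    plot_typeBear = sp_part$plot_type,
    setNames(unname(hab), paste0("habitat", habitat_levels[-1])),
    elevation = sp_part$elevation, ndvi = sp_part$ndvi,
    ordinal_day = sp_part$ordinal_day
  )
}
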