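## Pipeline: classify -> sample -> assemble -> fit the model families ->
## export report tables shaped like the analyses of a used-vs-available
## berry foraging study (hurdle selection models per species, seasonal
## shift model, sugar models, descriptive summaries).

#' Coefficient table of a fit
#'
#' @param fit a `glmm_agq` fit.
#' @return data frame with `term`, `estimate`, `se`, `z`, `p`.
#' @export
coef_table <- function(fit) {
  b <- coef(fit)
  se <- if (is.null(fit$se)) rep(NA_real_, length(b)) else fit$se
  z <- b / se
  data.frame(
    term = names(b), estimate = unname(b), se = unname(se),
    z = unname(z), p = unname(2 * pnorm(-abs(z))),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Habitat-averaged plot-type effect of a selection model
#'
#' The used-versus-available effect of a fitted occurrence or abundance
#' model on the link scale, averaged over habitats: the mean difference
#' between the linear predictors of a bear foraging plot and a random plot
#' across habitat levels, holding the numeric covariates at their means.
#' This summarises selection in one number even when the final model
#' carries a plot type x habitat interaction (where the main-effect
#' coefficient alone refers only to the reference habitat). `NA` if no
#' plot-type term survived selection.
#'
#' @param fit a `glmm_agq` final model.
#' @param data the analysis table (for habitat levels and covariate means).
#' @return link-scale effect (log-odds or log-count difference), or `NA`.
#' @export
plot_type_effect <- function(fit, data) {
  kept <- attr(terms(fit$fixed_formula), "term.labels")
  if (!any(grepl("plot_type", kept, fixed = TRUE))) {
    return(NA_real_)
  }
  nd <- expand.grid(
    habitat = levels(droplevels(data$habitat)),
    plot_type = c("Random", "Bear"), stringsAsFactors = FALSE
  )
  for (v in c("elevation", "ndvi", "slope", "ordinal_day")) {
    nd[[v]] <- mean(data[[v]])
  }
  nd$aspect <- levels(data$aspect)[1]
  eta <- predict(fit, nd, type = "link")
  mean(eta[nd$plot_type == "Bear"]) - mean(eta[nd$plot_type == "Random"])
}

## full fixed-effect term set after the VIF screen
selection_terms <- function(plots, vif_cutoff = 3) {
  numerics <- c("elevation", "ndvi", "slope", "ordinal_day")
  vs <- vif_screen(plots[numerics], cutoff = vif_cutoff)
  terms <- c(
    "plot_type", "habitat", vs$retained, "aspect",
    "plot_type:habitat",
    if ("ordinal_day" %in% vs$retained) "plot_type:ordinal_day"
  )
  list(terms = terms, vif = vs)
}

#' Used-versus-available hurdle analysis for one berry species
#'
#' The full protocol for one species: VIF screen of the numeric predictors
#' (cut-off 3), a full model per hurdle part containing plot type, habitat,
#' the retained landscape characteristics, sampling date, a plot type x
#' habitat and a plot type x date interaction; likelihood-ratio backward
#' selection per part; single-step adjusted pairwise contrasts for the
#' surviving habitat(-interaction) term; and population-level prediction
#' curves over the date window at mean elevation.
#'
#' @param plots assembled analysis table ([assemble_plot_data()]).
#' @param species `"bilberry"` or `"lingonberry"`.
#' @param alpha selection threshold (default 0.05).
#' @param vif_cutoff collinearity cut-off (default 3).
#' @param nAGQ quadrature nodes (default 10).
#' @param mc_draws,mc_seed Monte-Carlo settings for the contrast
#'   adjustment.
#' @param min_positive minimum positive counts for the abundance part.
#' @return list with `occurrence` and `abundance` sub-lists (`selection`,
#'   `fit`, `coefficients`, `contrasts`), `vif`, and `predictions`.
#' @export
run_berry_selection <- function(plots, species, alpha = 0.05, vif_cutoff = 3,
                                nAGQ = 10, mc_draws = 1e5, mc_seed = 1,
                                min_positive = 30) {
  cnt_col <- paste0("count_", species)
  if (!cnt_col %in% names(plots)) stop("no column ", cnt_col)
  st <- selection_terms(plots, vif_cutoff)

  run_part <- function(dat, resp, family) {
    dat <- droplevels(dat)
    f <- reformulate(c(st$terms, "(1 | bear_id)"), response = resp)
    full <- glmm_agq(f, dat, family = family, nAGQ = nAGQ, hessian = FALSE)
    sel <- backward_select(full, alpha = alpha)
    kept <- attr(terms(sel$fit$fixed_formula), "term.labels")
    ctr <- NULL
    ctr_term <- if ("plot_type:habitat" %in% kept) {
      "plot_type:habitat"
    } else if ("habitat" %in% kept) "habitat"
    if (!is.null(ctr_term)) {
      ctr <- pairwise_contrasts(sel$fit, ctr_term,
        ndraws = mc_draws,
        seed = mc_seed
      )
    }
    list(
      selection = sel, fit = sel$fit, coefficients = coef_table(sel$fit),
      contrasts = ctr, contrast_term = ctr_term
    )
  }

  occ_dat <- plots
  occ_dat$occ <- as.numeric(plots[[cnt_col]] >= 1)
  occ <- run_part(occ_dat, "occ", "binomial")

  pos <- plots[plots[[cnt_col]] >= 1, , drop = FALSE]
  abn <- NULL
  if (nrow(pos) >= min_positive) {
    pos$cnt <- pos[[cnt_col]]
    abn <- run_part(pos, "cnt", "truncnbinom")
  } else {
    warning(
      "only ", nrow(pos), " positive ", species,
      " plots; abundance part skipped"
    )
  }

  ## population-level prediction curves over the date window
  days <- seq(min(plots$ordinal_day), max(plots$ordinal_day))
  nd <- expand.grid(
    ordinal_day = days,
    plot_type = levels(plots$plot_type),
    habitat = levels(plots$habitat), stringsAsFactors = FALSE
  )
  nd$elevation <- mean(plots$elevation)
  nd$ndvi <- mean(plots$ndvi)
  nd$slope <- mean(plots$slope)
  nd$aspect <- levels(plots$aspect)[1]
  preds <- list(occurrence = predict_population(occ$fit, nd))
  if (!is.null(abn)) preds$abundance <- predict_population(abn$fit, nd)

  list(
    species = species, vif = st$vif, occurrence = occ, abundance = abn,
    predictions = preds
  )
}

#' Seasonal shift in berry abundance at foraging locations
#'
#' Long-format model of ripe-berry counts at bear foraging plots in the two
#' productive habitats (clearcut, mature forest), two rows per plot (one
#' per species), with a species x date x habitat three-way interaction and
#' a plot-level random intercept; negative binomial by default (the counts
#' are overdispersed), zero-truncated as a config option. Backward
#' selection reports which interactions survive.
#'
#' @param plots assembled analysis table.
#' @param habitats habitats retained (default clearcut, mature forest;
#'   clearcut is the reference).
#' @param truncated use the zero-truncated family on positive counts only.
#' @param alpha selection threshold.
#' @param nAGQ quadrature nodes (default 5; many small groups).
#' @return list with `selection`, `fit`, `coefficients`, `data`.
#' @export
run_seasonal_shift <- function(plots, habitats = c("clearcut", "mature_forest"),
                               truncated = FALSE, alpha = 0.05, nAGQ = 5) {
  d <- plots[plots$plot_type == "Bear" & plots$habitat %in% habitats, ,
    drop = FALSE
  ]
  if (!nrow(d)) stop("no foraging plots in the selected habitats")
  long <- rbind(
    data.frame(
      plot_id = d$plot_id, species = "bilberry", count = d$count_bilberry,
      ordinal_day = d$ordinal_day, habitat = as.character(d$habitat)
    ),
    data.frame(
      plot_id = d$plot_id, species = "lingonberry", count = d$count_lingonberry,
      ordinal_day = d$ordinal_day, habitat = as.character(d$habitat)
    )
  )
  long$species <- factor(long$species, levels = c("bilberry", "lingonberry"))
  long$habitat <- factor(long$habitat, levels = habitats)
  family <- "nbinom"
  if (truncated) {
    long <- long[long$count >= 1, , drop = FALSE]
    family <- "truncnbinom"
  }
  full <- glmm_agq(
    count ~ species * ordinal_day * habitat + (1 | plot_id),
    long,
    family = family, nAGQ = nAGQ, hessian = FALSE
  )
  sel <- backward_select(full, alpha = alpha)
  list(
    selection = sel, fit = sel$fit, coefficients = coef_table(sel$fit),
    data = long
  )
}

#' Sugar-content (TSS) analysis
#'
#' Per-species linear mixed model of total soluble solids as a function of
#' the full predictor set (plot type, habitat, sampling date, aspect,
#' slope, elevation, NDVI) with a bear-level random intercept, reduced by
#' likelihood-ratio backward selection; plus the Welch t-test between the
#' species' TSS means.
#'
#' @param plots assembled analysis table with `tss_*` columns.
#' @param species species to model (default bilberry and lingonberry).
#' @param alpha selection threshold.
#' @param nAGQ quadrature nodes (Gaussian integrates exactly; kept for
#'   interface symmetry).
#' @param min_n minimum TSS observations per species (default 30).
#' @return list with one entry per species (`selection`, `fit`,
#'   `coefficients`, `n`) and `t_tests` between species.
#' @export
run_sugar_analysis <- function(plots, species = c("bilberry", "lingonberry"),
                               alpha = 0.05, nAGQ = 5, min_n = 30) {
  out <- list()
  for (sp in species) {
    col <- paste0("tss_", sp)
    d <- plots[!is.na(plots[[col]]), , drop = FALSE]
    if (nrow(d) < min_n) {
      warning("only ", nrow(d), " TSS values for ", sp, "; skipped")
      next
    }
    d$tss <- d[[col]]
    ## clearcut as sugar-model reference habitat
    d$habitat <- stats::relevel(droplevels(d$habitat), ref = intersect(
      c("clearcut", levels(droplevels(d$habitat))), levels(droplevels(d$habitat))
    )[1])
    full <- glmm_agq(
      tss ~ plot_type + habitat + ordinal_day + aspect + slope +
        elevation + ndvi + (1 | bear_id),
      d,
      family = "gaussian", nAGQ = nAGQ, hessian = FALSE
    )
    sel <- backward_select(full, alpha = alpha)
    out[[sp]] <- list(
      selection = sel, fit = sel$fit,
      coefficients = coef_table(sel$fit), n = nrow(d)
    )
  }
  tt <- list()
  cmb <- utils::combn(species, 2)
  for (j in seq_len(ncol(cmb))) {
    a <- plots[[paste0("tss_", cmb[1, j])]]
    b <- plots[[paste0("tss_", cmb[2, j])]]
    tt[[paste(cmb[1, j], "vs", cmb[2, j])]] <-
      welch_t(a[!is.na(a)], b[!is.na(b)])
  }
  out$t_tests <- tt
  out
}

#' Descriptive summaries of a classified, assembled study
#'
#' @param segments combined segment table (all bears).
#' @param plots assembled analysis table.
#' @param tracks named list of tracks (for fix success).
#' @return nested list of summary statistics.
#' @export
descriptive_summaries <- function(segments, plots, tracks) {
  fx <- vapply(tracks, fix_success_rate, numeric(1))
  forage <- plots[plots$plot_type == "Bear", , drop = FALSE]
  occ_pct <- function(cnt, rows) 100 * mean(cnt[rows] >= 1)
  species <- c("bilberry", "lingonberry", "crowberry")
  occ <- lapply(setNames(species, species), function(sp) {
    cnt <- plots[[paste0("count_", sp)]]
    list(
      foraging = occ_pct(cnt, plots$plot_type == "Bear"),
      random = occ_pct(cnt, plots$plot_type == "Random")
    )
  })
  dens <- lapply(setNames(species, species), function(sp) {
    cnt <- plots[[paste0("count_", sp)]]
    if (any(cnt >= 1)) mean(cnt[cnt >= 1]) else NA_real_
  })
  tss <- lapply(setNames(species, species), function(sp) {
    v <- plots[[paste0("tss_", sp)]]
    if (is.null(v)) {
      return(NULL)
    }
    list(mean = mean(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE), n = sum(!is.na(v)))
  })
  list(
    n_segments = nrow(segments),
    mean_fixes_per_segment = mean(segments$n_fixes),
    fix_range = range(segments$n_fixes),
    fix_success = mean(fx), fix_success_by_bear = fx,
    n_plots = c(
      foraging = sum(plots$plot_type == "Bear"),
      random = sum(plots$plot_type == "Random")
    ),
    occurrence_pct = occ,
    pct_neither = 100 * mean(forage$count_bilberry == 0 &
      forage$count_lingonberry == 0),
    density_occupied = dens,
    tss = tss,
    count_correlation = pearson_cor(
      plots$count_bilberry,
      plots$count_lingonberry
    )
  )
}

#' Run the full analysis pipeline on a scenario directory
#'
#' Reads the scenario inputs (`telemetry.csv`, `plots.csv`), re-classifies
#' foraging segments, assembles the used-versus-available table (seeded
#' random-plot bear assignment), fits the per-species hurdle selection
#' models, the seasonal-shift model and the sugar models, computes
#' descriptive summaries, and (optionally) writes the report tables:
#' `coefficients_*.csv`, `selection_*.csv`, `contrasts_*.csv`,
#' `predictions_*.csv`, `summary.json` and `run_log.txt`. All randomness
#' (bear assignment, contrast adjustment) flows from `seed`, so two runs
#' with equal inputs and seed produce identical report directories.
#'
#' @param scenario_dir directory written by [make_scenario()].
#' @param out_dir report directory, or `NULL` to skip writing.
#' @param seed master seed for the analysis-side randomness.
#' @param alpha significance threshold (default 0.05).
#' @param nAGQ quadrature nodes for the selection models.
#' @param mc_draws Monte-Carlo draws for contrast adjustment.
#' @param classifier classifier settings (`d_min`, `d_max`, `min_fixes`,
#'   `long_run`, `buffer`).
#' @param sites optional attractant-site table for the exclusion buffer.
#' @return (invisibly) the full report list.
#' @export
run_analysis <- function(scenario_dir, out_dir = NULL, seed = 1, alpha = 0.05,
                         nAGQ = 10, mc_draws = 1e5,
                         classifier = list(
                           d_min = 25, d_max = 300,
                           min_fixes = 3, long_run = 7, buffer = 200
                         ),
                         sites = NULL) {
  tele_path <- file.path(scenario_dir, "telemetry.csv")
  plot_path <- file.path(scenario_dir, "plots.csv")
  tracks <- read_telemetry(tele_path)
  plots_raw <- read_plots(plot_path)

  set.seed(seed)
  segs <- lapply(tracks, function(tr) {
    s <- find_foraging_segments(tr,
      d_min = classifier$d_min,
      d_max = classifier$d_max, min_fixes = classifier$min_fixes
    )
    exclude_near_sites(s, tr, sites, radius = classifier$buffer)
  })
  segments <- do.call(rbind, segs)
  rownames(segments) <- NULL

  forage <- plots_raw[plots_raw$plot_type == "Bear", , drop = FALSE]
  random <- plots_raw[plots_raw$plot_type == "Random", , drop = FALSE]
  plots <- assemble_plot_data(forage, random)

  bil <- run_berry_selection(plots, "bilberry",
    alpha = alpha, nAGQ = nAGQ,
    mc_draws = mc_draws, mc_seed = seed
  )
  lin <- run_berry_selection(plots, "lingonberry",
    alpha = alpha, nAGQ = nAGQ,
    mc_draws = mc_draws, mc_seed = seed
  )
  seasonal <- run_seasonal_shift(plots, alpha = alpha)
  sugar <- run_sugar_analysis(plots, alpha = alpha)
  summaries <- descriptive_summaries(segments, plots, tracks)

  report <- list(
    bilberry = bil, lingonberry = lin, seasonal = seasonal,
    sugar = sugar, summaries = summaries, seed = seed,
    n_dropped = attr(plots, "n_dropped")
  )
  if (!is.null(out_dir)) write_report(report, out_dir, tele_path, plot_path)
  invisible(report)
}

## serialise the report tables; everything deterministic given the inputs
write_report <- function(report, out_dir, tele_path, plot_path) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  put <- function(df, name) {
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  for (sp in c("bilberry", "lingonberry")) {
    r <- report[[sp]]
    for (part in c("occurrence", "abundance")) {
      pr <- r[[part]]
      if (is.null(pr)) next
      put(pr$coefficients, sprintf("coefficients_%s_%s.csv", sp, part))
      put(pr$selection$trace, sprintf("selection_%s_%s.csv", sp, part))
      if (!is.null(pr$contrasts)) {
        put(
          as.data.frame(pr$contrasts),
          sprintf("contrasts_%s_%s.csv", sp, part)
        )
      }
      if (!is.null(report[[sp]]$predictions[[part]])) {
        put(
          report[[sp]]$predictions[[part]],
          sprintf("predictions_%s_%s.csv", sp, part)
        )
      }
    }
  }
  put(report$seasonal$coefficients, "coefficients_seasonal.csv")
  put(report$seasonal$selection$trace, "selection_seasonal.csv")
  for (sp in intersect(c("bilberry", "lingonberry"), names(report$sugar))) {
    put(report$sugar[[sp]]$coefficients, sprintf("coefficients_sugar_%s.csv", sp))
    put(report$sugar[[sp]]$selection$trace, sprintf("selection_sugar_%s.csv", sp))
  }
  jsonlite::write_json(
    list(
      summaries = report$summaries, t_tests = report$sugar$t_tests,
      n_dropped = as.list(report$n_dropped), seed = report$seed
    ),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
  )
  writeLines(
    c(
      paste("seed:", report$seed),
      paste("telemetry_md5:", unname(tools::md5sum(tele_path))),
      paste("plots_md5:", unname(tools::md5sum(plot_path)))
    ),
    file.path(out_dir, "run_log.txt")
  )
  invisible(out_dir)
}
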