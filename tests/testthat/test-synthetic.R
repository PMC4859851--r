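# Synthetic study generator: landscape, berry field, sugar, movement,
# scenario reproducibility

test_that("landscape shares hit their targets and layers stay in range", {
  set.seed(111)
  g <- gen_landscape(nrow = 100, ncol = 100)
  sh <- prop.table(table(g$layers$habitat))
  expect_equal(unname(sh[["clearcut"]]), 0.08, tolerance = 0.015)
  expect_equal(unname(sh[["bog"]]), 0.10, tolerance = 0.015)
  expect_equal(unname(sh[["young_forest"]]), 0.42, tolerance = 0.015)
  expect_equal(unname(sh[["mature_forest"]]), 0.40, tolerance = 0.015)
  expect_true(all(g$layers$elevation >= 200 & g$layers$elevation <= 600))
  expect_true(all(g$layers$ndvi >= -1 & g$layers$ndvi <= 0.86))
  expect_true(all(g$layers$slope >= 0 & g$layers$slope <= 77))
  expect_true(all(g$layers$aspect %in% c("N", "E", "S", "W")))
  expect_error(gen_landscape(shares = c(bog = 0.5, clearcut = 0.1)), "sum to 1")
})

test_that("landscape generation is seed-deterministic; single class is uniform", {
  set.seed(7)
  a <- gen_landscape(nrow = 30, ncol = 30)
  set.seed(7)
  b <- gen_landscape(nrow = 30, ncol = 30)
  expect_identical(a, b)
  set.seed(8)
  u <- gen_landscape(nrow = 20, ncol = 20, shares = c(bog = 1))
  expect_true(all(u$layers$habitat == "bog"))
})

test_that("berry counts follow the hurdle structure with the truncated mean", {
  set.seed(112)
  df <- data.frame(
    habitat = "mature_forest", elevation = 400, ndvi = 0.4,
    ordinal_day = 233
  )[rep(1, 3e4), ]
  params <- berry_field_params()["bilberry"]
  cnt <- sample_plot_counts(df, params)$count_bilberry
  pp <- params$bilberry
  lp_occ <- pp$occ$intercept + pp$occ$habitat[["mature_forest"]] +
    pp$occ$elevation * 400 + pp$occ$ordinal_day * 233
  lp_abn <- pp$abn$intercept + pp$abn$habitat[["mature_forest"]] +
    pp$abn$ordinal_day * 233
  expect_equal(mean(cnt > 0), plogis(lp_occ), tolerance = 0.02)
  expect_equal(mean(cnt[cnt > 0]),
    bearberry:::ztnb_mean(exp(lp_abn), pp$theta),
    tolerance = 0.03
  )
  ## occurrence pushed to -inf silences the species entirely
  off <- params
  off$bilberry$occ$intercept <- -50
  expect_true(all(sample_plot_counts(df[1:1000, ], off)$count_bilberry == 0))
})

test_that("species counts are generated independently (near-zero correlation)", {
  set.seed(113)
  sc <- make_scenario(seed = 113)
  ct <- pearson_cor(sc$plots$count_bilberry, sc$plots$count_lingonberry)
  expect_lt(abs(ct$r), 0.15)
})

test_that("sugar content: exact at zero noise, species means near defaults", {
  df <- data.frame(
    ndvi = 0.44, elevation = 400, ordinal_day = 233,
    aspect = "N", plot_type = "Random"
  )
  sp <- sugar_params()
  tss <- gen_sugar(df, counts = 1, sp$bilberry, sp$centers, sd_override = 0)
  expect_equal(tss, 8.48 + sp$bilberry$aspect[["N"]])
  df2 <- rbind(df, df)
  df2$plot_type <- c("Random", "Bear")
  tss_lb <- gen_sugar(df2, c(1, 1), sp$lingonberry, sp$centers,
    sd_override = 0
  )
  expect_equal(tss_lb, c(12.04, 12.04 + 0.579))
  ## scenario-level means stay near the configured species means
  set.seed(114)
  sc <- make_scenario(seed = 114)
  expect_equal(mean(sc$plots$tss_bilberry, na.rm = TRUE), 8.48, tolerance = 0.35)
  expect_equal(mean(sc$plots$tss_lingonberry, na.rm = TRUE), 12.04, tolerance = 0.45)
  expect_equal(sd(sc$plots$tss_bilberry, na.rm = TRUE), 1.42, tolerance = 0.35)
  ## sugar only where the species occurs
  expect_true(all(is.na(sc$plots$tss_bilberry[sc$plots$count_bilberry == 0])))
})

test_that("movement: attraction steers foraging to berry-rich cells, null does not", {
  set.seed(115)
  grid <- make_test_grid(seed = 115, nrow = 80, ncol = 80)
  patch <- bearberry:::smooth_field(80, 80, scales = 40)
  attract <- berry_expectation(grid, berry_field_params()$bilberry, patch)
  mp <- movement_params()
  mean_attr_at_forage <- function(w) {
    mp$w <- w
    vals <- unlist(lapply(1:3, function(i) {
      tr <- simulate_bear(grid, attract, mp, n_days = 14, bear_id = paste0("B", i))
      seg <- find_foraging_segments(tr)
      pos <- choose_sample_positions(seg, tr)
      if (!nrow(pos)) {
        return(numeric(0))
      }
      rc <- cell_at(grid, pos$x, pos$y)
      attract[cbind(rc$row, rc$col)]
    }))
    mean(vals)
  }
  a0 <- mean_attr_at_forage(0)
  a3 <- mean_attr_at_forage(3)
  expect_lt(abs(a0), 0.35) # null attraction: ~landscape mean (0)
  expect_gt(a3, a0 + 0.3) # selection emerges with attraction
})

test_that("step-length regimes respect the classifier band by state", {
  set.seed(116)
  grid <- make_test_grid(seed = 116, nrow = 40, ncol = 40)
  tr <- simulate_bear(grid, NULL, movement_params(), n_days = 7)
  seg <- find_foraging_segments(tr)
  expect_gt(nrow(seg), 3) # foraging bouts occur
  steps <- compute_steps(tr)
  for (i in seq_len(nrow(seg))) {
    s <- steps[seg$start[i]:(seg$end[i] - 1)]
    expect_true(all(s >= 25 & s <= 300))
  }
})

test_that("scenarios are byte-identical under one seed and round-trip", {
  d1 <- file.path(tempdir(), "scA")
  d2 <- file.path(tempdir(), "scB")
  unlink(c(d1, d2), recursive = TRUE)
  cfg <- scenario_config()
  cfg$landscape$nrow <- cfg$landscape$ncol <- 60
  cfg$n_days <- 6
  cfg$n_random <- 60
  make_scenario(cfg, dir = d1, seed = 99)
  make_scenario(cfg, dir = d2, seed = 99)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      label = f
    )
  }
  ## ground truth records the generating coefficients faithfully
  gt <- jsonlite::read_json(file.path(d1, "ground_truth.json"),
    simplifyVector = TRUE
  )
  expect_equal(
    gt$berry$bilberry$occ$intercept,
    berry_field_params()$bilberry$occ$intercept
  )
  expect_equal(gt$seed, 99)
  ## the telemetry and plots round-trip through the readers
  tracks <- read_telemetry(file.path(d1, "telemetry.csv"))
  expect_length(tracks, 7)
  expect_true(all(sapply(tracks, nrow) == 6 * 48))
  plots <- read_plots(file.path(d1, "plots.csv"))
  expect_true(all(c("count_bilberry", "tss_lingonberry") %in% names(plots)))
  grid <- read_landscape(file.path(d1, "grid"))
  expect_equal(grid$nrow, 60)
})

test_that("direct plot-dataset generator exposes its ground truth", {
  set.seed(117)
  g <- gen_plot_dataset(recovery_params(), n_bear = 200, n_random = 200)
  expect_equal(nrow(g$data), 400)
  expect_setequal(levels(g$data$plot_type), c("Random", "Bear"))
  tc <- truth_coefs(recovery_params()$bilberry$occ)
  expect_equal(tc[["plot_typeBear"]], 2.297)
  expect_equal(tc[["habitatmature_forest"]], 2.59)
  expect_equal(tc[["ordinal_day"]], -0.022)
})
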