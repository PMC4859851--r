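# Trajectory classification: step series, foraging segments, sampling
# positions, exclusion buffer, fix success.

track_from_xy <- function(x, y, valid = rep(TRUE, length(x))) {
  as_track(data.frame(
    bear_id = "B1",
    timestamp = as.POSIXct("2014-08-07", tz = "UTC") + (seq_along(x) - 1) * 1800,
    x = ifelse(valid, x, NA), y = ifelse(valid, y, NA), valid = valid
  ))
}

## place fixes so that consecutive distances equal `steps` (along x)
track_from_steps <- function(steps) {
  track_from_xy(cumsum(c(0, steps)), rep(0, length(steps) + 1))
}

test_that("step lengths are Euclidean with NA around failed fixes", {
  expect_equal(compute_steps(track_from_xy(c(0, 3), c(0, 4))), 5)
  tr <- track_from_xy(c(0, 10, 20), c(0, 0, 0), valid = c(TRUE, FALSE, TRUE))
  expect_equal(compute_steps(tr), c(NA_real_, NA_real_))
  expect_length(compute_steps(track_from_xy(5, 5)), 0)
  set.seed(4)
  x <- runif(100, 0, 1e3)
  y <- runif(100, 0, 1e3)
  d <- sapply(2:100, function(i) sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2))
  expect_equal(compute_steps(track_from_xy(x, y)), d)
})

test_that("segment rule: three fixes with in-band steps qualify, slow runs do not", {
  s <- find_foraging_segments(track_from_steps(c(30, 40)))
  expect_equal(nrow(s), 1)
  expect_equal(s$n_fixes, 3)
  expect_equal(nrow(find_foraging_segments(track_from_steps(c(10, 10, 10)))), 0)
  ## boundary values are inclusive
  expect_equal(nrow(find_foraging_segments(track_from_steps(c(25, 300)))), 1)
  expect_equal(nrow(find_foraging_segments(track_from_steps(c(24.9, 300.1)))), 0)
})

test_that("classifier equals brute-force enumeration of maximal windows", {
  set.seed(11)
  for (i in 1:200) {
    tr <- make_random_track(n = sample(10:60, 1), p_invalid = runif(1, 0, 0.25))
    got <- find_foraging_segments(tr)
    want <- brute_segments(compute_steps(tr))
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("an injected failed fix splits or shortens segments, never lengthens", {
  set.seed(21)
  for (i in 1:50) {
    tr <- make_random_track(n = 40, p_invalid = 0)
    base <- find_foraging_segments(tr)
    j <- sample(40, 1)
    tr2 <- tr
    tr2$valid[j] <- FALSE
    tr2$x[j] <- NA
    tr2$y[j] <- NA
    pert <- find_foraging_segments(tr2)
    expect_lte(sum(pert$n_fixes), sum(base$n_fixes))
  }
})

test_that("widening the step band never shrinks the classified fix total", {
  set.seed(31)
  for (i in 1:30) {
    tr <- make_random_track(n = 50, p_invalid = 0.1)
    narrow <- find_foraging_segments(tr, d_min = 25, d_max = 300)
    wide <- find_foraging_segments(tr, d_min = 10, d_max = 400)
    expect_gte(sum(wide$n_fixes), sum(narrow$n_fixes))
  }
})

test_that("sampling positions: second fix always, second-to-last from 7 fixes", {
  for (n_steps in c(2, 4, 6, 9)) {
    tr <- track_from_steps(rep(50, n_steps))
    seg <- find_foraging_segments(tr)
    pos <- choose_sample_positions(seg, tr)
    n_fixes <- n_steps + 1
    if (n_fixes >= 7) {
      expect_equal(pos$fix, c(2L, n_fixes - 1L))
      expect_equal(pos$slot, c("second", "second_to_last"))
    } else {
      expect_equal(pos$fix, 2L)
      expect_equal(pos$slot, "second")
    }
    expect_false(anyDuplicated(pos$fix) > 0)
    expect_equal(unique(pos$ordinal_day), 219L) # 7 Aug 2014
  }
})

test_that("exclusion buffer removes whole segments near sites, inclusively", {
  tr <- track_from_steps(rep(50, 4))
  seg <- find_foraging_segments(tr)
  expect_equal(nrow(exclude_near_sites(seg, tr, data.frame(x = 0, y = 150))), 0)
  expect_equal(nrow(exclude_near_sites(seg, tr, data.frame(x = 0, y = 200))), 0)
  expect_equal(nrow(exclude_near_sites(seg, tr, data.frame(x = 0, y = 201))), 1)
  expect_identical(exclude_near_sites(seg, tr, NULL), seg)
  expect_identical(exclude_near_sites(seg, tr, data.frame(x = numeric(0), y = numeric(0))), seg)
  ## random segments/sites against an all-pairs distance check
  set.seed(41)
  for (i in 1:20) {
    tr <- make_random_track(n = 40, p_invalid = 0.05)
    seg <- find_foraging_segments(tr)
    if (!nrow(seg)) next
    sites <- data.frame(x = runif(3, -500, 500), y = runif(3, -500, 500))
    got <- exclude_near_sites(seg, tr, sites, radius = 200)
    keep <- sapply(seq_len(nrow(seg)), function(k) {
      idx <- seg$start[k]:seg$end[k]
      dmin <- min(sqrt(outer(tr$x[idx], sites$x, "-")^2 +
        outer(tr$y[idx], sites$y, "-")^2))
      dmin > 200
    })
    expect_equal(got$start, seg$start[keep])
  }
})

test_that("fix success is the valid share of scheduled fixes", {
  tr <- make_random_track(n = 48, p_invalid = 0)
  tr$valid[1:4] <- FALSE
  expect_equal(fix_success_rate(tr), 44 / 48)
  expect_equal(fix_success_rate(make_random_track(10, 0)), 1)
  expect_error(fix_success_rate(make_random_track(5, 0)[0, ]), "empty")
})

test_that("simulated fix failures reproduce the scheduled success rate", {
  set.seed(51)
  grid <- make_test_grid()
  mp <- movement_params()
  rates <- replicate(10, {
    tr <- simulate_bear(grid, NULL, mp, n_days = 28)
    fix_success_rate(tr)
  })
  expect_equal(mean(rates), 0.92, tolerance = 0.01)
})

test_that("track validation catches duplicates and unordered input", {
  d <- data.frame(
    bear_id = "B1",
    timestamp = as.POSIXct("2014-08-07", tz = "UTC") + c(3600, 0, 1800),
    x = 1:3, y = 1:3, valid = TRUE
  )
  tr <- as_track(d) # sorted
  expect_equal(tr$x, c(2L, 3L, 1L))
  d2 <- d
  d2$timestamp[2] <- d2$timestamp[1]
  expect_error(as_track(d2), "duplicate")
})
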