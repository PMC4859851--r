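# Independent oracles and fixture generators used across tests. The
# oracles deliberately use naive enumeration / direct arithmetic, never the
# package's own code paths.

## brute-force enumeration of all maximal windows whose every step lies in
## [d_min, d_max]: O(n^2) over fix-index windows
brute_segments <- function(steps, d_min = 25, d_max = 300, min_fixes = 3) {
  n <- length(steps) + 1 # number of fixes
  ok <- !is.na(steps) & steps >= d_min & steps <= d_max
  out <- NULL
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b - a + 1 < min_fixes) next
      if (!all(ok[a:(b - 1)])) next
      maximal <- (a == 1 || !ok[a - 1]) && (b == n || !ok[b])
      if (maximal) out <- rbind(out, c(start = a, end = b))
    }
  }
  if (is.null(out)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  as.data.frame(out)
}

## random single-bear track mixing the three step regimes with failed fixes
make_random_track <- function(n = 40, p_invalid = 0.1, bear_id = "T1") {
  regime <- sample(1:3, n - 1, replace = TRUE)
  len <- c(runif(n - 1)) * c(24, 275, 400)[regime] + c(0, 25, 301)[regime]
  ang <- runif(n - 1, 0, 2 * pi)
  x <- cumsum(c(0, len * cos(ang)))
  y <- cumsum(c(0, len * sin(ang)))
  valid <- runif(n) >= p_invalid
  x[!valid] <- NA
  y[!valid] <- NA
  as_track(data.frame(
    bear_id = bear_id,
    timestamp = as.POSIXct("2014-08-07", tz = "UTC") + (seq_len(n) - 1) * 1800,
    x = x, y = y, valid = valid
  ))
}

## small landscape reused by several tests (generation is cheap)
make_test_grid <- function(seed = 123, nrow = 60, ncol = 60) {
  set.seed(seed)
  gen_landscape(nrow = nrow, ncol = ncol)
}

## bilberry-like generator parameters with an explicit plot-type effect,
## used for parameter-recovery checks (generating model = fitted model)
recovery_params <- function() {
  p <- berry_field_params()["bilberry"]
  p$bilberry$occ$plot_type <- 2.297
  p$bilberry$abn$plot_type <- 0.828
  p
}
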