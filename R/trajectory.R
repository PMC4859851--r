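## Trajectory module: turn 30-min GPS fix streams into berry-foraging
## segments and the positions at which plots are sampled.
##
## A track is a data frame for ONE bear with columns bear_id, timestamp
## (POSIXct, UTC, on the 30-min schedule), x, y (projected metres) and
## valid (logical; FALSE = failed fix, coordinates NA). Failed fixes are
## kept as rows so that gaps are explicit, never silently dropped.

#' Validate and order a single-bear GPS track
#'
#' @param df data frame with columns `bear_id`, `timestamp`, `x`, `y`,
#'   `valid`.
#' @return the track, time-ordered, with class `c("bear_track",
#'   "data.frame")`.
#' @export
as_track <- function(df) {
  need <- c("bear_id", "timestamp", "x", "y", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("track is missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(df$bear_id)) > 1) stop("a track holds a single bear")
  df$valid <- as.logical(df$valid)
  df <- df[order(df$timestamp), , drop = FALSE]
  if (anyDuplicated(df$timestamp)) stop("duplicate timestamps in track")
  if (any(df$valid & (!is.finite(df$x) | !is.finite(df$y)))) {
    stop("valid fixes must have finite coordinates")
  }
  rownames(df) <- NULL
  class(df) <- c("bear_track", "data.frame")
  df
}

#' Step lengths of a GPS track
#'
#' Euclidean distances between successive fixes. Any interval touching a
#' failed fix is `NA`, mirroring the treatment of failed fixes in 30-min
#' bear telemetry: a missing location invalidates the step before and after
#' it.
#'
#' @param track a single-bear track (see [as_track()]).
#' @return numeric vector of length `nrow(track) - 1` (length 0 for fewer
#'   than 2 fixes).
#' @export
compute_steps <- function(track) {
  n <- nrow(track)
  if (n < 2) {
    return(numeric(0))
  }
  dx <- diff(track$x)
  dy <- diff(track$y)
  d <- sqrt(dx^2 + dy^2)
  ok <- track$valid[-n] & track$valid[-1]
  d[!ok] <- NA_real_
  d
}

#' Classify berry-foraging segments from a track
#'
#' Berry foraging appears in 30-min bear telemetry as runs of consistently
#' slow, meandering movement. A segment is a maximal run of at least
#' `min_fixes` consecutive fixes whose every step length lies in
#' `[d_min, d_max]` metres (default 25-300 m). Missing steps (failed fixes)
#' and steps outside the band terminate a run. With `rule = "total"` the
#' band is instead applied to the cumulative path length of the run, an
#' alternative reading of the slow-movement criterion kept switchable.
#'
#' @param track a single-bear track.
#' @param d_min,d_max step-length band in metres (defaults 25 and 300).
#' @param min_fixes minimum fixes per segment (default 3, i.e. 1.5 h).
#' @param rule `"per_step"` (default) or `"total"`.
#' @return data frame with one row per segment: `bear_id`, `start`, `end`
#'   (inclusive fix indices), `n_fixes`, `start_time`, `end_time`.
#' @export
find_foraging_segments <- function(track, d_min = 25, d_max = 300,
                                   min_fixes = 3,
                                   rule = c("per_step", "total")) {
  rule <- match.arg(rule)
  stopifnot(d_min > 0, d_max > d_min, min_fixes >= 2)
  steps <- compute_steps(track)
  empty <- data.frame(
    bear_id = character(0), start = integer(0), end = integer(0),
    n_fixes = integer(0)
  )
  if (!length(steps)) {
    return(empty)
  }

  if (rule == "per_step") {
    ok <- !is.na(steps) & steps >= d_min & steps <= d_max
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & r$lengths >= (min_fixes - 1)
    seg <- data.frame(start = starts[keep], end = ends[keep] + 1L)
  } else {
    ## maximal runs of non-missing steps, then total path length in band
    ok <- !is.na(steps)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values & r$lengths >= (min_fixes - 1))
    seg <- do.call(rbind, lapply(keep, function(i) {
      tot <- sum(steps[starts[i]:ends[i]])
      if (tot >= d_min && tot <= d_max) {
        data.frame(start = starts[i], end = ends[i] + 1L)
      }
    }))
    if (is.null(seg)) {
      return(empty)
    }
  }
  if (!nrow(seg)) {
    return(empty)
  }
  data.frame(
    bear_id = track$bear_id[1], start = as.integer(seg$start),
    end = as.integer(seg$end), n_fixes = as.integer(seg$end - seg$start + 1L),
    start_time = track$timestamp[seg$start], end_time = track$timestamp[seg$end]
  )
}

#' Plot-sampling positions within foraging segments
#'
#' Berry abundance is sampled once per foraging segment, at the second fix,
#' to limit spatial autocorrelation between samples; long segments of at
#' least `long_run` fixes (default 7, i.e. >3.5 h of slow movement) are
#' additionally sampled at the second-to-last fix.
#'
#' @param segments segment table from [find_foraging_segments()].
#' @param track the track the segments index into.
#' @param long_run fix count from which the second-to-last position is also
#'   sampled (default 7).
#' @return data frame with one row per sampled position: `bear_id`,
#'   `segment` (row number in `segments`), `slot` (`"second"` or
#'   `"second_to_last"`), `fix` (index into the track), `x`, `y`,
#'   `ordinal_day`.
#' @export
choose_sample_positions <- function(segments, track, long_run = 7) {
  if (!nrow(segments)) {
    return(data.frame(
      bear_id = character(0), segment = integer(0), slot = character(0),
      fix = integer(0), x = numeric(0), y = numeric(0),
      ordinal_day = integer(0)
    ))
  }
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, ]
    idx <- s$start + 1L # second fix, 1-based
    slots <- data.frame(segment = i, slot = "second", fix = idx)
    if (s$n_fixes >= long_run) {
      slots <- rbind(slots, data.frame(
        segment = i, slot = "second_to_last",
        fix = s$end - 1L
      ))
    }
    slots
  })
  pos <- do.call(rbind, rows)
  data.frame(
    bear_id = track$bear_id[pos$fix], segment = pos$segment,
    slot = pos$slot, fix = pos$fix,
    x = track$x[pos$fix], y = track$y[pos$fix],
    ordinal_day = as.integer(strftime(track$timestamp[pos$fix],
      format = "%j", tz = "UTC"
    ))
  )
}

#' Drop segments near known attractant sites
#'
#' Removes every foraging segment with any fix within `radius` metres
#' (inclusive) of any listed site, the buffer used to exclude trajectories
#' near slaughter dumps and agricultural fields where bears forage on other
#' foods.
#'
#' @param segments segment table from [find_foraging_segments()].
#' @param track the track the segments index into.
#' @param sites data frame (or 2-column matrix) of site `x`, `y` in the same
#'   projection; empty or `NULL` returns the input unchanged.
#' @param radius buffer radius in metres (default 200).
#' @return the filtered segment table.
#' @export
exclude_near_sites <- function(segments, track, sites, radius = 200) {
  if (is.null(sites) || !NROW(sites) || !nrow(segments)) {
    return(segments)
  }
  sites <- as.data.frame(sites)
  sx <- sites[[1]]
  sy <- sites[[2]]
  near <- vapply(seq_len(nrow(segments)), function(i) {
    idx <- segments$start[i]:segments$end[i]
    d2 <- outer(track$x[idx], sx, "-")^2 + outer(track$y[idx], sy, "-")^2
    any(d2 <= radius^2)
  }, logical(1))
  segments[!near, , drop = FALSE]
}

#' GPS fix success of a track
#'
#' @param track a single-bear track (failed fixes present as rows).
#' @return fraction of scheduled fixes that were valid, in `[0, 1]`.
#' @export
fix_success_rate <- function(track) {
  if (!nrow(track)) stop("empty track")
  mean(track$valid)
}
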