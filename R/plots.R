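## Plot-selection protocol: digit-based offset from the GPS position,
## relocation away from visible foraging signs, random available plots,
## and assembly of the used-versus-available analysis table.

#' Offset a plot centre from a GPS position by the coordinate-digit rule
#'
#' The field protocol de-biases plot placement by walking 0-9 m from the
#' GPS position: the distance is the last digit of the (truncated integer)
#' Y coordinate and the cardinal direction is taken from the last digit of
#' the X coordinate. The digit-to-direction mapping is any fixed bijection
#' of the four cardinal directions; the default maps digit mod 4 = 0,1,2,3
#' to N,E,S,W and is configurable.
#'
#' @param x,y GPS coordinates in metres (vectorised).
#' @param direction_map character(4), the directions assigned to digit mod
#'   4 = 0..3 (default `c("N","E","S","W")`).
#' @return data frame with offset centre `x`, `y` plus `distance` (m) and
#'   `direction`.
#' @export
offset_plot_location <- function(x, y, direction_map = c("N", "E", "S", "W")) {
  stopifnot(setequal(direction_map, c("N", "E", "S", "W")))
  dist <- trunc(abs(y)) %% 10
  dir <- direction_map[(trunc(abs(x)) %% 10) %% 4 + 1]
  dx <- dist * (dir == "E") - dist * (dir == "W")
  dy <- dist * (dir == "N") - dist * (dir == "S")
  data.frame(x = x + dx, y = y + dy, distance = dist, direction = dir)
}

#' Relocate a plot centre away from foraging signs
#'
#' If a selected plot shows obvious foraging signs (stripped twigs, fallen
#' berries), the plot is moved to the opposite direction from the original
#' GPS position at the same distance, i.e. the centre is reflected through
#' the origin position. Applying the rule twice returns the original
#' centre.
#'
#' @param center_x,center_y plot centre from [offset_plot_location()].
#' @param origin_x,origin_y the original GPS position.
#' @param signs logical; relocate where `TRUE` (vectorised).
#' @return data frame with the (possibly reflected) centre `x`, `y`.
#' @export
relocate_if_signs <- function(center_x, center_y, origin_x, origin_y, signs) {
  signs <- rep_len(as.logical(signs), length(center_x))
  data.frame(
    x = ifelse(signs, 2 * origin_x - center_x, center_x),
    y = ifelse(signs, 2 * origin_y - center_y, center_y)
  )
}

#' Draw random (available) plot locations
#'
#' Uniform locations within the grid extent, the "available" arm of the
#' used-versus-available design. Draws come from the current RNG stream, so
#' seeding the session makes them reproducible.
#'
#' @param n number of plots (default 375, the available sample size of the
#'   study design emulated here).
#' @param grid a `landscape_grid` defining the extent.
#' @return data frame of `n` rows with columns `x`, `y`.
#' @export
draw_random_plots <- function(n = 375, grid) {
  if (n < 1) stop("n must be >= 1")
  data.frame(
    x = runif(n, grid$x0, grid$x0 + grid$ncol * grid$cell),
    y = runif(n, grid$y0, grid$y0 + grid$nrow * grid$cell)
  )
}

#' Assemble the used-versus-available analysis table
#'
#' Binds annotated foraging and random plot records, applies the analysis
#' filters (drop plots in habitat `"other"`; drop rows with any missing
#' model covariate), assigns each random plot to one of the monitored bears
#' uniformly at random (so a bear-level random intercept can be fitted),
#' and sets up the factor codings: `plot_type` with reference `Random`,
#' `habitat` with reference `bog`, `aspect` with reference `N`.
#'
#' @param foraging,random annotated plot data frames (see
#'   [annotate_plots()]); `foraging` must carry `bear_id`.
#' @param bear_ids character vector of monitored bears to assign random
#'   plots to (defaults to the bears present in `foraging`).
#' @return single analysis data frame; attribute `"n_dropped"` records how
#'   many rows each filter removed.
#' @export
assemble_plot_data <- function(foraging, random, bear_ids = NULL) {
  if (!nrow(foraging) && !nrow(random)) stop("no plot records supplied")
  if (is.null(bear_ids)) bear_ids <- unique(as.character(foraging$bear_id))
  if (!length(bear_ids)) stop("no bear ids available for random-plot assignment")
  if (is.null(random$bear_id)) random$bear_id <- NA_character_
  unassigned <- is.na(random$bear_id)
  random$bear_id[unassigned] <- sample(bear_ids, sum(unassigned), replace = TRUE)
  foraging$plot_type <- "Bear"
  random$plot_type <- "Random"
  cols <- union(names(foraging), names(random))
  for (nm in setdiff(cols, names(foraging))) foraging[[nm]] <- NA
  for (nm in setdiff(cols, names(random))) random[[nm]] <- NA
  dat <- rbind(foraging[cols], random[cols])

  n0 <- nrow(dat)
  dat <- dat[dat$habitat != "other", , drop = FALSE]
  n_other <- n0 - nrow(dat)
  covars <- intersect(
    c("habitat", "elevation", "ndvi", "slope", "aspect", "ordinal_day"),
    names(dat)
  )
  ok <- complete.cases(dat[covars])
  n_incomplete <- sum(!ok)
  dat <- dat[ok, , drop = FALSE]

  dat$plot_type <- factor(dat$plot_type, levels = c("Random", "Bear"))
  dat$habitat <- factor(dat$habitat,
    levels = intersect(HABITAT_LEVELS[HABITAT_LEVELS != "other"], unique(dat$habitat))
  )
  dat$aspect <- factor(dat$aspect, levels = ASPECT_LEVELS)
  dat$bear_id <- factor(dat$bear_id)
  rownames(dat) <- NULL
  attr(dat, "n_dropped") <- c(other_habitat = n_other, incomplete = n_incomplete)
  dat
}
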