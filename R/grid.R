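## Landscape layers on a shared regular grid, stored/exchanged as ESRI
## ASCII rasters (plain text). Matrix convention: row 1 is the northernmost
## row, matching the ESRI ASCII row order.

HABITAT_LEVELS <- c("bog", "clearcut", "mature_forest", "young_forest", "other")
ASPECT_LEVELS <- c("N", "E", "S", "W")

#' Construct a landscape grid
#'
#' Bundles co-registered landscape layers (habitat class, elevation in m,
#' NDVI, slope in degrees, aspect class) on one regular grid. Categorical
#' layers (`habitat`, `aspect`) are character matrices; continuous layers
#' numeric matrices. Row 1 is the northern edge.
#'
#' @param x0,y0 coordinates of the lower-left (south-west) corner, metres.
#' @param cell cell size in metres.
#' @param layers named list of equally sized matrices.
#' @return object of class `"landscape_grid"`.
#' @export
landscape_grid <- function(x0, y0, cell, layers) {
  stopifnot(length(layers) >= 1, !is.null(names(layers)))
  dims <- unique(lapply(layers, dim))
  if (length(dims) != 1) stop("all layers must share the grid dimensions")
  structure(
    list(
      x0 = x0, y0 = y0, cell = cell,
      nrow = dims[[1]][1], ncol = dims[[1]][2], layers = layers
    ),
    class = "landscape_grid"
  )
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(
    "landscape_grid:", x$nrow, "x", x$ncol, "cells of", x$cell,
    "m; origin (", x$x0, ",", x$y0, ")\n"
  )
  cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Read and write single-layer ESRI ASCII grids
#'
#' Plain-text raster exchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values from north to south. `NODATA` cells become `NA` on read and are
#' written back as the `NODATA` value.
#'
#' @param path file path.
#' @param mat numeric matrix (row 1 = north).
#' @param x0,y0,cell grid geometry (lower-left corner, metres).
#' @param nodata value standing for missing cells (default -9999).
#' @return `read_asc`: list with `mat`, `x0`, `y0`, `cell`;
#'   `write_asc`: the path, invisibly.
#' @export
read_asc <- function(path) {
  lines <- readLines(path, n = 6)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- setNames(
    as.numeric(vapply(kv, `[`, "", 2)),
    tolower(vapply(kv, `[`, "", 1))
  )
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr))) stop("malformed ESRI ASCII header in ", path)
  vals <- scan(path, skip = 6, quiet = TRUE)
  if (length(vals) != hdr["ncols"] * hdr["nrows"]) {
    stop("cell count does not match header in ", path)
  }
  mat <- matrix(vals, nrow = hdr["nrows"], ncol = hdr["ncols"], byrow = TRUE)
  mat[mat == hdr["nodata_value"]] <- NA
  list(
    mat = mat, x0 = unname(hdr["xllcorner"]), y0 = unname(hdr["yllcorner"]),
    cell = unname(hdr["cellsize"]), nodata = unname(hdr["nodata_value"])
  )
}

#' @rdname read_asc
#' @export
write_asc <- function(mat, path, x0, y0, cell, nodata = -9999) {
  hdr <- c(
    paste("ncols", ncol(mat)), paste("nrows", nrow(mat)),
    paste("xllcorner", format(x0, scientific = FALSE)),
    paste("yllcorner", format(y0, scientific = FALSE)),
    paste("cellsize", format(cell, scientific = FALSE)),
    paste("NODATA_value", nodata)
  )
  m <- mat
  m[is.na(m)] <- nodata
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write / read all layers of a landscape grid as ESRI ASCII files
#'
#' One file per layer (`<layer>.asc`). Categorical layers are written as
#' integer codes (`habitat`: bog=1, clearcut=2, mature_forest=3,
#' young_forest=4, other=5; `aspect`: N=1, E=2, S=3, W=4) and decoded on
#' read. Reading errors if the layer headers disagree.
#'
#' @param grid a `landscape_grid`.
#' @param dir directory for the `.asc` files.
#' @return `write_landscape`: `dir`, invisibly; `read_landscape`: a
#'   `landscape_grid`.
#' @export
write_landscape <- function(grid, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(grid$layers)) {
    lay <- grid$layers[[nm]]
    if (nm == "habitat") lay <- matrix(match(lay, HABITAT_LEVELS), nrow(lay), ncol(lay))
    if (nm == "aspect") lay <- matrix(match(lay, ASPECT_LEVELS), nrow(lay), ncol(lay))
    write_asc(lay, file.path(dir, paste0(nm, ".asc")), grid$x0, grid$y0, grid$cell)
  }
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  files <- list.files(dir, pattern = "\\.asc$", full.names = TRUE)
  if (!length(files)) stop("no .asc layers in ", dir)
  reads <- lapply(files, read_asc)
  names(reads) <- sub("\\.asc$", "", basename(files))
  geo <- unique(lapply(reads, function(r) c(r$x0, r$y0, r$cell, dim(r$mat))))
  if (length(geo) != 1) stop("layer headers disagree in ", dir)
  layers <- lapply(names(reads), function(nm) {
    m <- reads[[nm]]$mat
    if (nm == "habitat") m <- matrix(HABITAT_LEVELS[m], nrow(m), ncol(m))
    if (nm == "aspect") m <- matrix(ASPECT_LEVELS[m], nrow(m), ncol(m))
    m
  })
  names(layers) <- names(reads)
  landscape_grid(reads[[1]]$x0, reads[[1]]$y0, reads[[1]]$cell, layers)
}

#' Nearest-cell lookup
#'
#' Maps point coordinates to grid row/column by nearest cell (no
#' interpolation; habitat is categorical and the continuous layers follow
#' the same convention). Points exactly on a cell boundary take the lower
#' index (deterministic tie-break). Out-of-extent points are an error.
#'
#' @param grid a `landscape_grid`.
#' @param x,y point coordinates (metres), vectorised.
#' @return list with integer vectors `row`, `col`.
#' @export
cell_at <- function(grid, x, y) {
  xmax <- grid$x0 + grid$ncol * grid$cell
  ytop <- grid$y0 + grid$nrow * grid$cell
  if (any(x < grid$x0 | x > xmax | y < grid$y0 | y > ytop, na.rm = TRUE) ||
    anyNA(x) || anyNA(y)) {
    stop("point outside grid extent")
  }
  col <- pmax(1L, as.integer(ceiling((x - grid$x0) / grid$cell)))
  row <- pmax(1L, as.integer(ceiling((ytop - y) / grid$cell)))
  list(row = row, col = col)
}

#' Annotate plot locations with landscape covariates
#'
#' Nearest-cell lookup of every layer at the given coordinates, producing
#' the covariate block of a plot record.
#'
#' @param xy data frame with columns `x`, `y` (metres).
#' @param grid a `landscape_grid` with layers `habitat`, `elevation`,
#'   `ndvi`, `slope`, `aspect`.
#' @param plot_type `"Bear"` or `"Random"`, recycled.
#' @param ordinal_day integer day-of-year per row, recycled.
#' @return `xy` with covariate columns appended.
#' @export
annotate_plots <- function(xy, grid, plot_type, ordinal_day) {
  rc <- cell_at(grid, xy$x, xy$y)
  idx <- cbind(rc$row, rc$col)
  out <- xy
  out$plot_type <- rep_len(as.character(plot_type), nrow(xy))
  out$ordinal_day <- as.integer(rep_len(ordinal_day, nrow(xy)))
  for (nm in names(grid$layers)) out[[nm]] <- grid$layers[[nm]][idx]
  out
}
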