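## Readers and writers for the plain-text exchange formats: telemetry CSV,
## plot-record CSV, YAML run configuration. All CSVs have a header row,
## UTF-8, '.' decimal separator; coordinates are planar metres; timestamps
## ISO-8601 UTC.

TELEMETRY_COLS <- c("bear_id", "timestamp", "x", "y", "valid")

#' Read GPS telemetry into per-bear tracks
#'
#' Expects columns `bear_id`, `timestamp` (ISO-8601, UTC), `x`, `y`
#' (metres), `valid` (0/1); failed fixes appear as rows with empty
#' coordinates and `valid = 0`. Rows out of time order are sorted with a
#' warning; malformed timestamps are an error naming the offending line.
#'
#' @param path CSV file.
#' @return named list of [as_track()] data frames, one per bear.
#' @export
read_telemetry <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!nrow(raw)) stop("empty telemetry file: ", path)
  miss <- setdiff(TELEMETRY_COLS, names(raw))
  if (length(miss)) stop("telemetry is missing columns: ", paste(miss, collapse = ", "))
  ts <- as.POSIXct(strptime(raw$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  alt <- is.na(ts)
  if (any(alt)) {
    ts[alt] <- as.POSIXct(strptime(raw$timestamp[alt], "%Y-%m-%d %H:%M:%S",
      tz = "UTC"
    ))
  }
  bad <- which(is.na(ts))
  if (length(bad)) {
    stop(
      "malformed timestamp at line ", bad[1] + 1, " of ", path, ": '",
      raw$timestamp[bad[1]], "'"
    )
  }
  num <- function(v) suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
  df <- data.frame(
    bear_id = raw$bear_id, timestamp = ts,
    x = num(raw$x), y = num(raw$y),
    valid = as.integer(raw$valid) == 1L
  )
  out <- lapply(split(df, df$bear_id), function(d) {
    if (is.unsorted(d$timestamp, strictly = FALSE)) {
      warning("telemetry rows out of time order for bear ", d$bear_id[1], "; sorted")
    }
    as_track(d)
  })
  out
}

#' @param tracks named list of tracks (or a single track).
#' @rdname read_telemetry
#' @export
write_telemetry <- function(tracks, path) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, as.data.frame))
  df$timestamp <- strftime(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  df$valid <- as.integer(df$valid)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and write plot-record tables
#'
#' One row per 1-m2 plot with position, covariates, per-species counts,
#' sugar content and the foraging-sign flag; missing values are empty
#' fields.
#'
#' @param path CSV file.
#' @param plots plot data frame.
#' @return `read_plots`: data frame; `write_plots`: the path, invisibly.
#' @export
read_plots <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!nrow(df)) stop("empty plot table: ", path)
  if ("foraging_signs" %in% names(df)) {
    df$foraging_signs <- as.logical(df$foraging_signs)
  }
  df
}

#' @rdname read_plots
#' @export
write_plots <- function(plots, path) {
  df <- as.data.frame(plots)
  if ("foraging_signs" %in% names(df)) {
    df$foraging_signs <- as.integer(df$foraging_signs)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and write a run configuration
#'
#' YAML serialisation of the nested configuration list (classifier
#' thresholds, significance level, quadrature nodes, Monte-Carlo draws,
#' seeds, scenario parameters).
#'
#' @param path YAML file.
#' @param config configuration list.
#' @return `read_config`: list; `write_config`: the path, invisibly.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  writeLines(yaml::as.yaml(config), path)
  invisible(path)
}
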