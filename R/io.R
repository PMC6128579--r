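#' Sensor-log and labeled-observation CSV input/output
#'
#' The on-disk interchange format is plain CSV (comma separator, dot
#' decimal, UTF-8, header row required). A sensor log holds one row per tag
#' per second with columns
#' `timestamp,tag_id,ax,ay,az,x,y,rssi_1,...,rssi_6`:
#' `timestamp` in integer seconds from the epoch of the log, acceleration
#' in g, plane coordinates in meters (Sensor 1 is the origin) and per-sensor
#' received signal strength in dBm. The `x`, `y` and `rssi_*` columns may be
#' empty for accelerometer-only logs.
#'
#' @param path file path of the CSV.
#' @return `read_sensor_log()`: data.frame with the 13 columns above, one
#'   row per data row in file order; empty position/RSSI cells become `NA`.
#' @export
read_sensor_log <- function(path) {
  cols <- sensor_log_columns()
  if (!file.exists(path)) stop("sensor log not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  if (!identical(names(raw), cols)) {
    stop("sensor log header must be exactly: ", paste(cols, collapse = ","))
  }
  out <- raw
  numeric_cols <- setdiff(cols, "tag_id")
  for (cc in numeric_cols) {
    txt <- trimws(raw[[cc]])
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(txt != "" & is.na(val))
    if (length(bad)) {
      stop(sprintf("sensor log %s: cannot parse field '%s' on line %d",
                   path, cc, bad[1] + 1L))  # +1 for the header line
    }
    required <- cc %in% c("timestamp", "ax", "ay", "az")
    if (required && any(txt == "")) {
      stop(sprintf("sensor log %s: missing required field '%s' on line %d",
                   path, cc, which(txt == "")[1] + 1L))
    }
    out[[cc]] <- val
  }
  out
}

#' @rdname read_sensor_log
#' @param records data.frame with the sensor-log columns (as returned by
#'   [read_sensor_log()] or [simulate_track_and_rssi()]).
#' @return `write_sensor_log()`: `path`, invisibly. Reading the file back
#'   reproduces `records` to printed precision.
#' @export
write_sensor_log <- function(records, path) {
  cols <- sensor_log_columns()
  if (!all(cols %in% names(records))) {
    stop("records must have columns ", paste(cols, collapse = ","))
  }
  records <- records[, cols]
  numeric_cols <- setdiff(cols, "tag_id")
  for (cc in numeric_cols) {
    v <- records[[cc]]
    if (!is.numeric(v)) stop("column ", cc, " must be numeric")
    if (any(is.infinite(v) | is.nan(v))) {
      stop("column ", cc, " contains non-finite values")
    }
  }
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

sensor_log_columns <- function() {
  c("timestamp", "tag_id", "ax", "ay", "az", "x", "y",
    paste0("rssi_", 1:6))
}

#' Labeled-observation table I/O
#'
#' A labeled-observation CSV references episodes inside a sensor log:
#' columns `tag_id,start,end,label`, with `start` and `end` the first and
#' last timestamp (inclusive) of the episode and `label` one of
#' [behavior_levels()] or empty for unlabeled episodes.
#'
#' @param path CSV file path.
#' @return `read_labeled_observations()`: data.frame with those 4 columns.
#' @export
read_labeled_observations <- function(path) {
  if (!file.exists(path)) stop("observation table not found: ", path)
  d <- utils::read.csv(path, colClasses = "character", na.strings = NULL)
  need <- c("tag_id", "start", "end", "label")
  if (!identical(names(d), need)) {
    stop("observation table header must be: ", paste(need, collapse = ","))
  }
  d$start <- as.numeric(d$start)
  d$end <- as.numeric(d$end)
  if (anyNA(d$start) || anyNA(d$end)) {
    stop("start/end must be numeric in ", path)
  }
  d$label[trimws(d$label) == ""] <- NA_character_
  if (!all(is.na(d$label) | d$label %in% behavior_levels())) {
    stop("unknown behavior label in ", path)
  }
  d
}

#' @rdname read_labeled_observations
#' @param episodes data.frame with `tag_id,start,end,label`.
#' @export
write_labeled_observations <- function(episodes, path) {
  need <- c("tag_id", "start", "end", "label")
  stopifnot(all(need %in% names(episodes)))
  utils::write.csv(episodes[, need], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Assemble observations from a sensor log and an episode table
#'
#' Joins each episode row `(tag_id, start, end)` against the matching
#' per-second rows of the sensor log and returns one [observation()] per
#' episode. Episodes whose samples are missing from the log are an error.
#'
#' @param log sensor-log data.frame ([read_sensor_log()]).
#' @param episodes labeled-observation data.frame
#'   ([read_labeled_observations()]).
#' @return list of `cow_observation`.
#' @export
observations_from_log <- function(log, episodes) {
  lapply(seq_len(nrow(episodes)), function(i) {
    e <- episodes[i, ]
    rows <- log[log$tag_id == e$tag_id &
                  log$timestamp >= e$start & log$timestamp <= e$end, ,
                drop = FALSE]
    expect_n <- e$end - e$start + 1
    if (nrow(rows) != expect_n) {
      stop(sprintf("episode %d (tag %s, %s..%s): %d of %d samples in log",
                   i, e$tag_id, format(e$start), format(e$end),
                   nrow(rows), expect_n))
    }
    rows <- rows[order(rows$timestamp), ]
    observation(e$tag_id, rows[, c("timestamp", "ax", "ay", "az")],
                if (is.na(e$label)) NA_character_ else e$label)
  })
}

#' Reference tables from the field evaluation of the method
#'
#' Small packaged tables summarizing the dairy-barn field evaluation of the
#' two-stage classifier, used as worked examples and as fixtures for the
#' metric computations:
#'
#' * `trial_duration_counts()`: per-behavior composition of the recorded
#'   observations by duration (`original`, the `kept` count surviving the
#'   >5 s filter, and counts in duration bins `<4 s`, `4 s` ... `>8 s`).
#' * `trial_confusion_stage1()`: the 7x7 first-stage confusion matrix
#'   (rows = predicted, columns = observed) on the 7212-sample test split.
#' * `trial_confusion_fusion()`: the fused-stage matrix for the samples
#'   first predicted feeding or standing: rows feeding, standing and
#'   uncertain (abstentions), columns observed feeding/standing.
#'
#' @return A data.frame (`trial_duration_counts`) or an integer matrix with
#'   dimnames (confusion fixtures).
#' @export
trial_duration_counts <- function() {
  p <- system.file("extdata", "trial_duration_counts.csv",
                   package = "cowsense", mustWork = TRUE)
  utils::read.csv(p, stringsAsFactors = FALSE)
}

#' @rdname trial_duration_counts
#' @export
trial_confusion_stage1 <- function() {
  read_confusion_fixture("trial_confusion_stage1.csv")
}

#' @rdname trial_duration_counts
#' @export
trial_confusion_fusion <- function() {
  read_confusion_fixture("trial_confusion_fusion.csv")
}

read_confusion_fixture <- function(fname) {
  p <- system.file("extdata", fname, package = "cowsense", mustWork = TRUE)
  d <- utils::read.csv(p, row.names = 1, check.names = FALSE)
  as.matrix(d)
}
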