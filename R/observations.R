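#' Labeled accelerometer observations
#'
#' An observation is one behavior episode for one leg tag: an ordered run of
#' 1 Hz tri-axial acceleration samples (units of g, tag range +/- 8 g) with
#' an optional behavior label. Observations are the unit that the duration
#' filter, the windowing step and the train/test split operate on.
#'
#' @param tag_id identifier of the leg tag (scalar, coerced to character).
#' @param samples data.frame with columns `timestamp` (integer seconds,
#'   strictly increasing at 1 s spacing), `ax`, `ay`, `az` (g).
#' @param label a behavior label from [behavior_levels()], or `NA` for
#'   prediction-time input.
#' @return An object of class `cow_observation`: a list with elements
#'   `tag_id`, `label`, `samples`, `duration` (seconds = number of samples).
#' @examples
#' s <- data.frame(timestamp = 0:5, ax = 0, ay = 0, az = 1)
#' obs <- observation("tag1", s, "standing")
#' obs$duration
#' @export
observation <- function(tag_id, samples, label = NA_character_) {
  stopifnot(is.data.frame(samples))
  need <- c("timestamp", "ax", "ay", "az")
  if (!all(need %in% names(samples))) {
    stop("samples must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(samples) < 1L) stop("an observation needs at least one sample")
  ts <- samples$timestamp
  if (nrow(samples) > 1L && any(diff(ts) != 1)) {
    stop("samples must be time-ordered at exactly 1 s spacing")
  }
  acc <- as.matrix(samples[, c("ax", "ay", "az")])
  if (any(!is.finite(acc))) stop("acceleration values must be finite")
  if (any(abs(acc) > 8)) {
    stop("acceleration outside the tag's +/- 8 g range")
  }
  if (!is.na(label)) behavior_code(label)  # validates
  structure(
    list(tag_id = as.character(tag_id), label = label,
         samples = samples[, need], duration = nrow(samples)),
    class = "cow_observation"
  )
}

#' @export
print.cow_observation <- function(x, ...) {
  cat(sprintf("<cow_observation> tag %s, label %s, %d s\n",
              x$tag_id, x$label, x$duration))
  invisible(x)
}

#' Duration filter for behavior observations
#'
#' Keeps only observations lasting strictly more than
#' `min_exclusive_duration` seconds (default 5 s, i.e. >= 6 s at the tag's
#' 1 Hz resolution). Short episodes do not contain the whole course of a
#' behavior and are excluded from training and evaluation; the filter
#' ignores labels so unlabeled prediction-time input passes through the same
#' rule.
#'
#' @param observations list of [observation()] objects.
#' @param min_exclusive_duration seconds; an observation is kept iff
#'   `duration > min_exclusive_duration`.
#' @return The kept observations, in input order.
#' @export
filter_observations <- function(observations, min_exclusive_duration = 5) {
  durations <- vapply(observations, function(o) o$duration, numeric(1))
  if (any(durations <= 0 | durations != round(durations))) {
    stop("durations must be positive integers")
  }
  observations[durations > min_exclusive_duration]
}

#' Extract the centered classification window
#'
#' Takes the central `window_len`-second contiguous slice of an observation
#' (ties resolved toward the start), so that the middle of transition
#' behaviors such as lying down and standing up is retained. Observations
#' shorter than the window are an error; apply [filter_observations()]
#' first.
#'
#' @param obs a [observation()].
#' @param window_len window length in seconds (default 6).
#' @return A `cow_observation` of exactly `window_len` samples.
#' @export
extract_window <- function(obs, window_len = 6) {
  n <- obs$duration
  if (n < window_len) {
    stop(sprintf("observation lasts %d s, shorter than the %d s window",
                 n, window_len))
  }
  start <- floor((n - window_len) / 2) + 1L
  sl <- obs$samples[start:(start + window_len - 1L), , drop = FALSE]
  rownames(sl) <- NULL
  observation(obs$tag_id, sl, obs$label)
}

#' Turn a window into a feature vector
#'
#' Two representations of a 6 s window are available for the weak learners:
#'
#' * `"raw"`: the 18 acceleration values `(ax, ay, az)` for each of the 6
#'   seconds, in time order. Preserves the temporal shape of transition
#'   behaviors.
#' * `"summary"`: 14 window descriptors --- per-axis mean, standard
#'   deviation, minimum and maximum (12 values), plus the signal magnitude
#'   area `mean(|ax|+|ay|+|az|)` and the mean vector magnitude
#'   `mean(sqrt(ax^2+ay^2+az^2))`.
#'
#' @param window a `cow_observation` of exactly 6 samples.
#' @param mode `"raw"` (default) or `"summary"`.
#' @return Named numeric vector of length 18 (`raw`) or 14 (`summary`).
#' @export
featurize <- function(window, mode = c("raw", "summary")) {
  mode <- match.arg(mode)
  if (window$duration != 6L) {
    stop("featurize expects a 6 s window; got ", window$duration, " s")
  }
  a <- as.matrix(window$samples[, c("ax", "ay", "az")])
  if (mode == "raw") {
    v <- as.vector(t(a))
    names(v) <- paste0(rep(c("ax", "ay", "az"), times = 6), "_t",
                       rep(1:6, each = 3))
    return(v)
  }
  per_axis <- function(x) c(mean = mean(x), sd = stats::sd(x),
                            min = min(x), max = max(x))
  v <- c(per_axis(a[, 1]), per_axis(a[, 2]), per_axis(a[, 3]),
         sma = mean(abs(a[, 1]) + abs(a[, 2]) + abs(a[, 3])),
         magnitude = mean(sqrt(rowSums(a^2))))
  names(v) <- c(paste0("ax_", c("mean", "sd", "min", "max")),
                paste0("ay_", c("mean", "sd", "min", "max")),
                paste0("az_", c("mean", "sd", "min", "max")),
                "sma", "magnitude")
  v
}

#' Build the design matrix for a set of observations
#'
#' Filters (optionally), windows and featurizes a list of observations in
#' one step.
#'
#' @param observations list of `cow_observation`.
#' @param mode feature mode passed to [featurize()].
#' @param window_len seconds, passed to [extract_window()].
#' @return list with `x` (numeric matrix, one row per observation), `y`
#'   (character labels, possibly `NA`) and `tag_id`.
#' @export
featurize_observations <- function(observations, mode = "raw",
                                   window_len = 6) {
  rows <- lapply(observations, function(o) {
    featurize(extract_window(o, window_len), mode)
  })
  list(
    x = do.call(rbind, rows),
    y = vapply(observations, function(o) o$label, character(1)),
    tag_id = vapply(observations, function(o) o$tag_id, character(1))
  )
}

#' Random train/test split of observations
#'
#' Splits observations at random into a training fraction (default 60%) and
#' the complementary testing fraction, reproducibly from a seed. The split
#' ignores labels.
#'
#' @param n number of observations (or a list of them, whose length is
#'   used).
#' @param train_frac fraction assigned to training (default 0.6).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test`,
#'   `length(train) == round(train_frac * n)`.
#' @export
split_train_test <- function(n, train_frac = 0.6, seed = NULL) {
  if (is.list(n)) n <- length(n)
  if (n < 1) stop("need at least one observation to split")
  n_train <- round(train_frac * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = sort(idx), test = setdiff(seq_len(n), sort(idx)))
}
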