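#' Configuration of the synthetic barn simulator
#'
#' The simulator emulates the study conditions of a leg-tag deployment in
#' a 25 x 13 m loose-housing area: labeled behavior episodes per tag,
#' per-behavior 1 Hz acceleration motifs, positions consistent with the
#' behavior (feeding about one body length from the headlocks, lying in
#' the stall rows, walking as capped-speed waypoint tracks) and RSSI from
#' the lognormal shadowing channel. Motifs are minimal signals that
#' reproduce the separability structure seen in the field: five clearly
#' distinguishable behaviors plus a feeding/standing pair that is nearly
#' identical from the leg and is resolvable only through position.
#'
#' `feeding_overlap_amp` controls how much feeding differs from standing
#' in the acceleration domain: it is the amplitude (g) of a slow
#' oscillation superimposed on the standing motif. `0` makes the two
#' distributions identical; the default 0.05 g (equal to the sensor noise)
#' leaves them only weakly separable.
#'
#' @param n_per_class episodes generated per behavior class (default 100).
#' @param geometry a [barn_geometry()].
#' @param shadowing a [shadowing_params()]; the default simulation channel
#'   uses 1 dB shadowing noise, calibrated so the positioning-error
#'   distribution on the default grid matches the regime observed in the
#'   field (mean planimetric error around 0.9--1.3 m, errors rarely above
#'   2 m).
#' @param duration_ranges named list of `c(min, max)` episode durations in
#'   seconds; transitions span 3--8 s, other behaviors at least 6 s so a
#'   classification window always exists.
#' @param noise_sd named list of per-behavior accelerometer noise (g).
#' @param feeding_overlap_amp feeding-vs-standing oscillation amplitude
#'   (g).
#' @param feeding_band half-width (m) of the feeding position band around
#'   one body length from the headlocks.
#' @param body_length m, the feeding distance from the headlocks.
#' @param walk_amp named amplitudes (g) of the two gait motifs.
#' @param max_speed walking speed cap (m/s).
#' @param n_tags number of simulated leg tags.
#' @param seed master seed; every downstream draw derives from it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_per_class = 100,
                              geometry = barn_geometry(),
                              shadowing = shadowing_params(sigma = 1),
                              duration_ranges = NULL,
                              noise_sd = NULL,
                              feeding_overlap_amp = 0.05,
                              feeding_band = 0.3,
                              body_length = 1.5,
                              walk_amp = c(normal_walking = 0.5,
                                           active_walking = 1.3),
                              max_speed = 1.5,
                              n_tags = 5,
                              seed = NULL) {
  if (is.null(duration_ranges)) {
    duration_ranges <- list(
      feeding = c(6, 40), lying = c(10, 60), standing = c(6, 40),
      lying_down = c(3, 8), standing_up = c(3, 8),
      normal_walking = c(6, 20), active_walking = c(6, 20)
    )
  }
  if (is.null(noise_sd)) {
    noise_sd <- list(feeding = 0.05, lying = 0.05, standing = 0.05,
                     lying_down = 0.1, standing_up = 0.1,
                     normal_walking = 0.08, active_walking = 0.08)
  }
  for (b in behavior_levels()) {
    r <- duration_ranges[[b]]
    if (is.null(r) || length(r) != 2 || r[1] > r[2] || r[1] < 1) {
      stop("infeasible duration range for ", b)
    }
    if (is.null(noise_sd[[b]]) || noise_sd[[b]] < 0) {
      stop("noise SD for ", b, " must be >= 0")
    }
  }
  structure(list(
    n_per_class = n_per_class, geometry = geometry, shadowing = shadowing,
    duration_ranges = duration_ranges, noise_sd = noise_sd,
    feeding_overlap_amp = feeding_overlap_amp, feeding_band = feeding_band,
    body_length = body_length, walk_amp = walk_amp, max_speed = max_speed,
    n_tags = n_tags, seed = seed
  ), class = "simulation_config")
}

#' Simulate a labeled behavior schedule
#'
#' Draws `n_per_class` episodes of each behavior, shuffles them across the
#' simulated tags, and lays them out as non-overlapping, time-ordered
#' intervals per tag (1 s gap between consecutive episodes). Durations are
#' uniform integers within each behavior's configured range.
#'
#' @param config a [simulation_config()].
#' @return data.frame `tag_id, start, end, label`, time-ordered within
#'   tag.
#' @export
simulate_schedule <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_per_class == 0) {
    return(data.frame(tag_id = character(), start = numeric(),
                      end = numeric(), label = character()))
  }
  labels <- rep(behavior_levels(), each = config$n_per_class)
  sched <- with_seed(derive_seed(config$seed, 1L), {
    durations <- vapply(labels, function(b) {
      r <- config$duration_ranges[[b]]
      sample(seq(r[1], r[2]), 1)
    }, numeric(1))
    ord <- sample.int(length(labels))
    data.frame(label = labels[ord], duration = durations[ord])
  })
  sched$tag_id <- paste0("tag", rep_len(seq_len(config$n_tags),
                                        nrow(sched)))
  sched <- sched[order(sched$tag_id), ]
  sched$start <- NA_real_
  sched$end <- NA_real_
  for (tg in unique(sched$tag_id)) {
    i <- which(sched$tag_id == tg)
    ends <- cumsum(sched$duration[i] + 1)
    sched$start[i] <- ends - sched$duration[i]
    sched$end[i] <- ends - 1
  }
  rownames(sched) <- NULL
  sched[, c("tag_id", "start", "end", "label")]
}

#' Simulate the acceleration motif of one episode
#'
#' Generates `duration` seconds of tri-axial acceleration (g) for a
#' behavior:
#' * lying: gravity on the lateral axis, `(1, 0, 0)` plus noise;
#' * standing: gravity on the vertical axis, `(0, 0, 1)` plus noise;
#' * feeding: the standing motif plus a slow low-amplitude oscillation on
#'   the body axis (head movement transmitted to the leg) --- deliberately
#'   near-identical to standing;
#' * lying down / standing up: smooth rotation of the gravity vector
#'   between the standing and lying orientations over the episode;
#' * walking: the standing baseline with i.i.d. gait bursts on all axes,
#'   active walking at about 2.5x the normal amplitude.
#'
#' Samples are clipped to the tag's +/- 8 g range.
#'
#' @param label a behavior from [behavior_levels()].
#' @param duration episode length in seconds (>= 1).
#' @param config a [simulation_config()] (motif parameters).
#' @param seed RNG seed; the same `(label, duration, seed)` always yields
#'   the same samples.
#' @return data.frame `ax, ay, az` with `duration` rows.
#' @export
simulate_accel <- function(label, duration, config = simulation_config(),
                           seed = NULL) {
  if (!label %in% behavior_levels()) stop("unknown label: ", label)
  if (duration < 1) stop("duration must be >= 1 s")
  t <- seq_len(duration)
  sd0 <- config$noise_sd[[label]]
  base <- with_seed(seed, {
    noise <- matrix(stats::rnorm(3 * duration, 0, sd0), ncol = 3)
    core <- switch(label,
      lying = cbind(rep(1, duration), 0, 0),
      standing = cbind(0, 0, rep(1, duration)),
      feeding = {
        phase <- stats::runif(1, 0, 2 * pi)
        cbind(0, config$feeding_overlap_amp * sin(2 * pi * 0.25 * t + phase),
              rep(1, duration))
      },
      lying_down = {
        theta <- (t - 1) / max(duration - 1, 1) * pi / 2
        cbind(sin(theta), 0, cos(theta))
      },
      standing_up = {
        theta <- (t - 1) / max(duration - 1, 1) * pi / 2
        cbind(cos(theta), 0, sin(theta))
      },
      normal_walking = ,
      active_walking = {
        # alternating stride impulses on the walking axis; active walking
        # strides harder and shakes the whole tag more
        amp <- config$walk_amp[[label]]
        alt <- (-1)^t
        jitter <- amp * 0.3 * matrix(stats::rnorm(3 * duration), ncol = 3)
        cbind(amp * alt, 0, rep(1, duration)) + jitter
      }
    )
    core + noise
  })
  base <- pmin(pmax(base, -8), 8)
  data.frame(ax = base[, 1], ay = base[, 2], az = base[, 3])
}

# Draw the (fixed) position of a stationary episode, or the per-second
# track of a walking episode, according to the behavior-position policy.
simulate_positions <- function(label, duration, config, seed = NULL) {
  g <- config$geometry
  with_seed(seed, {
    if (label == "feeding") {
      d <- config$body_length +
        stats::runif(1, -config$feeding_band, config$feeding_band)
      d <- max(d, 0.05)
      p <- c(stats::runif(1, 1, g$length_m - 1), d)
      matrix(rep(p, each = duration), ncol = 2)
    } else if (label %in% c("lying", "lying_down", "standing_up")) {
      # stall rows along the far wall
      p <- c(stats::runif(1, 1, g$length_m - 1),
             stats::runif(1, g$width_m - 3, g$width_m - 0.5))
      matrix(rep(p, each = duration), ncol = 2)
    } else if (label == "standing") {
      p <- c(stats::runif(1, 0.5, g$length_m - 0.5),
             stats::runif(1, 0.2, g$width_m - 0.2))
      matrix(rep(p, each = duration), ncol = 2)
    } else {
      # walking: straight track between two waypoints, speed-capped
      a <- c(stats::runif(1, 0.5, g$length_m - 0.5),
             stats::runif(1, 0.5, g$width_m - 0.5))
      b <- c(stats::runif(1, 0.5, g$length_m - 0.5),
             stats::runif(1, 0.5, g$width_m - 0.5))
      v <- b - a
      len <- sqrt(sum(v^2))
      max_len <- config$max_speed * (duration - 1)
      if (duration > 1 && len > max_len) {
        b <- a + v * max_len / len
      }
      frac <- if (duration == 1) 0 else (seq_len(duration) - 1) / (duration - 1)
      cbind(a[1] + frac * (b[1] - a[1]), a[2] + frac * (b[2] - a[2]))
    }
  })
}

#' Simulate the sensor log and ground truth for a schedule
#'
#' For every second of every scheduled episode, draws the tag's true
#' position from the behavior-position policy, generates the acceleration
#' motif, and produces the six-sensor RSSI vector through the lognormal
#' shadowing channel. The sensor log deliberately leaves the `x`/`y`
#' columns empty (position is what the localization stage must estimate);
#' the true track is returned separately.
#'
#' @param schedule data.frame from [simulate_schedule()].
#' @param config a [simulation_config()].
#' @return list with `log` (sensor-log data.frame, see
#'   [read_sensor_log()]) and `truth` (data.frame `timestamp, tag_id,
#'   true_x, true_y, true_label`).
#' @export
simulate_track_and_rssi <- function(schedule, config) {
  stopifnot(inherits(config, "simulation_config"))
  logs <- vector("list", nrow(schedule))
  truths <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    e <- schedule[i, ]
    dur <- e$end - e$start + 1
    acc <- simulate_accel(e$label, dur, config,
                          seed = derive_seed(config$seed, 10L + 3L * i))
    pos <- simulate_positions(e$label, dur, config,
                              seed = derive_seed(config$seed, 11L + 3L * i))
    dists <- vertex_sensor_distances(pos, config$geometry$sensors)
    rssi <- matrix(distance_to_rssi(
      as.vector(dists), config$shadowing,
      seed = derive_seed(config$seed, 12L + 3L * i)
    ), nrow = dur)
    ts <- seq(e$start, e$end)
    row <- data.frame(timestamp = ts, tag_id = e$tag_id,
                      ax = acc$ax, ay = acc$ay, az = acc$az,
                      x = NA_real_, y = NA_real_)
    for (s in 1:6) row[[paste0("rssi_", s)]] <- rssi[, s]
    logs[[i]] <- row
    truths[[i]] <- data.frame(timestamp = ts, tag_id = e$tag_id,
                              true_x = pos[, 1], true_y = pos[, 2],
                              true_label = e$label)
  }
  log <- do.call(rbind, logs)
  truth <- do.call(rbind, truths)
  ord <- order(log$tag_id, log$timestamp)
  list(log = log[ord, ], truth = truth[ord, ])
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs [simulate_schedule()] and [simulate_track_and_rssi()] and writes
#' the three pipeline input files into `dir`: `sensor_log.csv`,
#' `observations.csv` (the episode table) and `truth.csv`.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if missing).
#' @return Named list of the three file paths, invisibly.
#' @export
generate_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  schedule <- simulate_schedule(config)
  sim <- simulate_track_and_rssi(schedule, config)
  paths <- list(
    sensor_log = file.path(dir, "sensor_log.csv"),
    observations = file.path(dir, "observations.csv"),
    truth = file.path(dir, "truth.csv")
  )
  write_sensor_log(sim$log, paths$sensor_log)
  write_labeled_observations(schedule, paths$observations)
  utils::write.csv(sim$truth, paths$truth, row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Generate labeled observations in memory
#'
#' Convenience wrapper producing the [observation()] list directly
#' (schedule + acceleration motifs, no files), for examples and tests that
#' only exercise the classifier.
#'
#' @param config a [simulation_config()].
#' @return list of `cow_observation`.
#' @export
generate_observations <- function(config) {
  schedule <- simulate_schedule(config)
  lapply(seq_len(nrow(schedule)), function(i) {
    e <- schedule[i, ]
    dur <- e$end - e$start + 1
    acc <- simulate_accel(e$label, dur, config,
                          seed = derive_seed(config$seed, 10L + 3L * i))
    observation(e$tag_id,
                data.frame(timestamp = seq(e$start, e$end), acc),
                e$label)
  })
}
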