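#' Barn geometry for RSSI localization
#'
#' Describes the studied area of the free-stall barn: a rectangle of
#' `length_m` x `width_m` meters (default 25 x 13), the plane coordinates of
#' the six location sensors (Sensor 1 at the origin, x along the long axis),
#' the fixed reference sensor used for ranging correction, the headlock
#' line (the feeding barrier along one long wall), and the grid division
#' factor `S`.
#'
#' The default sensor layout places the six sensors on the boundary: three
#' along each long wall. The headlock line defaults to the `y = 0` wall, so
#' the perpendicular distance of a tag to the headlocks is its `y`
#' coordinate.
#'
#' @param length_m extent along x (m).
#' @param width_m extent along y (m).
#' @param sensors 6x2 numeric matrix of sensor coordinates (m).
#' @param reference length-2 coordinates of the reference sensor.
#' @param headlock two-point line, a 2x2 matrix (rows = endpoints).
#' @param S number of equal parts each boundary side is divided into when
#'   building the virtual grid; the grid then has `(S-1)^2` interior
#'   vertices.
#' @return A list of class `barn_geometry`.
#' @export
barn_geometry <- function(length_m = 25, width_m = 13,
                          sensors = NULL, reference = NULL,
                          headlock = NULL, S = 14) {
  if (is.null(sensors)) {
    sensors <- rbind(
      c(0, 0), c(length_m / 2, 0), c(length_m, 0),
      c(length_m, width_m), c(length_m / 2, width_m), c(0, width_m)
    )
  }
  sensors <- as.matrix(sensors)
  if (!all(dim(sensors) == c(6, 2))) stop("sensors must be a 6x2 matrix")
  if (is.null(reference)) reference <- c(length_m / 2, width_m / 2)
  if (is.null(headlock)) headlock <- rbind(c(0, 0), c(length_m, 0))
  headlock <- as.matrix(headlock)
  if (!all(dim(headlock) == c(2, 2))) {
    stop("headlock must be a 2x2 matrix of two endpoints")
  }
  if (S < 2 || S != round(S)) stop("S must be an integer >= 2")
  inside <- function(p) all(p[1] >= 0 & p[1] <= length_m &
                              p[2] >= 0 & p[2] <= width_m)
  if (!all(apply(sensors, 1, inside)) || !inside(reference)) {
    stop("sensors and reference must lie inside the studied area")
  }
  structure(list(length_m = length_m, width_m = width_m, sensors = sensors,
                 reference = reference, headlock = headlock, S = as.integer(S)),
            class = "barn_geometry")
}

#' Lognormal shadowing channel parameters
#'
#' Path-loss model linking RSSI (dBm) to distance (m):
#' \deqn{r = P_0 - 10\,n\,\log_{10}(d/d_0) + X_\sigma,}
#' with reference power `P0` at distance `d0`, path-loss exponent `n`, and
#' zero-mean Gaussian shadowing noise of `sigma` dB. With `sigma = 0` the
#' model is deterministic and ranging inverts it exactly.
#'
#' @param P0 received power at the reference distance (dBm).
#' @param d0 reference distance (m).
#' @param n path-loss exponent (> 0; ~2 free space, 2--4 indoors).
#' @param sigma shadowing standard deviation (dB, >= 0).
#' @return list of class `shadowing_params`.
#' @export
shadowing_params <- function(P0 = -40, d0 = 1, n = 2.5, sigma = 0) {
  if (n <= 0 || d0 <= 0 || sigma < 0) {
    stop("need n > 0, d0 > 0, sigma >= 0")
  }
  structure(list(P0 = P0, d0 = d0, n = n, sigma = sigma),
            class = "shadowing_params")
}

#' RSSI ranging under the lognormal shadowing model
#'
#' `rssi_to_distance()` inverts the path-loss curve,
#' `d = d0 * 10^((P0 - r) / (10 n))`; `distance_to_rssi()` evaluates it and
#' adds seeded Gaussian shadowing noise of `sigma` dB. With `sigma = 0`
#' they are mutual inverses.
#'
#' @param r RSSI values (dBm), any shape.
#' @param d distances (m), positive.
#' @param params a [shadowing_params()].
#' @param seed RNG seed for the shadowing noise.
#' @return Distances in meters / RSSI in dBm, same shape as the input.
#' @export
rssi_to_distance <- function(r, params = shadowing_params()) {
  params$d0 * 10^((params$P0 - r) / (10 * params$n))
}

#' @rdname rssi_to_distance
#' @export
distance_to_rssi <- function(d, params = shadowing_params(), seed = NULL) {
  if (any(d <= 0)) stop("distances must be positive")
  r <- params$P0 - 10 * params$n * log10(d / params$d0)
  if (params$sigma > 0) {
    r <- r + with_seed(seed, stats::rnorm(length(d), 0, params$sigma))
  }
  r
}

#' Build the virtual localization grid
#'
#' Divides each side of the studied-area rectangle into `S` equal parts;
#' the `(S-1)^2` interior lattice vertices are the candidate positions of
#' the similarity search. Vertices are ordered row-major from the origin
#' corner (y increasing, then x within a row), and each carries its
#' precomputed Euclidean distance vector `H` to the six location sensors.
#'
#' @param geometry a [barn_geometry()].
#' @return list of class `grid_map`: `vertices` ((S-1)^2 x 2 matrix), `H`
#'   ((S-1)^2 x 6 matrix), `geometry`.
#' @export
build_grid <- function(geometry) {
  stopifnot(inherits(geometry, "barn_geometry"))
  S <- geometry$S
  xs <- geometry$length_m * seq_len(S - 1) / S
  ys <- geometry$width_m * seq_len(S - 1) / S
  vertices <- as.matrix(expand.grid(x = xs, y = ys))  # x fastest: row-major
  H <- vertex_sensor_distances(vertices, geometry$sensors)
  structure(list(vertices = vertices, H = H, geometry = geometry),
            class = "grid_map")
}

vertex_sensor_distances <- function(points, sensors) {
  d <- sapply(seq_len(nrow(sensors)), function(i) {
    sqrt((points[, 1] - sensors[i, 1])^2 + (points[, 2] - sensors[i, 2])^2)
  })
  matrix(d, nrow = nrow(points))
}

#' Distance-vector similarity between a tag and a grid vertex
#'
#' The proximity score of a measured distance vector `D` (tag to the six
#' sensors) and a vertex's precomputed vector `H`:
#' \deqn{E(D,H) = \frac16 \sum_{i=1}^{6}
#'   \left(1 - \frac{|d_i - h_i|}{|d_i - h_i| + u_i}\right),}
#' with `u_i` the average of `d_i` and `h_i`. Each term is 1 where the
#' distances agree and decays toward 0 as they diverge, so `E` lies in
#' (0, 1] and equals 1 exactly when `D == H`. A degenerate term with
#' `d_i = h_i = 0` takes its limit value 1.
#'
#' @param D numeric length-6 measured distance vector (m).
#' @param H numeric length-6 vertex distance vector (m).
#' @return Scalar similarity in (0, 1].
#' @export
similarity <- function(D, H) {
  stopifnot(length(D) == 6, length(H) == 6)
  gap <- abs(D - H)
  u <- (abs(D) + abs(H)) / 2
  term <- ifelse(gap == 0, 1, 1 - gap / (gap + u))
  mean(term)
}

#' @rdname similarity
#' @param grid a [build_grid()] result.
#' @return `similarity_array()`: numeric vector of `(S-1)^2` similarities,
#'   in vertex-index order.
#' @export
similarity_array <- function(D, grid) {
  stopifnot(inherits(grid, "grid_map"), length(D) == 6)
  H <- grid$H
  Dm <- matrix(D, nrow(H), 6, byrow = TRUE)
  gap <- abs(Dm - H)
  u <- (abs(Dm) + abs(H)) / 2
  term <- 1 - gap / (gap + u)
  term[gap == 0] <- 1
  rowMeans(term)
}

#' Estimate a tag position from vertex similarities
#'
#' The position estimate is the centroid of the three grid vertices with
#' the highest similarity values (ties broken by smaller vertex index).
#'
#' @param C similarity vector from [similarity_array()].
#' @param grid the matching [build_grid()] result.
#' @return Named numeric `c(x, y)` in meters.
#' @export
estimate_position <- function(C, grid) {
  stopifnot(inherits(grid, "grid_map"), length(C) == nrow(grid$vertices))
  if (length(C) < 3) stop("need at least 3 grid vertices")
  top3 <- order(-C, seq_along(C))[1:3]
  c(x = mean(grid$vertices[top3, 1]), y = mean(grid$vertices[top3, 2]))
}

#' Reference-sensor ranging correction
#'
#' The fixed reference sensor sees the same channel conditions as the tags;
#' comparing its known (`e`) and RSSI-measured (`f`) distances to the six
#' location sensors gives a relative error coefficient
#' \deqn{\delta = \frac16 \sum_{i=1}^{6} \frac{e_i - f_i}{f_i},}
#' and every tag-measured distance is then rescaled as
#' `d' = d * (1 + delta)`, removing the common (systematic) part of the
#' ranging error.
#'
#' @param e true reference-to-sensor distances (m), length 6.
#' @param f RSSI-measured reference-to-sensor distances (m), length 6,
#'   strictly positive.
#' @return `correction_coefficient()`: scalar `delta`.
#' @export
correction_coefficient <- function(e, f) {
  stopifnot(length(e) == length(f))
  if (any(f <= 0)) stop("measured reference distances must be positive")
  mean((e - f) / f)
}

#' @rdname correction_coefficient
#' @param D measured tag distance vector (m).
#' @param delta correction coefficient.
#' @return `correct_distances()`: the rescaled distance vector.
#' @export
correct_distances <- function(D, delta) {
  D * (1 + delta)
}

#' Perpendicular distance to the headlock line
#'
#' Distance from an estimated tag position to the feeding headlocks,
#' clipped to `[0, width_m]`. This is the position evidence the fusion
#' stage uses: a hind leg about one body length from the headlocks
#' indicates feeding.
#'
#' @param position numeric `c(x, y)` or an n x 2 matrix.
#' @param geometry a [barn_geometry()].
#' @return Distance(s) in meters.
#' @export
perpendicular_distance <- function(position, geometry) {
  stopifnot(inherits(geometry, "barn_geometry"))
  if (is.null(dim(position))) position <- matrix(position, ncol = 2)
  a <- geometry$headlock[1, ]
  b <- geometry$headlock[2, ]
  v <- b - a
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("degenerate headlock line")
  # distance from point to the infinite line through a, b
  d <- abs((position[, 1] - a[1]) * v[2] -
             (position[, 2] - a[2]) * v[1]) / nv
  pmin(pmax(d, 0), geometry$width_m)
}

#' Positioning-error summary
#'
#' Per-pair planimetric (Euclidean) errors between estimated and true
#' positions, summarized as maximum, mean and minimum, the indicators used
#' to judge localization performance per tag.
#'
#' @param estimates,truths n x 2 matrices (or data.frames with `x`, `y`).
#' @return Named numeric `c(max, mean, min)` in meters.
#' @export
positioning_error_summary <- function(estimates, truths) {
  estimates <- as.matrix(as.data.frame(estimates)[, 1:2])
  truths <- as.matrix(as.data.frame(truths)[, 1:2])
  if (nrow(estimates) != nrow(truths)) {
    stop("estimates and truths must pair up one-to-one")
  }
  err <- sqrt(rowSums((estimates - truths)^2))
  c(max = max(err), mean = mean(err), min = min(err))
}

#' Locate every record of a sensor log
#'
#' Runs the full localization chain for each log row carrying a complete
#' RSSI vector: RSSI -> distances (lognormal model), optional
#' reference-sensor correction, grid-similarity matching, top-3 centroid,
#' and perpendicular distance to the headlocks.
#'
#' @param log sensor-log data.frame with `rssi_1..rssi_6` columns.
#' @param grid a [build_grid()] result.
#' @param params a [shadowing_params()] describing the ranging model.
#' @param delta reference-correction coefficient (default 0 = no
#'   correction; see [correction_coefficient()]).
#' @return data.frame `timestamp, tag_id, x, y, d_head`, one row per log
#'   row with complete RSSI (others are dropped).
#' @export
locate_positions <- function(log, grid, params = shadowing_params(),
                             delta = 0) {
  stopifnot(inherits(grid, "grid_map"))
  rssi <- as.matrix(log[, paste0("rssi_", 1:6)])
  ok <- stats::complete.cases(rssi)
  log <- log[ok, , drop = FALSE]
  rssi <- rssi[ok, , drop = FALSE]
  est <- matrix(NA_real_, nrow(log), 2)
  for (i in seq_len(nrow(log))) {
    D <- correct_distances(rssi_to_distance(rssi[i, ], params), delta)
    C <- similarity_array(D, grid)
    est[i, ] <- estimate_position(C, grid)
  }
  data.frame(
    timestamp = log$timestamp, tag_id = log$tag_id,
    x = est[, 1], y = est[, 2],
    d_head = perpendicular_distance(est, grid$geometry)
  )
}
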