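test_that("lognormal ranging inverts exactly without noise", {
  p <- shadowing_params(P0 = -40, d0 = 1, n = 2.5, sigma = 0)
  expect_equal(rssi_to_distance(p$P0, p), 1)
  expect_equal(rssi_to_distance(p$P0 - 10 * p$n, p), 10)
  expect_equal(rssi_to_distance(distance_to_rssi(3.7, p), p), 3.7)
  # seeded noise is reproducible and has the configured spread
  pn <- shadowing_params(sigma = 2)
  r1 <- distance_to_rssi(rep(5, 1000), pn, seed = 4)
  expect_identical(r1, distance_to_rssi(rep(5, 1000), pn, seed = 4))
  expect_equal(sd(r1), 2, tolerance = 0.15)
  expect_error(shadowing_params(n = -1), "n > 0")
})

test_that("the virtual grid has (S-1)^2 interior vertices", {
  g <- barn_geometry(length_m = 10, width_m = 10, S = 2)
  grid <- build_grid(g)
  expect_equal(nrow(grid$vertices), 1)
  expect_equal(unname(grid$vertices[1, ]), c(5, 5))
  g4 <- barn_geometry(length_m = 12, width_m = 8, S = 4)
  grid4 <- build_grid(g4)
  expect_equal(nrow(grid4$vertices), 9)
  expect_setequal(unique(grid4$vertices[, "x"]), c(3, 6, 9))
  expect_setequal(unique(grid4$vertices[, "y"]), c(2, 4, 6))
  # vertex coinciding with a sensor has distance 0 to it
  g2 <- barn_geometry(length_m = 10, width_m = 10, S = 2,
                      sensors = rbind(c(5, 5), c(0, 0), c(10, 0),
                                      c(10, 10), c(0, 10), c(5, 0)))
  expect_equal(build_grid(g2)$H[1, 1], 0)
  expect_error(barn_geometry(S = 1), "S must be")
})

test_that("similarity is 1 iff the distance vectors agree", {
  expect_equal(similarity(rep(2, 6), rep(2, 6)), 1)
  expect_equal(similarity(rep(2, 6), rep(4, 6)), 0.6)
  expect_equal(similarity(rep(1, 6), c(rep(1, 5), 3)), 11 / 12)
  expect_equal(similarity(rep(0, 6), rep(0, 6)), 1)  # degenerate limit
  withr::with_seed(8, {
    for (i in 1:50) {
      D <- runif(6, 0.1, 30)
      H <- runif(6, 0.1, 30)
      e <- similarity(D, H)
      expect_true(e > 0 && e < 1)
      expect_equal(similarity(D, D), 1)
    }
  })
})

test_that("similarity_array matches the per-vertex scalar computation", {
  grid <- build_grid(barn_geometry(S = 5))
  withr::with_seed(9, D <- runif(6, 1, 20))
  C <- similarity_array(D, grid)
  expect_length(C, 16)
  manual <- vapply(seq_len(nrow(grid$H)),
                   function(j) similarity(D, grid$H[j, ]), numeric(1))
  expect_equal(C, manual)
  # a tag exactly at a vertex scores 1 there, and that is the maximum
  C2 <- similarity_array(grid$H[7, ], grid)
  expect_equal(C2[7], 1)
  expect_equal(which.max(C2), 7)
  expect_true(all(C2 > 0 & C2 <= 1))
})

test_that("position estimate is the top-3 centroid with index ties", {
  grid <- build_grid(barn_geometry(length_m = 9, width_m = 9, S = 4))
  # construct similarities so vertices 1, 2, 4 win; their coords average
  C <- rep(0.1, 9)
  C[c(1, 2, 4)] <- c(0.9, 0.8, 0.7)
  v <- grid$vertices[c(1, 2, 4), ]
  expect_equal(estimate_position(C, grid),
               c(x = mean(v[, 1]), y = mean(v[, 2])))
  # all equal -> first three vertices by index
  expect_equal(estimate_position(rep(0.5, 9), grid),
               c(x = mean(grid$vertices[1:3, 1]),
                 y = mean(grid$vertices[1:3, 2])))
  g2 <- build_grid(barn_geometry(length_m = 10, width_m = 10, S = 2))
  expect_error(estimate_position(1, g2), "at least 3")
})

test_that("noiseless tags at grid vertices localize within one cell", {
  geometry <- barn_geometry()  # 25 x 13, S = 14
  grid <- build_grid(geometry)
  p0 <- shadowing_params(sigma = 0)
  cell_diag <- sqrt((geometry$length_m / 14)^2 + (geometry$width_m / 14)^2)
  withr::with_seed(10, picks <- sample(nrow(grid$vertices), 25))
  for (j in picks) {
    D <- rssi_to_distance(distance_to_rssi(grid$H[j, ], p0), p0)
    est <- estimate_position(similarity_array(D, grid), grid)
    err <- sqrt(sum((est - grid$vertices[j, ])^2))
    expect_lt(err, cell_diag)
  }
})

test_that("reference correction rescales distances by the error ratio", {
  e <- c(5, 7, 9, 11, 13, 15)
  expect_equal(correction_coefficient(e, e), 0)
  expect_equal(correct_distances(c(1, 2, 3, 4, 5, 6), 0),
               c(1, 2, 3, 4, 5, 6))
  d <- correction_coefficient(rep(10, 6), rep(8, 6))
  expect_equal(d, 0.25)
  expect_equal(correct_distances(4, d), 5)
  expect_error(correction_coefficient(e, c(0, e[-1])), "positive")
  # linearity: correcting a scaled vector scales the output
  D <- c(2, 4, 6, 8, 10, 12)
  expect_equal(correct_distances(3 * D, 0.2), 3 * correct_distances(D, 0.2))
})

test_that("headlock distance is perpendicular and clipped to the width", {
  # headlocks along the x = 0 wall of a 13-wide area
  g <- barn_geometry(length_m = 25, width_m = 13,
                     headlock = rbind(c(0, 0), c(0, 13)))
  expect_equal(perpendicular_distance(c(1.2, 7.0), g), 1.2)
  expect_equal(perpendicular_distance(c(0, 3), g), 0)
  expect_equal(perpendicular_distance(c(20, 3), g), 13)
  # default orientation: headlocks along y = 0
  gd <- barn_geometry()
  expect_equal(perpendicular_distance(c(12, 1.5), gd), 1.5)
})

test_that("positioning-error summaries", {
  a <- cbind(c(0, 1), c(0, 1))
  expect_equal(positioning_error_summary(a, a), c(max = 0, mean = 0, min = 0))
  expect_equal(positioning_error_summary(cbind(3, 4), cbind(0, 0)),
               c(max = 5, mean = 5, min = 5))
  est <- cbind(c(1, 2, 3), 0)
  tru <- cbind(0, 0)[rep(1, 3), ]
  expect_equal(positioning_error_summary(est, tru),
               c(max = 3, mean = 2, min = 1))
  expect_error(positioning_error_summary(a, cbind(1, 1)), "one-to-one")
})

test_that("finer grids do not worsen noiseless localization", {
  p0 <- shadowing_params(sigma = 0)
  withr::with_seed(12, tru <- cbind(runif(30, 1, 24), runif(30, 1, 12)))
  med_err <- vapply(c(4, 8, 14), function(S) {
    grid <- build_grid(barn_geometry(S = S))
    dists <- cowsense:::vertex_sensor_distances(tru, grid$geometry$sensors)
    errs <- vapply(seq_len(nrow(tru)), function(i) {
      D <- rssi_to_distance(distance_to_rssi(dists[i, ], p0), p0)
      est <- estimate_position(similarity_array(D, grid), grid)
      sqrt(sum((est - tru[i, ])^2))
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) <= 0))
})

test_that("a realistic channel lands in the field error regime", {
  # 1.5 dB shadowing on the default grid: mean planimetric error around a
  # meter, the magnitude seen with leg tags in practice
  grid <- build_grid(barn_geometry())
  ch <- shadowing_params(sigma = 1.5)
  p0 <- shadowing_params(sigma = 0)
  withr::with_seed(13, tru <- cbind(runif(100, 0, 25), runif(100, 0, 13)))
  dists <- cowsense:::vertex_sensor_distances(tru, grid$geometry$sensors)
  est <- t(vapply(seq_len(nrow(tru)), function(i) {
    r <- distance_to_rssi(dists[i, ], ch, seed = 1000 + i)
    estimate_position(similarity_array(rssi_to_distance(r, p0), grid), grid)
  }, numeric(2)))
  s <- positioning_error_summary(est, tru)
  expect_gte(s[["mean"]], 0.7)
  expect_lte(s[["mean"]], 1.5)
})
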