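test_that("mass functions are validated and normalized", {
  m <- mass_function(0.5, 0.4, 0.1)
  expect_equal(sum(m), 1)
  expect_error(mass_function(0.5, 0.4, 0.2), "sum to 1")
  expect_error(mass_function(-0.1, 1.0, 0.1), "nonnegative")
})

test_that("classifier evidence assigns the fixed confusable-pair masses", {
  expect_equal(unname(bpa_from_classifier("feeding")), c(0.5, 0.4, 0.1))
  expect_equal(unname(bpa_from_classifier("standing")), c(0.4, 0.5, 0.1))
  expect_error(bpa_from_classifier("lying"), "only to feeding/standing")
})

test_that("position evidence follows the three-interval division", {
  cfg <- fusion_config()  # body 1.5 m, error_max 1.30 m
  expect_equal(unname(bpa_from_position(1.5, cfg)), c(0.9, 0, 0.1))
  expect_equal(unname(bpa_from_position(0.75, cfg)), c(0.45, 0.45, 0.1))
  expect_equal(unname(bpa_from_position(5, cfg)), c(0, 0.9, 0.1))
  expect_equal(unname(bpa_from_position(2.15, cfg)), c(0.45, 0.45, 0.1))
  expect_equal(unname(bpa_from_position(0, cfg)), c(0, 0.9, 0.1))
  expect_error(bpa_from_position(-0.5, cfg), "lie in")
  expect_error(bpa_from_position(14, cfg), "lie in")
  # piecewise linear, uncertainty constant, feeding mass peaks at 1.5 m
  d <- seq(0, 13, by = 0.01)
  mf <- vapply(d, function(x) bpa_from_position(x, cfg)[["feeding"]],
               numeric(1))
  mu <- vapply(d, function(x) bpa_from_position(x, cfg)[["uncertainty"]],
               numeric(1))
  expect_true(all(mu == 0.1))
  expect_equal(max(mf), 0.9)
  expect_equal(d[which.max(mf)], 1.5)
  expect_true(all(abs(diff(mf)) < 0.01))  # no jumps
})

test_that("Dempster combination matches the hand-worked products", {
  m <- dempster_combine(mass_function(0.5, 0.4, 0.1),
                        mass_function(0.9, 0, 0.1))
  expect_equal(unname(m), c(0.921875, 0.0625, 0.015625), tolerance = 1e-12)
  m2 <- dempster_combine(mass_function(0.5, 0.4, 0.1),
                         mass_function(0.45, 0.45, 0.1))
  expect_equal(unname(m2), c(0.32, 0.265, 0.01) / 0.595, tolerance = 1e-12)
  # vacuous evidence is the identity
  any_m <- mass_function(0.3, 0.45, 0.25)
  expect_equal(dempster_combine(any_m, mass_function(0, 0, 1)), any_m)
  # total conflict is not combinable
  expect_error(dempster_combine(mass_function(1, 0, 0),
                                mass_function(0, 1, 0)), "conflict")
})

test_that("combination is commutative, associative and normalized", {
  ms <- random_masses(200, seed = 21)
  for (i in seq(1, 199, by = 2)) {
    a <- ms[[i]]; b <- ms[[i + 1]]
    ab <- dempster_combine(a, b)
    expect_equal(sum(ab), 1, tolerance = 1e-12)
    expect_true(all(ab >= 0))
    expect_equal(ab, dempster_combine(b, a), tolerance = 1e-12)
  }
  for (i in seq(1, 197, by = 3)) {
    a <- ms[[i]]; b <- ms[[i + 1]]; c <- ms[[i + 2]]
    expect_equal(dempster_combine(dempster_combine(a, b), c),
                 dempster_combine(a, dempster_combine(b, c)),
                 tolerance = 1e-12)
  }
})

test_that("the decision rules fire on margins and abstain otherwise", {
  cfg <- fusion_config(eps1 = 0.2, eps2 = 0.03)
  expect_equal(decide_behavior(mass_function(0.921875, 0.0625, 0.015625),
                               cfg), "feeding")
  expect_equal(decide_behavior(mass_function(0.0625, 0.921875, 0.015625),
                               cfg), "standing")
  un <- dempster_combine(mass_function(0.5, 0.4, 0.1),
                         mass_function(0.45, 0.45, 0.1))
  expect_equal(decide_behavior(un, cfg), "uncertain")
  # high uncertainty mass always abstains
  expect_equal(decide_behavior(mass_function(0.6, 0.1, 0.3), cfg),
               "uncertain")
  # the two rules can never fire together
  for (m in random_masses(200, seed = 22)) {
    d <- decide_behavior(m, cfg)
    f_rule <- m[[1]] > cfg$eps1 + m[[2]] && m[[3]] < cfg$eps2 &&
      m[[1]] > m[[3]]
    s_rule <- m[[2]] > cfg$eps1 + m[[1]] && m[[3]] < cfg$eps2 &&
      m[[2]] > m[[3]]
    expect_false(f_rule && s_rule)
    expect_equal(d, if (f_rule) "feeding" else if (s_rule) "standing"
                 else "uncertain")
  }
})

test_that("reclassification fuses the pair and passes everything else", {
  cfg <- fusion_config()
  out <- reclassify(c("lying", "feeding", "feeding", "normal_walking"),
                    c(NA, 1.5, 13, NA), cfg)
  expect_equal(out$final_label,
               c("lying", "feeding", "standing", "normal_walking"))
  expect_false(any(out$flag_uncertain))
  expect_true(all(is.na(out$m_feeding[c(1, 4)])))
  expect_error(reclassify(c("feeding", "standing"), 1.0), "equal length")
  expect_error(reclassify("feeding", NA_real_), "missing headlock")
  # adversarial positions never touch pass-through labels
  withr::with_seed(23, {
    labs <- sample(setdiff(behavior_levels(), confusable_pair()), 50,
                   replace = TRUE)
    d <- runif(50, 0, 13)
    out2 <- reclassify(labs, d, cfg)
    expect_equal(out2$final_label, labs)
  })
})
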