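test_that("weight initialization is uniform and validated", {
  expect_equal(init_weights(4), rep(0.25, 4))
  expect_equal(init_weights(1), 1)
  expect_error(init_weights(0), "positive integer")
})

test_that("weighted error sums the weights of the misclassified", {
  y <- rep(c("a", "b"), each = 5)
  p <- y; p[c(1, 6)] <- c("b", "a")
  expect_equal(weighted_error(y, p, init_weights(10)), 0.2)
  expect_equal(weighted_error(c("a", "b"), c("a", "a"), c(0.7, 0.3)), 0.3)
  expect_equal(weighted_error(y, y, init_weights(10)), 0)
})

test_that("learner coefficient follows the half-log SAMME form", {
  expect_equal(alpha_coefficient(0.5, 7), log(6))
  expect_equal(alpha_coefficient(36 / 37, 7), 0, tolerance = 1e-9)
  expect_equal(alpha_coefficient(0.1, 2), 0.5 * log(9))
  # strictly decreasing in err, positive iff err < 36/37 for K = 7
  errs <- seq(0.01, 0.99, by = 0.01)
  a <- vapply(errs, alpha_coefficient, numeric(1), K = 7)
  expect_true(all(diff(a) < 0))
  expect_true(all(a[errs < 36 / 37 - 1e-6] > 0))
  expect_true(all(a[errs > 36 / 37 + 1e-6] < 0))
  # K = 2 reduces to classic binary AdaBoost's half-log-odds
  expect_equal(alpha_coefficient(0.3, 2), 0.5 * log(0.7 / 0.3))
  # clamping keeps extreme errors finite
  expect_true(is.finite(alpha_coefficient(0, 7)))
  expect_true(is.finite(alpha_coefficient(1, 7)))
})

test_that("weight update upweights mistakes and renormalizes", {
  expect_equal(update_weights(c(0.5, 0.5), log(2), c(FALSE, TRUE)),
               c(2 / 3, 1 / 3))
  w <- c(0.2, 0.3, 0.5)
  expect_equal(update_weights(w, 0, c(TRUE, FALSE, TRUE)), w)
  expect_equal(update_weights(w, 1.3, c(FALSE, FALSE, FALSE)), w)
  # invariants: nonnegative, sum to one, for arbitrary patterns
  withr::with_seed(5, {
    for (i in 1:50) {
      w <- init_weights(8)
      for (l in 1:6) {
        w <- update_weights(w, runif(1, 0, 3), runif(8) > 0.4)
        expect_true(all(w >= 0))
        expect_equal(sum(w), 1, tolerance = 1e-9)
      }
    }
  })
})

test_that("prediction is the alpha-weighted vote with smallest-code ties", {
  cls <- behavior_levels()
  lrn <- function(k) list(type = "constant", class = cls[k])
  m <- new_ensemble_model(list(lrn(3), lrn(5)), c(1, 2),
                          feature_length = 2)
  expect_equal(predict(m, matrix(0, 1, 2)), cls[5])
  m_tie <- new_ensemble_model(list(lrn(3), lrn(5)), c(1, 1),
                              feature_length = 2)
  expect_equal(predict(m_tie, matrix(0, 1, 2)), cls[3])
  m1 <- new_ensemble_model(list(lrn(2)), 0.7, feature_length = 2)
  expect_equal(predict(m1, matrix(0, 3, 2)), rep(cls[2], 3))
  expect_error(predict(m1, matrix(0, 1, 5)), "expects 2 features")
})

test_that("predictions match an independent brute-force vote tally", {
  cls <- behavior_levels()
  withr::with_seed(17, {
    for (rep in 1:100) {
      L <- sample(1:6, 1)
      learners <- lapply(seq_len(L), function(l) {
        if (runif(1) < 0.4) {
          list(type = "constant", class = sample(cls, 1))
        } else {
          list(type = "threshold", feature = sample(1:3, 1),
               threshold = runif(1, -1, 1),
               lo = sample(cls, 1), hi = sample(cls, 1))
        }
      })
      model <- new_ensemble_model(learners, runif(L, 0, 2),
                                  feature_length = 3)
      x <- matrix(runif(15, -1, 1), 5, 3)
      expect_equal(predict(model, x), oracle_vote_tally(model, x))
    }
  })
})

test_that("boosting fits the synthetic ethogram and is reproducible", {
  sim <- generate_observations(simulation_config(n_per_class = 100, seed = 7))
  kept <- filter_observations(sim)
  feats <- featurize_observations(kept)
  model <- fit_adaboost(feats$x, feats$y, L = 10, seed = 7)
  expect_length(model$alpha, 10)
  expect_gte(model$train_accuracy, 0.95)
  # bit-reproducible from the seed
  model2 <- fit_adaboost(feats$x, feats$y, L = 10, seed = 7)
  expect_identical(model$alpha, model2$alpha)
  expect_identical(predict(model, feats$x), predict(model2, feats$x))
  # training error of vote prefixes does not trend upward with L
  prefix_err <- vapply(seq_len(model$L), function(l) {
    pm <- new_ensemble_model(model$learners[seq_len(l)],
                             model$alpha[seq_len(l)],
                             feature_length = model$feature_length)
    mean(predict(pm, feats$x) != feats$y)
  }, numeric(1))
  expect_lte(prefix_err[model$L], prefix_err[1])
  expect_true(all(diff(prefix_err) <= 0.05))
})

test_that("degenerate training sets are handled", {
  x <- matrix(rnorm(20), 10, 2)
  y <- rep("lying", 10)
  m <- fit_adaboost(x, y, L = 2, seed = 1)
  expect_equal(predict(m, x), rep("lying", 10))
  expect_error(fit_adaboost(x, y, L = 0), "positive integer")
})

test_that("a model survives a JSON round trip", {
  sim <- generate_observations(simulation_config(n_per_class = 8, seed = 3))
  feats <- featurize_observations(filter_observations(sim))
  model <- fit_adaboost(feats$x, feats$y, L = 3, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  save_ensemble(model, path)
  back <- load_ensemble(path)
  expect_identical(back$alpha, model$alpha)
  expect_identical(predict(back, feats$x), predict(model, feats$x))
  expect_identical(predict(back, feats$x, type = "votes"),
                   predict(model, feats$x, type = "votes"))
})

test_that("the network forward pass agrees with nnet's own predictions", {
  withr::with_seed(11, {
    x <- matrix(rnorm(60 * 4), 60, 4)
    y <- factor(ifelse(x[, 1] + x[, 2] > 0, "feeding", "lying"),
                levels = behavior_levels())
    fit <- nnet::nnet(x, nnet::class.ind(y), size = 5, softmax = TRUE,
                      maxit = 100, trace = FALSE)
    learner <- list(type = "nnet", dims = c(4, 5, 7), wts = fit$wts,
                    classes = behavior_levels())
    mine <- cowsense:::predict_weak(learner, x)
    theirs <- behavior_levels()[max.col(predict(fit, x),
                                        ties.method = "first")]
    expect_identical(mine, theirs)
  })
})
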