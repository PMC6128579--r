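#' Multiclass AdaBoost over back-propagation network weak learners
#'
#' `fit_adaboost()` trains the package's first-stage behavior classifier:
#' an adaptive-boosting ensemble for K classes with the SAMME-type
#' coefficient
#' \deqn{\alpha_l = \tfrac12 \ln\frac{1-err_l}{err_l} + \ln(K-1),}
#' where \eqn{err_l} is the weight of the training samples the l-th weak
#' learner misclassifies. Each iteration trains a weak learner on a
#' weighted resample of the training set (size N, with replacement,
#' probabilities equal to the current sample weights), so any learner
#' implementation works without native weight support; weights of
#' misclassified samples are then multiplied by \eqn{e^{\alpha_l}} and
#' renormalized. The default weak learner is a single-hidden-layer
#' feed-forward network trained by back-propagation ([nnet::nnet]).
#' Prediction is the \eqn{\alpha}-weighted vote
#' \eqn{\arg\max_k \sum_l \alpha_l I(G_l(p)=k)}, ties broken by the
#' smallest class code.
#'
#' All randomness (resampling and network initialization) derives from the
#' single `seed`, so a fit is bit-reproducible.
#'
#' @param x numeric feature matrix, one row per training sample (see
#'   [featurize_observations()]).
#' @param y character labels, a subset of `classes`.
#' @param L number of boosting iterations (weak learners).
#' @param classes ordered class set; codes are positions in this vector.
#'   Default the 7-behavior ethogram.
#' @param weak_learner list: `type` (`"nnet"`, `"threshold"` or
#'   `"constant"`), and for `"nnet"` the hidden-layer `size` (default 10)
#'   and `maxit` back-propagation epochs (default 200).
#' @param seed master RNG seed.
#' @return An object of class `cow_ensemble`: list with `learners`,
#'   `alpha`, `K`, `L`, `classes`, `feature_length`, `seed`,
#'   `train_accuracy`.
#' @examples
#' \donttest{
#' sim <- generate_observations(simulation_config(n_per_class = 10, seed = 1))
#' feats <- featurize_observations(filter_observations(sim))
#' model <- fit_adaboost(feats$x, feats$y, L = 3, seed = 1)
#' table(predict(model, feats$x), feats$y)
#' }
#' @export
fit_adaboost <- function(x, y, L = 10, classes = behavior_levels(),
                         weak_learner = list(type = "nnet", size = 10,
                                             maxit = 200),
                         seed = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be a numeric matrix")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (!all(y %in% classes)) stop("y contains labels outside `classes`")
  if (!is.numeric(L) || L < 1 || L != round(L)) {
    stop("L must be a positive integer")
  }
  N <- nrow(x)
  K <- length(classes)
  w <- init_weights(N)
  learners <- vector("list", L)
  alpha <- numeric(L)
  for (l in seq_len(L)) {
    idx <- with_seed(derive_seed(seed, 2L * l - 1L),
                     sample.int(N, N, replace = TRUE, prob = w))
    g <- train_weak(x[idx, , drop = FALSE], y[idx], classes,
                    weak_learner, seed = derive_seed(seed, 2L * l))
    pred <- predict_weak(g, x)
    err <- weighted_error(y, pred, w)
    a <- alpha_coefficient(err, K)
    w <- update_weights(w, a, correct = pred == y)
    learners[[l]] <- g
    alpha[l] <- a
  }
  model <- structure(
    list(learners = learners, alpha = alpha, K = K, L = L,
         classes = classes, feature_length = ncol(x), seed = seed),
    class = "cow_ensemble"
  )
  model$train_accuracy <- mean(predict(model, x) == y)
  model
}

#' Boosting primitives
#'
#' The four steps of one boosting iteration, exposed individually:
#' uniform weight initialization, the weighted error rate of a learner's
#' predictions, the SAMME-type coefficient, and the multiplicative weight
#' update.
#'
#' @param N number of training samples.
#' @return `init_weights()`: numeric vector of `N` uniform weights summing
#'   to 1.
#' @export
init_weights <- function(N) {
  if (!is.numeric(N) || length(N) != 1 || N < 1 || N != round(N)) {
    stop("N must be a positive integer")
  }
  rep(1 / N, N)
}

#' @rdname init_weights
#' @param truth,pred label vectors of equal length.
#' @param weights normalized sample weights.
#' @return `weighted_error()`: total weight of misclassified samples, in
#'   \[0, 1\].
#' @export
weighted_error <- function(truth, pred, weights) {
  stopifnot(length(truth) == length(pred),
            length(truth) == length(weights))
  sum(weights[pred != truth])
}

#' @rdname init_weights
#' @param err weighted error rate; clamped to
#'   `[1e-10, 1 - 1e-10]` before evaluation so perfect or hopeless learners
#'   yield large finite coefficients.
#' @param K number of classes; the `log(K - 1)` offset keeps the
#'   coefficient positive for weak multiclass learners (err below
#'   `(K-1)/K`-ish; exactly: alpha > 0 iff err < (K-1)/( (K-1) + 1/(K-1) )).
#' @return `alpha_coefficient()`: the learner coefficient (natural logs).
#' @export
alpha_coefficient <- function(err, K) {
  eps <- 1e-10
  err <- min(max(err, eps), 1 - eps)
  0.5 * log((1 - err) / err) + log(K - 1)
}

#' @rdname init_weights
#' @param alpha learner coefficient.
#' @param correct logical per-sample vector, `TRUE` where the learner
#'   classified the sample correctly.
#' @return `update_weights()`: new normalized weights, misclassified
#'   samples upweighted by `exp(alpha)`.
#' @export
update_weights <- function(weights, alpha, correct) {
  stopifnot(length(weights) == length(correct))
  unnorm <- weights * exp(alpha * as.numeric(!correct))
  total <- sum(unnorm)
  if (!is.finite(total) || total <= 0) {
    stop("degenerate weight update: unnormalized weights sum to ", total)
  }
  unnorm / total
}

#' Assemble an ensemble from explicit weak learners
#'
#' Constructor used for testing, for loading persisted models and for
#' composing hand-built ensembles. Learners are lists tagged by `type`:
#' `"constant"` (`class`), `"threshold"` (`feature`, `threshold`, `lo`,
#' `hi`: predicts `lo` where `x[, feature] <= threshold`), or `"nnet"`
#' (`dims`, `wts`, as produced by training).
#'
#' @param learners list of weak-learner objects.
#' @param alpha numeric coefficients, one per learner, finite.
#' @param classes ordered class set.
#' @param feature_length expected number of feature columns.
#' @param seed seed recorded with the model (informational).
#' @return A `cow_ensemble`.
#' @export
new_ensemble_model <- function(learners, alpha, classes = behavior_levels(),
                               feature_length = NA_integer_, seed = NULL) {
  if (length(learners) != length(alpha)) {
    stop("need exactly one coefficient per learner")
  }
  if (length(learners) < 1) stop("an ensemble needs at least one learner")
  if (any(!is.finite(alpha))) stop("coefficients must be finite")
  structure(
    list(learners = learners, alpha = as.numeric(alpha), K = length(classes),
         L = length(learners), classes = classes,
         feature_length = feature_length, seed = seed),
    class = "cow_ensemble"
  )
}

#' Predict behaviors with a boosted ensemble
#'
#' @param object a `cow_ensemble`.
#' @param x numeric feature matrix (or single feature vector).
#' @param type `"class"` for labels, `"votes"` for the per-class
#'   \eqn{\alpha}-weighted vote matrix.
#' @param ... unused.
#' @return Character label vector, or a numeric matrix of votes with one
#'   column per class.
#' @export
predict.cow_ensemble <- function(object, x, type = c("class", "votes"),
                                 ...) {
  type <- match.arg(type)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (!is.na(object$feature_length) &&
      ncol(x) != object$feature_length) {
    stop(sprintf("model expects %d features, got %d",
                 object$feature_length, ncol(x)))
  }
  votes <- matrix(0, nrow(x), object$K,
                  dimnames = list(NULL, object$classes))
  for (l in seq_len(object$L)) {
    pred <- predict_weak(object$learners[[l]], x)
    ki <- match(pred, object$classes)
    votes[cbind(seq_len(nrow(x)), ki)] <-
      votes[cbind(seq_len(nrow(x)), ki)] + object$alpha[l]
  }
  if (type == "votes") return(votes)
  object$classes[max.col(votes, ties.method = "first")]
}

#' @export
print.cow_ensemble <- function(x, ...) {
  cat(sprintf("<cow_ensemble> %d weak learners, %d classes\n", x$L, x$K))
  cat("  alpha:", paste(signif(x$alpha, 4), collapse = " "), "\n")
  if (!is.null(x$train_accuracy)) {
    cat(sprintf("  training accuracy: %.3f\n", x$train_accuracy))
  }
  invisible(x)
}

# ---- weak learners ---------------------------------------------------------

train_weak <- function(x, y, classes, config, seed = NULL) {
  type <- config$type %||% "nnet"
  if (length(unique(y)) < 2L) {
    return(list(type = "constant", class = y[1]))
  }
  if (type == "nnet") {
    size <- config$size %||% 10
    maxit <- config$maxit %||% 200
    yf <- factor(y, levels = classes)
    fit <- with_seed(seed, nnet::nnet(
      x, nnet::class.ind(yf), size = size, softmax = TRUE,
      maxit = maxit, trace = FALSE, MaxNWts = 100000
    ))
    list(type = "nnet", dims = c(ncol(x), size, length(classes)),
         wts = fit$wts, classes = classes)
  } else if (type == "threshold") {
    train_threshold_stump(x, y, classes)
  } else {
    stop("unknown weak learner type: ", type)
  }
}

# Exhaustive single-feature decision stump (majority class on each side of
# the best midpoint threshold). Mostly a fast, serializable learner for
# tests and small problems.
train_threshold_stump <- function(x, y, classes) {
  best <- NULL
  best_acc <- -1
  for (j in seq_len(ncol(x))) {
    cuts <- unique(stats::quantile(x[, j], probs = seq(0.1, 0.9, 0.1),
                                   names = FALSE))
    for (t in cuts) {
      left <- x[, j] <= t
      if (!any(left) || all(left)) next
      lo <- names(which.max(table(factor(y[left], levels = classes))))
      hi <- names(which.max(table(factor(y[!left], levels = classes))))
      acc <- mean(ifelse(left, lo, hi) == y)
      if (acc > best_acc) {
        best_acc <- acc
        best <- list(type = "threshold", feature = j, threshold = t,
                     lo = lo, hi = hi)
      }
    }
  }
  best %||% list(type = "constant", class = y[1])
}

predict_weak <- function(learner, x) {
  switch(learner$type,
    constant = rep(learner$class, nrow(x)),
    threshold = ifelse(x[, learner$feature] <= learner$threshold,
                       learner$lo, learner$hi),
    nnet = predict_weak_nnet(learner, x),
    fixed = learner$preds[seq_len(nrow(x))],
    stop("unknown weak learner type: ", learner$type)
  )
}

# Forward pass of a single-hidden-layer softmax network from its flat
# weight vector (nnet's layout: per hidden unit a bias + input weights,
# then per output unit a bias + hidden weights). argmax over the linear
# output layer equals argmax over the softmax.
predict_weak_nnet <- function(learner, x) {
  p <- learner$dims[1]; h <- learner$dims[2]; k <- learner$dims[3]
  stopifnot(length(learner$wts) == (p + 1) * h + (h + 1) * k)
  w_ih <- matrix(learner$wts[seq_len((p + 1) * h)], nrow = p + 1)
  w_ho <- matrix(learner$wts[-seq_len((p + 1) * h)], nrow = h + 1)
  hid <- 1 / (1 + exp(-(cbind(1, x) %*% w_ih)))
  out <- cbind(1, hid) %*% w_ho
  learner$classes[max.col(out, ties.method = "first")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- persistence -----------------------------------------------------------

#' Save and load a boosted ensemble as JSON
#'
#' The model file is a single structured JSON document holding the
#' coefficients, class set, seed, and every weak learner's parameters
#' (flat weight vector and layer dimensions for network learners).
#' Coefficients round-trip bit-exactly and loaded models reproduce the
#' saved model's predictions.
#'
#' @param model a `cow_ensemble`.
#' @param path JSON file path.
#' @export
save_ensemble <- function(model, path) {
  stopifnot(inherits(model, "cow_ensemble"))
  doc <- list(
    format = "cowsense-ensemble-1",
    K = model$K, L = model$L, alpha = model$alpha,
    classes = model$classes, feature_length = model$feature_length,
    seed = model$seed, train_accuracy = model$train_accuracy,
    learners = lapply(model$learners, function(g) {
      g[setdiff(names(g), "fit")]
    })
  )
  # I(17) = 17 significant digits, enough to round-trip doubles bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_ensemble
#' @return `load_ensemble()`: the reconstructed `cow_ensemble`.
#' @export
load_ensemble <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(doc$format, "cowsense-ensemble-1")) {
    stop("not a cowsense ensemble model file: ", path)
  }
  learners <- lapply(doc$learners, function(g) {
    g$dims <- as.integer(g$dims)
    g$wts <- as.numeric(g$wts)
    g$classes <- as.character(g$classes)
    if (g$type == "nnet" && length(g$wts) == 0) {
      stop("network learner without weights in ", path)
    }
    g
  })
  model <- new_ensemble_model(
    learners, as.numeric(doc$alpha), classes = as.character(doc$classes),
    feature_length = doc$feature_length %||% NA_integer_,
    seed = doc$seed
  )
  model$train_accuracy <- doc$train_accuracy
  model
}
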