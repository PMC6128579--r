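#' Confusion matrix of predicted vs observed behaviors
#'
#' Builds the square count table with rows = predicted and columns =
#' observed labels, in the order of `classes`. Predictions may include the
#' fusion stage's `"uncertain"` abstention, which adds an extra
#' `uncertain` row (never a column).
#'
#' @param truth observed labels, all in `classes`.
#' @param pred predicted labels, in `classes` or `"uncertain"`.
#' @param classes ordered class set (default the 7-behavior ethogram).
#' @return Integer matrix with dimnames `predicted` x `observed`.
#' @export
confusion_matrix <- function(truth, pred, classes = behavior_levels()) {
  if (length(truth) != length(pred)) {
    stop("truth and pred must have equal length")
  }
  if (!all(truth %in% classes)) stop("unknown label in truth")
  pred_classes <- classes
  if (any(pred == "uncertain")) pred_classes <- c(classes, "uncertain")
  if (!all(pred %in% pred_classes)) stop("unknown label in pred")
  cm <- table(factor(pred, levels = pred_classes),
              factor(truth, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(pred_classes),
              dimnames = list(predicted = pred_classes, observed = classes))
  m
}

#' Per-class accuracy, sensitivity and precision
#'
#' One-vs-rest reduction of a confusion matrix for `target_class`,
#' followed by the three standard ratios:
#' \deqn{Accuracy = (TP + TN) / (TP + FP + FN + TN)}
#' \deqn{Sensitivity = TP / (TP + FN)}
#' \deqn{Precision = TP / (TP + FP)}
#' where TP is the diagonal cell, FP the rest of the predicted row, FN the
#' rest of the observed column, and TN everything else. With
#' `exclude_uncertain = TRUE` the abstention row is removed from all
#' totals first (abstained samples are not scored at all); with `FALSE`
#' abstentions stay in the observed-column totals and therefore count
#' against sensitivity and accuracy.
#'
#' @param cm confusion matrix from [confusion_matrix()] (or any matrix
#'   with predicted rows / observed columns).
#' @param target_class the class to score.
#' @param exclude_uncertain drop the `uncertain` row before computing
#'   totals.
#' @return Named numeric `c(accuracy, sensitivity, precision)`;
#'   zero-denominator ratios are `NaN`.
#' @export
classwise_metrics <- function(cm, target_class, exclude_uncertain = FALSE) {
  if (!target_class %in% rownames(cm) || !target_class %in% colnames(cm)) {
    stop("class not in confusion matrix: ", target_class)
  }
  if (exclude_uncertain && "uncertain" %in% rownames(cm)) {
    cm <- cm[rownames(cm) != "uncertain", , drop = FALSE]
  }
  tp <- cm[target_class, target_class]
  fp <- sum(cm[target_class, ]) - tp
  fn <- sum(cm[, target_class]) - tp
  tn <- sum(cm) - tp - fp - fn
  ratio <- function(num, den) if (den == 0) NaN else num / den
  c(accuracy = ratio(tp + tn, tp + fp + fn + tn),
    sensitivity = ratio(tp, tp + fn),
    precision = ratio(tp, tp + fp))
}

#' Bootstrap mean and standard deviation of a metric
#'
#' Resamples the (observed, predicted) pairs with replacement `B` times,
#' recomputes `metric` on each resample, and returns the bootstrap mean
#' and sample standard deviation --- the "mean +/- S.D." form used to
#' report classifier performance.
#'
#' @param truth,pred label vectors of equal length.
#' @param metric function `(truth, pred) -> number`, e.g. a wrapper
#'   around [classwise_metrics()].
#' @param B number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return Named numeric `c(mean, sd)`.
#' @export
bootstrap_summary <- function(truth, pred, metric, B = 1000, seed = NULL) {
  n <- length(truth)
  if (n < 1) stop("cannot bootstrap an empty sample")
  if (length(pred) != n) stop("truth and pred must have equal length")
  if (B < 1) stop("B must be >= 1")
  vals <- with_seed(seed, vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    metric(truth[idx], pred[idx])
  }, numeric(1)))
  c(mean = mean(vals), sd = stats::sd(vals))
}

#' Full metrics report for a set of predictions
#'
#' Per-class accuracy, sensitivity and precision with bootstrap standard
#' deviations, in one data.frame --- the tabular summary printed for each
#' evaluation stage.
#'
#' @param truth,pred label vectors.
#' @param classes ordered class set.
#' @param exclude_uncertain passed to [classwise_metrics()]; abstained
#'   samples are also removed from the bootstrap population when `TRUE`.
#' @param B bootstrap resamples; `B = 0` skips the bootstrap (SD columns
#'   `NA`).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame with columns `class, accuracy, accuracy_sd,
#'   sensitivity, sensitivity_sd, precision, precision_sd`.
#' @export
metrics_report <- function(truth, pred, classes = behavior_levels(),
                           exclude_uncertain = FALSE, B = 1000,
                           seed = NULL) {
  if (exclude_uncertain) {
    keep <- pred != "uncertain"
    truth <- truth[keep]
    pred <- pred[keep]
  }
  rows <- lapply(seq_along(classes), function(ci) {
    cl <- classes[ci]
    point <- classwise_metrics(confusion_matrix(truth, pred, classes), cl)
    sds <- rep(NA_real_, 3)
    if (B > 0) {
      sds <- vapply(1:3, function(k) {
        bootstrap_summary(truth, pred, function(tt, pp) {
          classwise_metrics(confusion_matrix(tt, pp, classes), cl)[k]
        }, B = B, seed = derive_seed(seed, 100 * ci + k))[["sd"]]
      }, numeric(1))
    }
    data.frame(class = cl,
               accuracy = point[["accuracy"]], accuracy_sd = sds[1],
               sensitivity = point[["sensitivity"]], sensitivity_sd = sds[2],
               precision = point[["precision"]], precision_sd = sds[3])
  })
  do.call(rbind, rows)
}

#' Render a confusion matrix as aligned plain text
#'
#' @param cm a [confusion_matrix()].
#' @return Character scalar with one line per predicted class plus header
#'   and marginal totals.
#' @export
format_confusion <- function(cm) {
  m <- rbind(cm, total = colSums(cm))
  m <- cbind(m, total = rowSums(m))
  txt <- utils::capture.output(print(m))
  paste(txt, collapse = "\n")
}
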