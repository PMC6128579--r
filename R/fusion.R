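#' Mass functions over the feeding/standing frame
#'
#' The evidence-fusion stage reasons over the frame of discernment
#' Theta = \{feeding, standing\}. A basic probability assignment (BPA)
#' here puts mass on \{Feeding\}, \{Standing\} and the whole frame
#' \{feeding, standing\} ("Uncertainty", the evidence's inability to tell
#' the two apart); the empty set carries mass 0 by construction and the
#' three masses sum to 1.
#'
#' @param feeding,standing,uncertainty nonnegative masses summing to 1.
#' @return Named numeric vector of class `mass_function`.
#' @examples
#' mass_function(0.5, 0.4, 0.1)
#' @export
mass_function <- function(feeding, standing, uncertainty) {
  m <- c(feeding = feeding, standing = standing, uncertainty = uncertainty)
  if (any(!is.finite(m)) || any(m < -1e-12)) {
    stop("masses must be finite and nonnegative")
  }
  if (abs(sum(m) - 1) > 1e-9) {
    stop("masses must sum to 1 (got ", format(sum(m)), ")")
  }
  structure(pmax(m, 0), class = "mass_function")
}

#' Fusion-stage configuration
#'
#' Thresholds and geometry constants of the feeding/standing decision:
#' `eps1` is the minimum margin by which the winning mass must exceed the
#' other behavior's mass, `eps2` the maximum tolerated uncertainty mass;
#' `body_length` is the average length of a cow's body excluding the head
#' (a hind leg at this distance from the headlocks indicates feeding),
#' `error_max` the worst mean positioning error of the localization system
#' (it widens the feeding-compatible zone), and `area_width` the width of
#' the studied area (the largest possible headlock distance).
#'
#' @param eps1 decision margin threshold (default 0.2).
#' @param eps2 uncertainty threshold (default 0.03); must satisfy
#'   `eps1 > eps2 > 0`.
#' @param body_length meters (default 1.5).
#' @param error_max meters (default 1.30).
#' @param area_width meters (default 13).
#' @return list of class `fusion_config`.
#' @export
fusion_config <- function(eps1 = 0.2, eps2 = 0.03, body_length = 1.5,
                          error_max = 1.30, area_width = 13) {
  if (!(eps1 > eps2 && eps2 > 0)) stop("need eps1 > eps2 > 0")
  if (!(body_length > 0 && body_length + error_max < area_width)) {
    stop("need 0 < body_length < body_length + error_max < area_width")
  }
  structure(list(eps1 = eps1, eps2 = eps2, body_length = body_length,
                 error_max = error_max, area_width = area_width),
            class = "fusion_config")
}

#' Classifier evidence BPA
#'
#' The first evidence source: the accelerometer classifier's verdict on
#' the confusable pair. The predicted behavior receives mass 0.5, the
#' other 0.4, and 0.1 remains on the frame, reflecting the classifier's
#' known weakness on these two behaviors.
#'
#' @param predicted_label `"feeding"` or `"standing"` (other behaviors do
#'   not enter fusion).
#' @return A [mass_function()] (`m1`).
#' @export
bpa_from_classifier <- function(predicted_label) {
  if (identical(predicted_label, "feeding")) {
    mass_function(0.5, 0.4, 0.1)
  } else if (identical(predicted_label, "standing")) {
    mass_function(0.4, 0.5, 0.1)
  } else {
    stop("fusion applies only to feeding/standing; got ",
         paste(predicted_label, collapse = ", "))
  }
}

#' Position evidence BPA
#'
#' The second evidence source: the perpendicular distance `D` of the hind
#' leg to the headlocks. Mass 0.9 is split between feeding and standing by
#' piecewise-linear interpolation over three intervals, with 0.1 always on
#' the frame:
#'
#' * `0 < D <= body_length`: feeding mass rises linearly from 0 at `D = 0`
#'   (leg against the barrier: the cow is parallel to or facing away from
#'   it, hence standing) to 0.9 at `D = body_length` (the feeding
#'   posture).
#' * `body_length < D <= body_length + error_max`: feeding mass falls
#'   linearly back to 0 across the localization-error margin.
#' * `D > body_length + error_max`: too far to feed; `(0, 0.9, 0.1)`.
#'
#' `D = 0` is assigned the first interval's limit `(0, 0.9, 0.1)`.
#'
#' @param d_head perpendicular headlock distance (m), in
#'   `[0, area_width]`.
#' @param config a [fusion_config()].
#' @return A [mass_function()] (`m2`).
#' @export
bpa_from_position <- function(d_head, config = fusion_config()) {
  if (!is.finite(d_head) || d_head < 0 || d_head > config$area_width) {
    stop("d_head must lie in [0, ", config$area_width, "] m")
  }
  bl <- config$body_length
  em <- config$error_max
  if (d_head <= bl) {
    frac <- (bl - d_head) / bl
    mass_function((1 - frac) * 0.9, frac * 0.9, 0.1)
  } else if (d_head <= bl + em) {
    frac <- (d_head - bl) / em
    mass_function((1 - frac) * 0.9, frac * 0.9, 0.1)
  } else {
    mass_function(0, 0.9, 0.1)
  }
}

#' Dempster's rule of combination
#'
#' Combines two BPAs over the feeding/standing frame: agreeing focal
#' elements multiply (`k1` collects the products supporting feeding, `k2`
#' standing, `k3` joint uncertainty) and the result is renormalized by the
#' total non-conflicting mass `K = k1 + k2 + k3`. The operator is
#' commutative and associative; total conflict (`K = 0`) means the
#' evidence cannot be combined and is an error.
#'
#' @param m1,m2 [mass_function()] objects.
#' @return The combined [mass_function()] `m1 (+) m2`.
#' @export
dempster_combine <- function(m1, m2) {
  stopifnot(inherits(m1, "mass_function"), inherits(m2, "mass_function"))
  k1 <- m1[["feeding"]] * m2[["feeding"]] +
    m1[["feeding"]] * m2[["uncertainty"]] +
    m2[["feeding"]] * m1[["uncertainty"]]
  k2 <- m1[["standing"]] * m2[["standing"]] +
    m1[["standing"]] * m2[["uncertainty"]] +
    m2[["standing"]] * m1[["uncertainty"]]
  k3 <- m1[["uncertainty"]] * m2[["uncertainty"]]
  K <- k1 + k2 + k3
  if (K <= 0) {
    stop("total conflict between evidence sources (K = 0): not combinable")
  }
  mass_function(k1 / K, k2 / K, k3 / K)
}

#' Decide feeding vs standing from combined evidence
#'
#' Declares feeding when the fused feeding mass exceeds the standing mass
#' by more than `eps1`, the uncertainty mass is below `eps2`, and the
#' feeding mass exceeds the uncertainty mass; symmetrically for standing.
#' If neither rule fires the sample is `"uncertain"` and is flagged for
#' exclusion from downstream statistics.
#'
#' @param m a combined [mass_function()].
#' @param config a [fusion_config()].
#' @return `"feeding"`, `"standing"` or `"uncertain"`.
#' @export
decide_behavior <- function(m, config = fusion_config()) {
  stopifnot(inherits(m, "mass_function"))
  f <- m[["feeding"]]; s <- m[["standing"]]; u <- m[["uncertainty"]]
  if (f > config$eps1 + s && u < config$eps2 && f > u) return("feeding")
  if (s > config$eps1 + f && u < config$eps2 && s > u) return("standing")
  "uncertain"
}

#' Second-stage reclassification of feeding/standing predictions
#'
#' Applies the full evidence-fusion chain to a vector of first-stage
#' predictions: labels other than feeding/standing pass through unchanged;
#' feeding/standing predictions are combined with their position evidence
#' (headlock distance) and re-decided. Abstentions are kept in the output
#' with `flag_uncertain = TRUE` rather than dropped, so callers control
#' their exclusion.
#'
#' @param first_stage_labels character vector of 7-class predictions.
#' @param d_head numeric vector of headlock distances (m), same length;
#'   may be `NA` for rows that are not feeding/standing.
#' @param config a [fusion_config()].
#' @return data.frame `first_stage_label, d_head, m_feeding, m_standing,
#'   m_uncertainty, final_label, flag_uncertain`.
#' @export
reclassify <- function(first_stage_labels, d_head,
                       config = fusion_config()) {
  n <- length(first_stage_labels)
  if (length(d_head) != n) {
    stop("first_stage_labels and d_head must have equal length")
  }
  out <- data.frame(
    first_stage_label = first_stage_labels,
    d_head = d_head,
    m_feeding = NA_real_, m_standing = NA_real_, m_uncertainty = NA_real_,
    final_label = first_stage_labels,
    flag_uncertain = FALSE,
    stringsAsFactors = FALSE
  )
  idx <- which(first_stage_labels %in% confusable_pair())
  for (i in idx) {
    if (is.na(d_head[i])) {
      stop("missing headlock distance for fused sample ", i)
    }
    m <- dempster_combine(bpa_from_classifier(first_stage_labels[i]),
                          bpa_from_position(d_head[i], config))
    out$m_feeding[i] <- m[["feeding"]]
    out$m_standing[i] <- m[["standing"]]
    out$m_uncertainty[i] <- m[["uncertainty"]]
    verdict <- decide_behavior(m, config)
    out$final_label[i] <- verdict
    out$flag_uncertain[i] <- verdict == "uncertain"
  }
  out
}
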