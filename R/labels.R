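#' The seven recognized cow behaviors
#'
#' The behavior ethogram used throughout the package. Seven mutually
#' exclusive behavior categories are recognized from a leg-mounted tag:
#' three inactive behaviors (feeding, lying, standing: little or no leg
#' movement), two posture transitions (lying down, standing up: 3--8 s
#' events), and two gaits (normal walking: at least one stride per second;
#' active walking: at least two forward strides per second).
#'
#' Labels are plain character strings; integer codes 1..7 index the same
#' classes in the fixed order returned by `behavior_levels()`.
#'
#' @return `behavior_levels()`: character vector of the 7 labels, in code
#'   order.
#' @examples
#' behavior_levels()
#' behavior_code("standing")
#' behavior_from_code(1:7)
#' @export
behavior_levels <- function() {
  c("feeding", "lying", "standing", "lying_down", "standing_up",
    "normal_walking", "active_walking")
}

#' @rdname behavior_levels
#' @param label character vector of behavior labels.
#' @return `behavior_code()`: integer codes in 1..7.
#' @export
behavior_code <- function(label) {
  code <- match(label, behavior_levels())
  if (anyNA(code) && !anyNA(label)) {
    bad <- unique(label[is.na(code)])
    stop("unknown behavior label(s): ", paste(bad, collapse = ", "))
  }
  code
}

#' @rdname behavior_levels
#' @param code integer vector of codes in 1..7.
#' @return `behavior_from_code()`: character labels.
#' @export
behavior_from_code <- function(code) {
  if (any(code < 1 | code > 7, na.rm = TRUE)) {
    stop("behavior codes must lie in 1..7")
  }
  behavior_levels()[code]
}

# The pair a leg tag cannot tell apart; only these enter evidence fusion.
confusable_pair <- function() c("feeding", "standing")

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. `seed = NULL` runs unseeded.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed below 2^31 from a master seed and a stream index.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + 97 * stream) %% 2147483587)
}

# Round half away from zero to `digits` decimals (printed-table convention;
# base round() is half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
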