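# Shared builders for in-code fixtures.

make_samples <- function(duration, base = c(0, 0, 1), t0 = 0) {
  data.frame(timestamp = seq(t0, t0 + duration - 1),
             ax = base[1], ay = base[2], az = base[3])
}

make_obs <- function(duration, label = "standing", tag = "tag1",
                     base = c(0, 0, 1), t0 = 0) {
  observation(tag, make_samples(duration, base, t0), label)
}

# n random valid mass functions, reproducibly
random_masses <- function(n, seed) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    w <- stats::runif(3)
    w <- w / sum(w)
    mass_function(w[1], w[2], w[3])
  }))
}

# independent re-statement of the weak learner semantics used by the
# vote-tally oracle (kept deliberately separate from the package internals)
oracle_weak_predict <- function(learner, x) {
  if (learner$type == "constant") {
    rep(learner$class, nrow(x))
  } else if (learner$type == "threshold") {
    ifelse(x[, learner$feature] <= learner$threshold, learner$lo, learner$hi)
  } else {
    stop("oracle only understands constant/threshold learners")
  }
}

oracle_vote_tally <- function(model, x) {
  sapply(seq_len(nrow(x)), function(i) {
    votes <- stats::setNames(numeric(length(model$classes)), model$classes)
    for (l in seq_along(model$learners)) {
      p <- oracle_weak_predict(model$learners[[l]], x[i, , drop = FALSE])
      votes[p] <- votes[p] + model$alpha[l]
    }
    model$classes[which(votes == max(votes))[1]]  # smallest code on ties
  })
}
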