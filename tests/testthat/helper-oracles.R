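# Independent brute-force oracles: literal double-loop transcriptions of the
# defining formulas, deliberately unvectorized and kept free of any package
# internals.

# Weighted Cox partial log-likelihood, nested loops, Breslow risk sets.
oracle_loglik <- function(beta, times, events, x, w) {
  ll <- 0
  n <- length(times)
  for (i in seq_len(n)) {
    if (events[i] == 1 && w[i] > 0) {
      den <- 0
      for (k in seq_len(n)) {
        if (times[i] <= times[k])
          den <- den + w[k] * exp(sum(beta * x[k, ]))
      }
      ll <- ll + w[i] * (sum(beta * x[i, ]) - log(den))
    }
  }
  ll
}

# Harrell C-index by exhaustive pair enumeration with the printed usable-pair
# rules: a pair (i, i*) is usable iff delta_i = 1 and t_{i*} > t_i.
oracle_cindex <- function(times, events, scores) {
  num <- 0
  n_c <- 0
  n <- length(times)
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    for (j in seq_len(n)) {
      if (times[j] > times[i]) {
        n_c <- n_c + 1
        if (scores[j] < scores[i]) num <- num + 1
        else if (scores[j] == scores[i]) num <- num + 0.5
      }
    }
  }
  if (n_c == 0) stop("no usable pairs")
  num / n_c
}

# AUC by exhaustive pair counting (Mann-Whitney with half credit for ties).
oracle_auc <- function(score, positive) {
  pos <- which(positive)
  neg <- which(!positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    if (score[i] > score[j]) tot <- tot + 1
    else if (score[i] == score[j]) tot <- tot + 0.5
  }
  tot / (length(pos) * length(neg))
}

# Small random survival dataset with S balanced subgroups.
random_survdata <- function(n = 20, p = 3, S = 2, seed = 1,
                            tie_times = FALSE) {
  withr::with_seed(seed, {
    times <- if (tie_times) sample(1:max(3, n %/% 2), n, replace = TRUE)
             else rexp(n) + 0.1
    events <- rbinom(n, 1, 0.6)
    if (sum(events) == 0) events[1] <- 1L
    subgroup_surv(times = times, events = events,
                  subgroups = rep_len(seq_len(S), n),
                  covariates = matrix(rnorm(n * p), n, p))
  })
}

# Deterministic, row-order-invariant toy classifier for exercising the
# out-of-fold machinery without classifier randomness: class probabilities
# proportional to exp(-distance to the class centroid).
centroid_classifier <- function(x, y) {
  classes <- sort(unique(y))
  centers <- t(sapply(classes, function(s) colMeans(x[y == s, , drop = FALSE])))
  function(newx) {
    d <- sapply(seq_along(classes), function(ci)
      rowSums(sweep(newx, 2, centers[ci, ])^2))
    d <- matrix(d, nrow = nrow(newx))
    pr <- exp(-d / (2 * max(d)))
    pr / rowSums(pr)
  }
}
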