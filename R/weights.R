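# Individual subgroup weights as classification-based probability ratios:
# w_s(y, x) = p(s | y, x) / p(s). The conditional class probabilities are
# estimated out-of-fold by multi-class classification on (x, log t, delta),
# the prior p(s) by the relative subgroup frequency.

# Feature matrix handed to the classifiers: covariates plus the survival
# response, with time entered on the log scale.
classifier_features <- function(data) {
  cbind(data$covariates, log_time = log(data$times), event = data$events)
}

fit_class_model <- function(classifier, x, y, S, seed, n_inner_folds = 10) {
  if (is.function(classifier)) return(classifier(x, y))
  switch(classifier,
    lasso = ,
    ridge = {
      inner <- make_folds(y, n_inner_folds, seed)
      cvfit <- glmnet::cv.glmnet(x, factor(y, levels = seq_len(S)),
                                 family = "multinomial",
                                 alpha = if (classifier == "lasso") 1 else 0,
                                 foldid = inner, type.measure = "deviance")
      function(newx) {
        pr <- stats::predict(cvfit, newx = newx, s = "lambda.min",
                             type = "response")
        matrix(pr, nrow = nrow(newx), ncol = S)
      }
    },
    rf = {
      rf <- ranger::ranger(x = x, y = factor(y, levels = seq_len(S)),
                           probability = TRUE, num.trees = 500,
                           seed = seed, num.threads = 1)
      function(newx) {
        pr <- stats::predict(rf, data = newx, num.threads = 1)$predictions
        pr[, as.character(seq_len(S)), drop = FALSE]
      }
    },
    stop("validation error: unknown classifier")
  )
}

#' Out-of-fold subgroup membership probabilities
#'
#' Estimates \eqn{p(s \mid y, x)} by K-fold cross-validated multi-class
#' classification: entry `(i, s)` is the probability predicted for patient `i`
#' by the fold model that did not see patient `i`, preventing overfitting of
#' the weights. Classifier features are the covariates augmented by the
#' response (log observed time and event indicator).
#'
#' @param data A [subgroup_surv] object with `S >= 2` subgroups.
#' @param classifier `"lasso"` / `"ridge"` (multinomial logistic regression
#'   with the respective penalty, tuned by its own internal 10-fold CV inside
#'   each outer fold), `"rf"` (probability random forest, 500 trees), or a
#'   function `f(x, y)` returning a prediction function `g(newx)` that yields
#'   an `nrow(newx) x S` probability matrix (used for testing and extensions).
#' @param n_folds Number of outer folds (default 10).
#' @param seed Integer seed; fold assignment and classifier randomness are
#'   deterministic given it.
#' @param foldid Optional explicit outer fold assignment (length `n`,
#'   values in `1..n_folds`); overrides the seeded assignment. Folds are
#'   otherwise stratified by subgroup.
#' @return An `n x S` matrix of out-of-fold probabilities; rows sum to 1.
#' @export
estimate_subgroup_probs <- function(data, classifier = c("lasso", "ridge", "rf"),
                                    n_folds = 10, seed = 1, foldid = NULL) {
  stopifnot(inherits(data, "subgroup_surv"))
  if (data$S < 2) stop("validation error: at least two subgroups required")
  if (is.character(classifier)) classifier <- match.arg(classifier)
  x <- classifier_features(data)
  if (is.null(foldid)) {
    foldid <- make_folds(data$subgroups, n_folds, derive_seed(seed, 1L))
    # every fold's training part must contain all S labels; refold once
    ok <- function(fid) all(vapply(seq_len(n_folds), function(k)
      length(unique(data$subgroups[fid != k])) == data$S, logical(1)))
    if (!ok(foldid)) {
      foldid <- make_folds(data$subgroups, n_folds, derive_seed(seed, 2L))
      if (!ok(foldid))
        stop("fit error: a fold's training part misses a subgroup label even after refolding")
    }
  } else {
    if (length(foldid) != data$n)
      stop("dimension mismatch: foldid must have length n")
    n_folds <- max(foldid)
  }
  probs <- matrix(NA_real_, data$n, data$S,
                  dimnames = list(NULL, paste0("s", seq_len(data$S))))
  for (k in sort(unique(foldid))) {
    tr <- which(foldid != k)
    te <- which(foldid == k)
    if (length(unique(data$subgroups[tr])) < data$S)
      stop("fit error: fold training part misses a subgroup label")
    pred <- fit_class_model(classifier, x[tr, , drop = FALSE],
                            data$subgroups[tr], data$S,
                            seed = derive_seed(seed, 100L + k))
    probs[te, ] <- pred(x[te, , drop = FALSE])
  }
  probs
}

#' Turn class probabilities into a per-patient weight matrix
#'
#' Column `s` holds the weights for the subgroup-`s` model:
#' \eqn{w_s(y, x) = \hat p(s \mid y, x) / \hat p(s)}, with the prior
#' \eqn{\hat p(s)} the relative frequency of subgroup `s`. Weights are
#' nonnegative but not constrained to `(0, 1)`; the small-subgroup columns can
#' exceed 1 substantially. No truncation or renormalization is applied here —
#' the Cox fitter rescales whatever weights it receives to sum to `n`.
#'
#' @param prob_matrix `n x S` probability matrix (rows summing to 1), e.g.
#'   from [estimate_subgroup_probs()].
#' @param subgroups Integer labels in `1..S`, length `n`; every label must
#'   occur (so that every prior is positive).
#' @param classifier Optional label recorded on the result.
#' @return A `weight_matrix` object: list with `values` (`n x S`),
#'   `prob_matrix`, `priors` (length `S`) and `classifier`.
#' @export
compute_weight_matrix <- function(prob_matrix, subgroups, classifier = NULL) {
  prob_matrix <- as.matrix(prob_matrix)
  S <- ncol(prob_matrix)
  if (length(subgroups) != nrow(prob_matrix))
    stop("dimension mismatch: subgroups must match prob_matrix rows")
  if (any(prob_matrix < 0) || any(abs(rowSums(prob_matrix) - 1) > 1e-6))
    stop("validation error: prob_matrix rows must be probabilities summing to 1")
  counts <- tabulate(as.integer(subgroups), nbins = S)
  if (any(counts == 0))
    stop("validation error: empty subgroup (every prior p(s) must be > 0)")
  priors <- counts / sum(counts)
  values <- sweep(prob_matrix, 2, priors, "/")
  structure(list(values = values, prob_matrix = prob_matrix,
                 priors = priors, classifier = classifier),
            class = "weight_matrix")
}

#' Estimate the full weight matrix from training data
#'
#' Convenience wrapper: [estimate_subgroup_probs()] followed by
#' [compute_weight_matrix()].
#'
#' @inheritParams estimate_subgroup_probs
#' @return A `weight_matrix` object.
#' @export
estimate_weights <- function(data, classifier = c("lasso", "ridge", "rf"),
                             n_folds = 10, seed = 1, foldid = NULL) {
  pm <- estimate_subgroup_probs(data, classifier, n_folds = n_folds,
                                seed = seed, foldid = foldid)
  compute_weight_matrix(pm, data$subgroups,
                        classifier = if (is.character(classifier))
                          classifier[1] else "custom")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("weight_matrix: %d patients x %d subgroups (classifier: %s)\n",
              nrow(x$values), ncol(x$values), x$classifier %||% "?"))
  cat("  priors:", paste(sprintf("%.3f", x$priors), collapse = ", "), "\n")
  cat("  column means:",
      paste(sprintf("%.3f", colMeans(x$values)), collapse = ", "), "\n")
  invisible(x)
}

# Mann-Whitney AUC with midrank tie handling.
auc_rank <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("validation error: both groups must be nonempty")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Group-separation AUC of the subgroup classifier
#'
#' Measures how well the out-of-fold class probabilities discriminate two
#' latent groups of subgroups: each patient is scored by the sum of its
#' probabilities over the subgroups mapped to group 1, and the AUC of that
#' score for group-1 vs group-2 membership is returned (0.5 = no
#' discrimination, 1 = perfect separation).
#'
#' @inheritParams estimate_subgroup_probs
#' @param group_map Integer vector of length `S` mapping each subgroup label
#'   to group 1 or 2.
#' @param prob_matrix Optional precomputed out-of-fold probability matrix.
#' @return AUC in `[0, 1]`.
#' @export
group_separation_auc <- function(data, group_map, classifier = "rf",
                                 n_folds = 10, seed = 1, prob_matrix = NULL) {
  stopifnot(inherits(data, "subgroup_surv"))
  if (length(group_map) != data$S || !all(group_map %in% c(1, 2)))
    stop("validation error: group_map must map each of the S labels to group 1 or 2")
  g <- group_map[data$subgroups]
  if (length(unique(g)) < 2)
    stop("validation error: both groups must be nonempty")
  pm <- prob_matrix %||%
    estimate_subgroup_probs(data, classifier, n_folds = n_folds, seed = seed)
  score <- rowSums(pm[, which(group_map == 1), drop = FALSE])
  auc_rank(score, g == 1)
}

#' Write / read a weight matrix as CSV with a JSON sidecar
#'
#' The CSV has `n` rows and `S` named columns of weights; the sidecar stores
#' classifier, seed and priors.
#'
#' @param wm A `weight_matrix`.
#' @param file Output CSV path.
#' @param seed Seed to record (optional).
#' @export
write_weight_matrix <- function(wm, file, seed = NULL) {
  utils::write.csv(as.data.frame(wm$values), file, row.names = FALSE)
  jsonlite::write_json(list(classifier = wm$classifier, seed = seed,
                            priors = wm$priors),
                       paste0(sub("\\.[^.]*$", "", file), ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
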