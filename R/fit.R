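# Lasso-penalized weighted Cox fitting. The solver is glmnet's coordinate
# descent for the Cox family (Breslow ties, observation weights); everything
# around it -- weight normalization, the CV deviance for lambda selection,
# model construction -- lives here.

normalize_weights <- function(weights, n) {
  if (length(weights) != n)
    stop("dimension mismatch: weights must have length n")
  if (anyNA(weights) || any(weights < 0) || any(!is.finite(weights)))
    stop("validation error: weights must be finite and nonnegative")
  tot <- sum(weights)
  if (tot <= 0) stop("fit error: all weights are zero")
  weights * (n / tot)
}

# glmnet warns when it truncates an ill-conditioned path deep end; the
# truncation is handled explicitly wherever paths are consumed, so those
# warnings are muffled (anything else propagates).
quiet_path <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("lambda value", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

# glmnet refuses a single-column x; pad with a zero column and drop it again.
glmnet_x <- function(x) {
  if (ncol(x) >= 2) return(list(x = x, pad = FALSE))
  list(x = cbind(x, .pad. = 0), pad = TRUE)
}

#' Fit a weighted lasso-penalized Cox model at a fixed penalty
#'
#' Maximizes the weighted Cox partial log-likelihood (see
#' [weighted_cox_loglik()]) minus the lasso penalty
#' \eqn{\lambda \sum_j |\beta_j|}. Input weights are rescaled internally to
#' sum to the sample size `n`, so multiplying all weights by a positive
#' constant does not change the fit; covariates are standardized internally
#' (weighted mean/variance) and coefficients are reported on the original
#' scale. A patient with weight 0 has no influence on the fit.
#'
#' @param data A [subgroup_surv] object.
#' @param weights Nonnegative weight vector of length `n`.
#' @param lambda Nonnegative penalty level (on the glmnet scale, i.e. relative
#'   to the average weighted log-likelihood).
#' @param thresh,maxit Coordinate-descent convergence tolerance and maximum
#'   number of passes, passed to [glmnet::glmnet()].
#' @return An object of class `cox_lasso_fit` with elements `coefficients`
#'   (length `p`, named, exact zeros below the `1e-12` threshold), `lambda`,
#'   `weights_used` (post-normalization, summing to `n`), `cv_curve` (filled
#'   by [fit_model()] when lambda came from cross-validation, else `NULL`)
#'   and `n_nonzero`.
#' @export
fit_weighted_cox_lasso <- function(data, weights, lambda,
                                   thresh = 1e-7, maxit = 1e5) {
  stopifnot(inherits(data, "subgroup_surv"))
  if (length(lambda) != 1 || !is.finite(lambda) || lambda < 0)
    stop("validation error: lambda must be a single nonnegative number")
  wn <- normalize_weights(weights, data$n)
  if (sum(data$events * wn) <= 0)
    stop("fit error: no usable events (all events have weight zero)")
  y <- survival::Surv(data$times, data$events)
  gx <- glmnet_x(data$covariates)
  fit <- quiet_path(glmnet::glmnet(gx$x, y, family = "cox", weights = wn,
                                   standardize = TRUE, thresh = thresh,
                                   maxit = maxit))
  cf <- quiet_path(glmnet::coef.glmnet(fit, s = lambda, exact = TRUE,
                                       x = gx$x, y = y, weights = wn,
                                       standardize = TRUE, thresh = thresh,
                                       maxit = maxit))
  beta <- drop(as.matrix(cf))
  if (gx$pad) beta <- beta[seq_len(data$p)]
  beta[abs(beta) < 1e-12] <- 0
  names(beta) <- colnames(data$covariates)
  structure(list(coefficients = beta, lambda = lambda, weights_used = wn,
                 cv_curve = NULL, n_nonzero = sum(beta != 0),
                 mode = NULL, target_subgroup = NULL, S = data$S,
                 classifier = NULL),
            class = "cox_lasso_fit")
}

#' @export
print.cox_lasso_fit <- function(x, ...) {
  cat(sprintf("cox_lasso_fit: %d of %d coefficients nonzero, lambda = %.5g\n",
              x$n_nonzero, length(x$coefficients), x$lambda))
  if (!is.null(x$mode))
    cat(sprintf("  model: %s%s, target subgroup %s\n", x$mode,
                if (!is.null(x$classifier)) paste0(" (", x$classifier, ")") else "",
                x$target_subgroup %||% "-"))
  invisible(x)
}

# Evaluate the weighted partial log-likelihood for every column of a
# coefficient matrix (p x L). Shared order/rank bookkeeping across columns.
loglik_path <- function(beta_mat, data, weights) {
  eta_mat <- data$covariates %*% beta_mat
  dw <- data$events * weights
  ord <- order(data$times, decreasing = TRUE)
  nge <- findInterval(-data$times, -data$times[ord])
  idx <- dw > 0
  apply(eta_mat, 2, function(eta) {
    if (!any(idx)) return(0)
    m <- max(eta)
    cs <- cumsum((weights * exp(eta - m))[ord])
    sum(dw[idx] * (eta[idx] - (m + log(cs[nge[idx]]))))
  })
}

#' Select the lasso penalty by cross-validated partial-likelihood deviance
#'
#' Builds the automatic decreasing log-spaced lambda grid (100 values from the
#' smallest all-zero-solution lambda down to a ratio of `1e-2` when
#' \eqn{n \le p}, `1e-4` otherwise) and evaluates each lambda by K-fold
#' cross-validation with the Verweij--van Houwelingen partial-likelihood
#' deviance: for fold k, \eqn{-2\{l(\hat\beta_{-k}) - l_{-k}(\hat\beta_{-k})\}}
#' where \eqn{l} is the weighted log-likelihood on the full data and
#' \eqn{l_{-k}} on the training part, so held-out patients keep their weights.
#' Folds are stratified by the event indicator and deterministic given `seed`.
#' The returned lambda minimizes the summed deviance.
#'
#' @inheritParams fit_weighted_cox_lasso
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @return The selected lambda (a member of the grid), with attribute
#'   `cv_curve`: a data.frame of `(lambda, deviance)` pairs.
#' @export
select_lambda_cv <- function(data, weights, n_folds = 10, seed = 1) {
  stopifnot(inherits(data, "subgroup_surv"))
  if (n_folds < 2) stop("validation error: n_folds must be at least 2")
  wn <- normalize_weights(weights, data$n)
  if (sum(data$events * wn) <= 0)
    stop("fit error: no usable events (all events have weight zero)")
  y <- survival::Surv(data$times, data$events)
  gx <- glmnet_x(data$covariates)
  full <- quiet_path(glmnet::glmnet(gx$x, y, family = "cox", weights = wn,
                                    standardize = TRUE))
  grid <- full$lambda
  # Folds are assigned over positive-weight rows only (stratified by event
  # indicator); zero-weight rows contribute nothing to any fit or deviance,
  # so they are parked in fold 1. This makes the fold partition of a
  # zero-weighted model coincide with that of the corresponding row-subset
  # model under the same seed.
  pos <- wn > 0
  foldid <- rep(1L, data$n)
  foldid[pos] <- make_folds(data$events[pos], n_folds, seed)
  dev <- rep(0, length(grid))
  used <- 0L
  for (k in seq_len(n_folds)) {
    tr <- which(foldid != k)
    if (sum((data$events * wn)[tr]) <= 0) {
      warning(sprintf("fold %d skipped: no weighted events in its training part", k))
      next
    }
    fit_k <- tryCatch(
      quiet_path(glmnet::glmnet(gx$x[tr, , drop = FALSE], y[tr, , drop = FALSE],
                                family = "cox", weights = wn[tr],
                                standardize = TRUE, lambda = grid)),
      error = function(e) {
        warning(sprintf("fold %d training fit failed (%s); using the null model for this fold",
                        k, conditionMessage(e)))
        NULL
      })
    bmat <- if (is.null(fit_k)) matrix(0, data$p, length(grid))
            else as.matrix(fit_k$beta)
    if (!is.null(fit_k) && gx$pad) bmat <- bmat[seq_len(data$p), , drop = FALSE]
    if (ncol(bmat) < length(grid))  # path truncated by the solver
      bmat <- cbind(bmat, bmat[, rep(ncol(bmat), length(grid) - ncol(bmat)),
                               drop = FALSE])
    l_full <- loglik_path(bmat, data, wn)
    l_train <- loglik_path(bmat, subset_rows(data, tr), wn[tr])
    dev <- dev + (-2) * (l_full - l_train)
    used <- used + 1L
  }
  if (used == 0L) stop("fit error: all cross-validation folds were skipped")
  best <- grid[which.min(dev)]
  attr(best, "cv_curve") <- data.frame(lambda = grid, deviance = dev)
  best
}

#' Fixed subgroup down-weighting
#'
#' The fixed-weight baseline: patients of the target subgroup get weight 1,
#' everyone else the constant `w`. `w = 0` reduces the subsequent fit to the
#' subgroup-only model, `w = 1` to the pooled model (both degenerate ends are
#' allowed).
#'
#' @param data A [subgroup_surv] object.
#' @param target_subgroup Subgroup label in `1..S`, present in `data`.
#' @param w Constant weight in `[0, 1]` for patients outside the target
#'   subgroup.
#' @return Numeric weight vector of length `n`.
#' @export
fixed_weight_vector <- function(data, target_subgroup, w) {
  stopifnot(inherits(data, "subgroup_surv"))
  if (!target_subgroup %in% data$subgroups)
    stop("validation error: target_subgroup not present in data")
  if (length(w) != 1 || !is.finite(w) || w < 0 || w > 1)
    stop("validation error: w must lie in [0, 1]")
  ifelse(data$subgroups == target_subgroup, 1, w)
}

#' Specify one Cox model variant
#'
#' The model menu compared throughout: `estimated_weights` (individual
#' probability-ratio weights from a multi-class classifier), `fixed_weights`
#' (constant down-weighting of the other subgroups), `subgroup` (target
#' subgroup rows only) and `combined` (all rows pooled at weight 1, with the
#' subgroup indicator included as additional dummy-coded covariates).
#'
#' @param mode One of `"estimated_weights"`, `"fixed_weights"`, `"subgroup"`,
#'   `"combined"`.
#' @param target_subgroup Subgroup label the model is fitted for.
#' @param fixed_w Constant weight in `[0, 1]`; required iff
#'   `mode = "fixed_weights"`.
#' @param classifier `"lasso"`, `"ridge"` or `"rf"`; required iff
#'   `mode = "estimated_weights"`.
#' @param include_subgroup_indicator For `combined` mode: add `S - 1` dummy
#'   columns for the subgroup label (reference = label 1). Default `TRUE`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(mode, target_subgroup, fixed_w = NULL,
                       classifier = NULL, include_subgroup_indicator = TRUE) {
  mode <- match.arg(mode, c("estimated_weights", "fixed_weights",
                            "subgroup", "combined"))
  if (mode == "fixed_weights") {
    if (is.null(fixed_w)) stop("validation error: fixed_w required for fixed_weights mode")
  } else if (!is.null(fixed_w)) {
    stop("validation error: fixed_w only allowed in fixed_weights mode")
  }
  if (mode == "estimated_weights") {
    if (is.null(classifier))
      stop("validation error: classifier required for estimated_weights mode")
    if (is.character(classifier))
      classifier <- match.arg(classifier, c("lasso", "ridge", "rf"))
  } else if (!is.null(classifier)) {
    stop("validation error: classifier only allowed in estimated_weights mode")
  }
  structure(list(mode = mode, target_subgroup = target_subgroup,
                 fixed_w = fixed_w, classifier = classifier,
                 include_subgroup_indicator = include_subgroup_indicator),
            class = "model_spec")
}

# Append S-1 dummy columns (reference = label 1) to the covariate matrix.
add_subgroup_dummies <- function(data) {
  if (data$S < 2) return(data)
  dm <- sapply(2:data$S, function(s) as.numeric(data$subgroups == s))
  dm <- matrix(dm, nrow = data$n)
  colnames(dm) <- paste0("subgroup", 2:data$S)
  out <- data
  out$covariates <- cbind(data$covariates, dm)
  out$p <- ncol(out$covariates)
  out
}

#' Fit one model variant with cross-validated penalty
#'
#' Dispatches a [model_spec()] to the corresponding weighted Cox lasso fit:
#' estimated weights (column `target_subgroup` of the weight matrix), fixed
#' weights, the subgroup-only fit (target rows, unit weights) or the pooled
#' fit with subgroup-indicator dummies. The penalty is always selected by
#' [select_lambda_cv()].
#'
#' @param spec A [model_spec()].
#' @param data Training data, a [subgroup_surv] object.
#' @param seed Integer seed (fold assignments, classifier fitting).
#' @param weight_matrix Optional precomputed [estimate_weights()] result to
#'   reuse in `estimated_weights` mode (must match `spec$classifier`).
#' @param n_folds Folds for the lambda cross-validation (and, in
#'   `estimated_weights` mode, for the out-of-fold class probabilities).
#' @return A `cox_lasso_fit` whose `cv_curve` holds the lambda trace and whose
#'   `mode`/`target_subgroup`/`classifier` fields record the dispatch.
#' @export
fit_model <- function(spec, data, seed = 1, weight_matrix = NULL,
                      n_folds = 10) {
  stopifnot(inherits(spec, "model_spec"), inherits(data, "subgroup_surv"))
  if (!spec$target_subgroup %in% data$subgroups)
    stop("validation error: target_subgroup not present in data")
  fitdata <- data
  if (spec$mode == "estimated_weights") {
    wm <- weight_matrix %||%
      estimate_weights(data, classifier = spec$classifier,
                       n_folds = n_folds, seed = seed)
    weights <- wm$values[, spec$target_subgroup]
  } else if (spec$mode == "fixed_weights") {
    weights <- fixed_weight_vector(data, spec$target_subgroup, spec$fixed_w)
  } else if (spec$mode == "subgroup") {
    fitdata <- subset_rows(data, which(data$subgroups == spec$target_subgroup))
    weights <- rep(1, fitdata$n)
  } else { # combined
    if (isTRUE(spec$include_subgroup_indicator))
      fitdata <- add_subgroup_dummies(data)
    weights <- rep(1, fitdata$n)
  }
  lam <- select_lambda_cv(fitdata, weights, n_folds = n_folds, seed = seed)
  fit <- fit_weighted_cox_lasso(fitdata, weights, as.numeric(lam))
  fit$cv_curve <- attr(lam, "cv_curve")
  fit$mode <- spec$mode
  fit$target_subgroup <- spec$target_subgroup
  fit$classifier <- spec$classifier
  fit$S <- data$S
  fit
}

#' Write a fitted model to CSV with a JSON sidecar
#'
#' The CSV holds one row per covariate (`name`, `coefficient`); the sidecar
#' (same path with extension `.json`) records lambda, mode, classifier, seed
#' and the CV curve.
#'
#' @param fit A `cox_lasso_fit`.
#' @param file Output CSV path.
#' @param seed Seed to record in the sidecar (optional).
#' @export
write_fit <- function(fit, file, seed = NULL) {
  utils::write.csv(data.frame(name = names(fit$coefficients),
                              coefficient = unname(fit$coefficients)),
                   file, row.names = FALSE)
  meta <- list(lambda = fit$lambda, mode = fit$mode,
               classifier = fit$classifier,
               target_subgroup = fit$target_subgroup,
               n_nonzero = fit$n_nonzero, seed = seed,
               cv_curve = fit$cv_curve)
  jsonlite::write_json(meta, paste0(sub("\\.[^.]*$", "", file), ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
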