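#' Harrell's concordance index
#'
#' The proportion of usable patient pairs whose risk-score ordering matches
#' their survival-time ordering:
#' \deqn{CI = \frac{1}{n_c} \sum_{i:\,\delta_i = 1}\; \sum_{i^*:\, t_{i^*} > t_i}
#'   \left[ 1(\hat r_{i^*} < \hat r_i) + \tfrac12\, 1(\hat r_{i^*} = \hat r_i)
#'   \right].}
#' A pair \eqn{(i, i^*)} is usable iff \eqn{\delta_i = 1} and
#' \eqn{t_{i^*} > t_i}; pairs where both patients die at the same time, both
#' are censored, or one is censored before the other dies are unusable (a
#' censoring tied with an event at the same time is also unusable, as the
#' strict inequality requires). \eqn{n_c} is the number of usable pairs.
#' Values near 1 indicate good discrimination, 0.5 random prediction.
#'
#' @param times Observed times.
#' @param events 0/1 event indicators.
#' @param risk_scores Finite risk scores \eqn{\hat r(x_i) = \hat\beta' x_i};
#'   higher score = higher predicted risk = shorter expected survival.
#' @return CI in `[0, 1]`. Errors if there is no usable pair (the index is
#'   undefined, not 0.5).
#' @export
#' @examples
#' harrell_c_index(c(2, 4, 4, 6, 8), c(1, 1, 0, 1, 0), c(5, 4, 4, 1, 1))
harrell_c_index <- function(times, events, risk_scores) {
  n <- length(times)
  if (length(events) != n || length(risk_scores) != n)
    stop("dimension mismatch: times, events and risk_scores must share length")
  if (!all(is.finite(risk_scores)))
    stop("validation error: risk scores must be finite")
  ev <- which(events == 1)
  if (length(ev) == 0) stop("undefined result: no usable pairs")
  usable <- outer(times[ev], times, FUN = function(a, b) b > a)
  conc <- outer(risk_scores[ev], risk_scores, FUN = function(a, b) b < a)
  tie <- outer(risk_scores[ev], risk_scores, FUN = "==")
  n_c <- sum(usable)
  if (n_c == 0) stop("undefined result: no usable pairs")
  (sum(usable & conc) + 0.5 * sum(usable & tie)) / n_c
}

#' C-index of a fitted model on one subgroup's test data
#'
#' Restricts the test data to the target subgroup, computes linear-predictor
#' risk scores from the fit's coefficients and returns [harrell_c_index()].
#' For a `combined`-mode fit the subgroup-indicator dummy columns are rebuilt
#' for the test rows with the training reference level (label 1).
#'
#' @param fit A `cox_lasso_fit` (from [fit_model()] or
#'   [fit_weighted_cox_lasso()]).
#' @param test Test data, a [subgroup_surv] object.
#' @param target_subgroup Subgroup label to evaluate; must occur in `test`.
#' @return Harrell's C-index on the subgroup's test rows.
#' @export
score_fit <- function(fit, test, target_subgroup) {
  stopifnot(inherits(fit, "cox_lasso_fit"), inherits(test, "subgroup_surv"))
  idx <- which(test$subgroups == target_subgroup)
  if (length(idx) == 0)
    stop("validation error: target_subgroup absent from test data")
  x <- test$covariates[idx, , drop = FALSE]
  if (identical(fit$mode, "combined") &&
      length(fit$coefficients) == ncol(x) + fit$S - 1) {
    dm <- sapply(2:fit$S, function(s) as.numeric(test$subgroups[idx] == s))
    dm <- matrix(dm, nrow = length(idx))
    colnames(dm) <- paste0("subgroup", 2:fit$S)
    x <- cbind(x, dm)
  }
  if (length(fit$coefficients) != ncol(x))
    stop("dimension mismatch: fit coefficients do not match test covariates")
  harrell_c_index(test$times[idx], test$events[idx],
                  drop(x %*% fit$coefficients))
}
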