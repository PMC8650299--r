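#' Weighted Cox partial log-likelihood
#'
#' Evaluates the weighted partial log-likelihood
#' \deqn{l(\beta) = \sum_i \delta_i w_i \left[\beta'x_i -
#'   \log \sum_k 1(t_i \le t_k)\, w_k e^{\beta'x_k}\right],}
#' where the risk set of an event at \eqn{t_i} is every patient with
#' \eqn{t_k \ge t_i} (the event itself included). Tied event times share the
#' same risk set, i.e. Breslow tie handling. With all weights equal to 1 this
#' is the standard Breslow partial log-likelihood.
#'
#' @param beta Numeric coefficient vector of length `p`.
#' @param data A [subgroup_surv] object.
#' @param weights Nonnegative numeric vector of length `n`. Weights are used
#'   exactly as given (no normalization); rescaling all weights by a constant
#'   rescales the log-likelihood by the same constant.
#' @return A finite scalar. If no event carries positive weight
#'   (\eqn{\delta_i w_i = 0} for all `i`) the empty sum is 0.
#' @export
#' @examples
#' d <- subgroup_surv(c(1, 2, 3), c(1, 1, 0), c(1, 1, 1),
#'                    matrix(c(0.5, -1, 2), 3, 1))
#' weighted_cox_loglik(0.3, d, c(2, 1, 1))
weighted_cox_loglik <- function(beta, data, weights) {
  stopifnot(inherits(data, "subgroup_surv"))
  if (length(beta) != data$p)
    stop("dimension mismatch: beta must have length p")
  if (length(weights) != data$n)
    stop("dimension mismatch: weights must have length n")
  if (anyNA(weights) || any(weights < 0))
    stop("validation error: weights must be nonnegative")
  dw <- data$events * weights
  if (all(dw == 0)) return(0)
  eta <- drop(data$covariates %*% beta)
  m <- max(eta)
  # cumulative risk-set mass over times sorted in decreasing order
  ord <- order(data$times, decreasing = TRUE)
  cs <- cumsum((weights * exp(eta - m))[ord])
  # for each patient, number of k with t_k >= t_i (ties included)
  nge <- findInterval(-data$times, -data$times[ord])
  # only rows with delta_i w_i > 0 contribute; this also avoids 0 * log(0)
  # when every patient at risk beyond some time has weight zero
  idx <- dw > 0
  log_denom <- m + log(cs[nge[idx]])
  sum(dw[idx] * (eta[idx] - log_denom))
}

# Gradient of the weighted partial log-likelihood with respect to beta.
# u_i = delta_i w_i - w_i e^{eta_i} * sum_{events j: t_j <= t_i} delta_j w_j / D_j,
# grad = X'u. Used for KKT diagnostics and tests; not in the fitting path.
weighted_cox_score <- function(beta, data, weights) {
  eta <- drop(data$covariates %*% beta)
  m <- max(eta)
  r <- weights * exp(eta - m)
  ord <- order(data$times, decreasing = TRUE)
  cs <- cumsum(r[ord])
  nge <- findInterval(-data$times, -data$times[ord])
  denom <- cs[nge]                       # scaled by e^{-m}; cancels below
  dw <- data$events * weights
  a <- ifelse(denom > 0, dw / denom, 0)  # event mass / risk denominator
  # B_i = sum over events j with t_j <= t_i of a_j: cumulate ascending in time
  orda <- order(data$times)
  csa <- cumsum(a[orda])
  nle <- findInterval(data$times, data$times[orda])
  B <- csa[nle]
  u <- dw - r * B
  drop(crossprod(data$covariates, u))
}
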