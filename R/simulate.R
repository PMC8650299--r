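# Synthetic cohorts: four equally sized subgroups (1A, 1B, 2A, 2B) drawn from
# two latent groups with group-specific covariate mean shifts (controlled by
# the similarity parameter epsilon) and Weibull event and censoring times
# under group-specific linear predictors.

#' Prognostic effect vectors of the two latent groups
#'
#' The first 12 covariates ("genes") carry the effects; all remaining entries
#' are zero noise. The pattern mixes group-specific effects (genes 1–4),
#' opposite effects (5–6), same-direction effects of different size (7–8) and
#' joint effects (9–12), with alternating signs summing to zero.
#'
#' @param p Number of covariates, at least 12.
#' @return An `effect_table`: list with `beta1` and `beta2`, each length `p`.
#' @export
effect_table <- function(p = 12) {
  if (p < 12) stop("validation error: p must be at least 12")
  b1 <- c(1, 1, 0, 0, -0.5, 0.5, 0.75, 0.25, -1, -1, -0.75, -0.25)
  b2 <- c(0, 0, 1, 1, 0.5, -0.5, 0.25, 0.75, -1, -1, -0.75, -0.25)
  structure(list(beta1 = c(b1, rep(0, p - 12)), beta2 = c(b2, rep(0, p - 12))),
            class = "effect_table")
}

#' Solve Weibull parameters from two survival anchors
#'
#' Finds the unique scale \eqn{\eta} and shape \eqn{\kappa} with baseline
#' survival \eqn{S(t) = \exp(-\eta t^\kappa)} passing through two anchor
#' points, in closed form:
#' \eqn{\kappa = \log(\log S(t_1)/\log S(t_2)) / \log(t_1/t_2)},
#' \eqn{\eta = -\log S(t_1) / t_1^\kappa}. The defaults anchor at 3- and
#' 5-year survival, as obtained from Kaplan–Meier estimates of real cohorts.
#'
#' @param surv_t1,surv_t2 Survival probabilities at `t1` and `t2`, with
#'   `0 < surv_t2 < surv_t1 < 1`.
#' @param t1,t2 Anchor times, `0 < t1 < t2` (defaults 3 and 5).
#' @return A `weibull_params` object: list with `eta` and `kappa`.
#' @export
#' @examples
#' solve_weibull_params(0.57, 0.42)  # cohort-1 anchors
solve_weibull_params <- function(surv_t1, surv_t2, t1 = 3, t2 = 5) {
  if (!(t1 > 0 && t2 > t1))
    stop("validation error: need 0 < t1 < t2")
  if (!(surv_t1 > 0 && surv_t1 < 1 && surv_t2 > 0 && surv_t2 < surv_t1))
    stop("validation error: need 0 < surv_t2 < surv_t1 < 1")
  kappa <- log(log(surv_t1) / log(surv_t2)) / log(t1 / t2)
  eta <- -log(surv_t1) / t1^kappa
  stopifnot(abs(exp(-eta * t1^kappa) - surv_t1) < 1e-10,
            abs(exp(-eta * t2^kappa) - surv_t2) < 1e-10)
  structure(list(eta = eta, kappa = kappa), class = "weibull_params")
}

#' Covariate mean vector for one group
#'
#' Maps a group's effect vector to covariate means on the log2-expression
#' scale: \eqn{\mu = 4 + 4\epsilon} for strong effects (\eqn{|\beta| = 1}),
#' \eqn{\mu = 4 + 2\epsilon} for moderate effects
#' (\eqn{|\beta| \in \{0.5, 0.75\}}) and \eqn{\mu = 4} for weak or no effects
#' (\eqn{|\beta| \in \{0, 0.25\}}). Because the mapping is applied to each
#' group's own effect vector, \eqn{\epsilon} dials the between-group mean
#' separation: at \eqn{\epsilon = 0} the groups share one covariate
#' distribution.
#'
#' @param effects_for_group Effect vector whose magnitudes must lie in
#'   `{0, 0.25, 0.5, 0.75, 1}`.
#' @param epsilon Similarity parameter in `[0, 1]`.
#' @return Mean vector of the same length.
#' @export
covariate_means <- function(effects_for_group, epsilon) {
  if (epsilon < 0 || epsilon > 1)
    stop("validation error: epsilon must lie in [0, 1]")
  a <- abs(effects_for_group)
  tier <- numeric(length(a))
  strong <- abs(a - 1) < 1e-9
  moderate <- abs(a - 0.5) < 1e-9 | abs(a - 0.75) < 1e-9
  weak <- a < 1e-9 | abs(a - 0.25) < 1e-9
  if (!all(strong | moderate | weak))
    stop("validation error: effect magnitudes must be in {0, 0.25, 0.5, 0.75, 1}")
  4 + 4 * epsilon * strong + 2 * epsilon * moderate
}

#' Configure one simulation scenario
#'
#' Fully specifies one synthetic scenario: four subgroups of `n_per_subgroup`
#' patients each, `p` covariates, similarity parameter `epsilon`, the effect
#' vectors, and the two groups' Weibull parameters. The default Weibull
#' parameters are solved from the two cohorts' printed 3-/5-year survival
#' anchors: (0.57, 0.42) for group 1 and (0.75, 0.62) for group 2.
#'
#' @param n_per_subgroup Patients per subgroup (each of the 4 subgroups).
#' @param p Number of covariates (at least 12).
#' @param epsilon Similarity parameter in `[0, 1]`.
#' @param effects An [effect_table()] (defaults to the canonical one).
#' @param weibull List of two [solve_weibull_params()] results (group 1, 2).
#' @param seed Optional integer seed; [generate_dataset()] uses it when set.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_per_subgroup = 100, p = 100, epsilon = 0,
                              effects = effect_table(p),
                              weibull = list(solve_weibull_params(0.57, 0.42),
                                             solve_weibull_params(0.75, 0.62)),
                              seed = NULL) {
  stopifnot(n_per_subgroup >= 1, p >= 12,
            inherits(effects, "effect_table"),
            length(effects$beta1) == p, length(effects$beta2) == p,
            length(weibull) == 2,
            inherits(weibull[[1]], "weibull_params"),
            inherits(weibull[[2]], "weibull_params"))
  if (epsilon < 0 || epsilon > 1)
    stop("validation error: epsilon must lie in [0, 1]")
  structure(list(n_per_subgroup = as.integer(n_per_subgroup), p = as.integer(p),
                 epsilon = epsilon, effects = effects, weibull = weibull,
                 seed = seed),
            class = "simulation_config")
}

#' Simulate one group's patients
#'
#' Covariates are drawn i.i.d. normal with the group's mean vector (see
#' [covariate_means()]) and identity covariance. Event times follow the
#' Weibull inverse transform
#' \eqn{T = (-\log U / (\eta\, e^{x'\beta}))^{1/\kappa}}, \eqn{U \sim U[0,1]};
#' censoring times are drawn from the identical mechanism (same
#' \eqn{\eta, \kappa, \beta} and the same covariates) with an independent
#' uniform, so event and censoring time are i.i.d. given the covariates and
#' each patient is censored with probability exactly 1/2 — the observed data
#' are \eqn{t = \min(T, C)}, \eqn{\delta = 1(T \le C)}.
#'
#' Uses the current RNG state; seed externally (or via
#' [generate_dataset()]).
#'
#' @param n Number of patients.
#' @param group Latent group, 1 or 2.
#' @param config A [simulation_config()].
#' @return List with `times`, `events`, `covariates` (and latent `event_time`,
#'   `censor_time`).
#' @export
simulate_group <- function(n, group, config) {
  stopifnot(inherits(config, "simulation_config"), group %in% c(1, 2))
  beta <- if (group == 1) config$effects$beta1 else config$effects$beta2
  wb <- config$weibull[[group]]
  mu <- covariate_means(beta, config$epsilon)
  x <- matrix(stats::rnorm(n * config$p), n, config$p)
  x <- sweep(x, 2, mu, "+")
  colnames(x) <- paste0("x", seq_len(config$p))
  lp <- drop(x %*% beta)
  draw <- function() {
    u <- stats::runif(n)
    (-log(u) / (wb$eta * exp(lp)))^(1 / wb$kappa)
  }
  T_ev <- draw()
  C_cn <- draw()
  list(times = pmin(T_ev, C_cn), events = as.integer(T_ev <= C_cn),
       covariates = x, event_time = T_ev, censor_time = C_cn)
}

#' Generate one complete synthetic dataset
#'
#' Four subgroups of equal size: labels 1 and 2 ("1A", "1B") are drawn with
#' the group-1 parameters, labels 3 and 4 ("2A", "2B") with the group-2
#' parameters; within a group the two subgroups are i.i.d.
#'
#' @param config A [simulation_config()]. If `config$seed` is set the dataset
#'   is reproducible (and the caller's RNG state is left untouched);
#'   otherwise the current RNG state is used.
#' @return A [subgroup_surv] object with `4 * n_per_subgroup` rows.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  gen <- function() {
    groups <- c(1, 1, 2, 2)
    parts <- lapply(1:4, function(sg)
      simulate_group(config$n_per_subgroup, groups[sg], config))
    subgroup_surv(
      times = unlist(lapply(parts, `[[`, "times")),
      events = unlist(lapply(parts, `[[`, "events")),
      subgroups = rep(1:4, each = config$n_per_subgroup),
      covariates = do.call(rbind, lapply(parts, `[[`, "covariates")),
      subgroup_names = c("1A", "1B", "2A", "2B"))
  }
  if (!is.null(config$seed)) with_seed(config$seed, gen()) else gen()
}

#' The full simulation parameter grid
#'
#' Enumerates every scenario of the simulation study: per-subgroup sample
#' sizes 20–100 (by 10), 200, 500, 1000; `p` in 12, 100, 200; and `epsilon`
#' in 0–0.5 (by 0.1) and 1 — 252 combinations.
#'
#' @return A data.frame with columns `n_per_subgroup`, `p`, `epsilon`.
#' @export
scenario_grid <- function() {
  expand.grid(n_per_subgroup = c(20, 30, 40, 50, 60, 70, 80, 90, 100,
                                 200, 500, 1000),
              p = c(12, 100, 200),
              epsilon = c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 1),
              KEEP.OUT.ATTRS = FALSE)
}

#' Round-trip a simulation configuration through JSON
#'
#' @param config A [simulation_config()].
#' @param file JSON path.
#' @export
write_simulation_config <- function(config, file) {
  jsonlite::write_json(
    list(n_per_subgroup = config$n_per_subgroup, p = config$p,
         epsilon = config$epsilon,
         beta1 = config$effects$beta1, beta2 = config$effects$beta2,
         weibull = lapply(config$weibull, function(w)
           list(eta = w$eta, kappa = w$kappa)),
         seed = config$seed),
    file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  eff <- structure(list(beta1 = j$beta1, beta2 = j$beta2),
                   class = "effect_table")
  wb <- lapply(seq_len(nrow(j$weibull)), function(i)
    structure(list(eta = j$weibull$eta[i], kappa = j$weibull$kappa[i]),
              class = "weibull_params"))
  simulation_config(n_per_subgroup = j$n_per_subgroup, p = j$p,
                    epsilon = j$epsilon, effects = eff, weibull = wb,
                    seed = j$seed)
}
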