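---
title: "Weighted subgroup Cox models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted subgroup Cox models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subcox)
```

## The problem

Risk prediction from high-dimensional molecular covariates (typically
gene-expression profiles, $p \gg n$) is routinely attempted on cohorts that
are assembled from several studies, centers or clinically defined subgroups.
The two standard strategies sit at opposite ends of a trade-off. *Pooling*
all subgroups maximizes sample size but averages away subgroup-specific
effects when the subgroups are heterogeneous; *subgroup-only* analysis is
unbiased for the subgroup of interest but has little power at realistic
subgroup sizes. `subcox` implements a middle road: a separate model per
subgroup that keeps **all** patients in the likelihood, each with an
individual, data-estimated weight expressing how much that patient resembles
the target subgroup.

## The model

For patient $i$ we observe $(t_i, \delta_i, s_i, x_i)$: the observed time
$t_i = \min(T_i, C_i)$, the event indicator $\delta_i = 1(T_i \le C_i)$, a
subgroup label $s_i \in \{1, \dots, S\}$ and covariates
$x_i \in \mathbb{R}^p$. Hazards follow the Cox proportional hazards form
$h(t \mid x_i) = h_0(t) e^{\beta' x_i}$, and coefficients are estimated from
the weighted partial log-likelihood

$$
l(\beta) = \sum_{i=1}^n \delta_i w_i \Big[ \beta' x_i -
  \log \sum_{k=1}^n 1(t_i \le t_k)\, w_k\, e^{\beta' x_k} \Big],
$$

with nonnegative per-patient weights $w_i$. The indicator $1(t_i \le t_k)$
makes tied event times share one risk set, i.e. Breslow tie handling; this
is adopted consistently everywhere, including the unpenalized oracle used in
the tests, because it is what the likelihood above literally states.
Estimation maximizes $l(\beta) - \lambda \sum_j |\beta_j|$; the lasso
penalty produces the sparse solutions appropriate for $p \gg n$ and does the
variable selection.

Setting weights degenerately recovers the standard approaches, which the
package exposes as a model menu:

* `subgroup` — only the target subgroup's rows (equivalently $w = 0$
  outside it);
* `combined` — all rows at weight 1, with the subgroup label dummy-coded
  into $S - 1$ additional covariates;
* `fixed_weights` — weight 1 inside the target subgroup, a constant
  $w \in [0, 1]$ outside it;
* `estimated_weights` — the individual weights described next.

## Individual weights as probability ratios

For target subgroup $s$, the weight that converts an expectation under the
pooled distribution $p(y, x)$ into one under the subgroup distribution
$p(y, x \mid s)$ is the density ratio

$$
w_s(y, x) = \frac{p(y, x \mid s)}{p(y, x)} = \frac{p(s \mid y, x)}{p(s)},
$$

where the second form, obtained from Bayes' rule, only needs a multi-class
classifier for the subgroup label given covariates *and response*, plus the
empirical subgroup frequency $\hat p(s)$. The package estimates
$p(s \mid y, x)$ by 10-fold cross-validation — each patient's probability
comes from the fold model that never saw that patient — to prevent the
weights from overfitting the training data. Three classifiers are provided:
multinomial logistic regression with lasso or ridge penalty (each tuning its
own penalty by an internal 10-fold CV nested inside every outer fold) and a
probability random forest (500 trees, default feature subsampling). The same
outer fold partition is reused across classifiers so classifier comparisons
are not confounded by fold noise.

Design choices worth stating explicitly:

* The classifier features are $(x, \log t, \delta)$. The response encoding
  is genuinely open; time enters on the log scale because that is the scale
  on which a multiplicative hazard model is linear.
* The ratio is **not** truncated or renormalized: weights above 1 are
  meaningful (they say "this patient looks more like subgroup $s$ than an
  average patient does"), and small subgroups legitimately produce large
  weights through the $1/\hat p(s)$ factor. The Cox fitter rescales whatever
  weights it receives so that they sum to $n$, which makes $\lambda$
  comparable across weighting schemes and makes the fit invariant to
  rescaling all weights by a constant.
* Probability forests with their default leaf size give confident but not
  extreme probabilities even for perfectly separated classes; this is a
  calibration property of leaf averaging, not an error, and it does not
  affect the ranking-based separation diagnostics.

A useful diagnostic is `group_separation_auc()`: the AUC of the summed
within-group out-of-fold probabilities for telling two latent groups apart.
When subgroups are exchangeable it sits near 0.5 and all weights concentrate
near 1 (the estimated-weights model then *is* the pooled model, which is the
intended behavior); when groups separate it approaches 1 and the weights
approach the subgroup-indicator pattern.

## Penalty selection

$\lambda$ is chosen by 10-fold cross-validation on a log-spaced grid of 100
values from $\lambda_{\max}$ (the smallest $\lambda$ with an all-zero
solution, derived from the weighted score at $\beta = 0$) down to
$\lambda_{\max} \cdot 10^{-2}$ when $n \le p$ and
$\lambda_{\max} \cdot 10^{-4}$ otherwise. The CV criterion is the
Verweij–van Houwelingen partial-likelihood deviance: for fold $k$,
$-2\{l(\hat\beta_{-k}) - l_{-k}(\hat\beta_{-k})\}$, where $l$ is the
weighted log-likelihood on the full data and $l_{-k}$ on the data without
fold $k$. This construction needs no per-fold risk-set surgery, held-out
patients keep their weights, and the rule is the minimizing $\lambda$. The
grid and coordinate-descent conventions (convergence tolerance $10^{-7}$ on
the coefficient updates, at most $10^5$ passes, internal standardization by
weighted mean and variance with coefficients reported on the original
scale) follow the established penalized-regression practice for this model
family; the solver behind the module surface is glmnet's Cox coordinate
descent. Folds are stratified by the event indicator so that no training
part is event-free at small $n$; fold assignment is deterministic given the
seed. Fold assignment ignores zero-weight rows (they are parked in fold 1),
which makes a model with weight 0 on some patients select exactly the same
penalty as the model with those patients deleted — one of the exact
equivalences the test suite checks. A degenerate fold whose training part
cannot support a fit contributes the null coefficient path, with a warning;
a fold without weighted events is skipped.

Two further points were open and decided as follows. The subgroup-indicator
dummies of the `combined` model are penalized like every other column —
there is no principled reason to exempt $S - 1$ specific columns, and
uniform treatment keeps the model definition simple. And the zero threshold
for reporting a coefficient as exactly 0 (and counting nonzeros) is
$|\hat\beta_j| < 10^{-12}$, which makes sparsity counts reproducible across
platforms.

## Evaluation

Prediction is evaluated by Harrell's concordance index on the *test rows of
the target subgroup only*, using risk scores
$\hat r(x) = \hat\beta' x$. A pair $(i, i^*)$ is usable iff $\delta_i = 1$
and $t_{i^*} > t_i$; concordant pairs score 1, risk-score ties score
$\tfrac12$, and the index is the scored sum divided by the number of usable
pairs. Two literal consequences of the strict inequality: an event and a
censoring at the same time form an unusable pair, and a dataset without any
usable pair raises an error rather than returning 0.5. No inverse
probability-of-censoring weighting and no truncation horizon are applied, so
the index does depend on the censoring distribution; that dependence is
shared by every model under comparison, which is the use case here.

## The simulator

The synthetic cohorts are built to expose exactly the heterogeneity the
weights are supposed to detect. Four subgroups (1A, 1B, 2A, 2B) of equal
size $n$ come from two latent groups; within a group the two subgroups are
i.i.d. Covariates are independent normals with unit variance; the group
mean of covariate $j$ is $4 + 4\epsilon$ if $|\beta_j| = 1$,
$4 + 2\epsilon$ if $|\beta_j| \in \{0.5, 0.75\}$ and $4$ otherwise, applied
to each group's *own* effect vector — so $\epsilon \in [0, 1]$ dials the
between-group covariate separation from "indistinguishable" to "clearly
separated", while covariates with shared effects stay identically
distributed. The baseline level 4 mimics $\log_2$ expression values, where
prognostic genes tend to sit above the noise floor.

The effect vectors fix the first 12 covariates as prognostic — a mix of
group-specific effects, opposite effects, same-direction effects of
different size and joint effects, with signs alternating so the linear
predictor is centered — and everything beyond covariate 12 is noise.

Event times use the Weibull inverse transform
$T = \bigl(-\log U / (\eta\, e^{x'\beta})\bigr)^{1/\kappa}$ with
$U \sim U[0,1]$. The two groups' $(\eta, \kappa)$ are solved in closed form
from 3- and 5-year baseline survival anchors of two real NSCLC cohorts —
$(0.57, 0.42)$ for group 1 and $(0.75, 0.62)$ for group 2. Which anchor pair
maps to which group is a labeling convention; results are symmetric under
relabeling. Censoring times are drawn from the *identical* mechanism — same
$\eta$, $\kappa$, $\beta$ and the same covariate draw, with an independent
uniform. This is the only reading of "the same parameters as for the event
times" that forces the intended censoring level for every patient: given
$x$, the event and censoring times are i.i.d., so $P(\delta = 1) = 1/2$
exactly, i.e. approximately 50% censoring empirically, regardless of the
linear predictor. The full study grid crosses 12 sample sizes, three values
of $p$ and seven values of $\epsilon$ into 252 scenarios
(`scenario_grid()`).

What the simulator deliberately does not emulate: correlated covariates
(realistic expression covariance made no practical difference in earlier
comparisons of this design, so identity covariance is used), unequal
subgroup sizes, batch or platform effects, and informative censoring.
Passing tests on these cohorts therefore demonstrate correctness of the
machinery and the qualitative behavior of the weights, not performance on
any particular real cohort — the real-data path (`run_real_data_experiment`)
exists precisely because those questions must be answered per dataset.

## The experiment loop

`run_simulation_experiment()` repeats, per replicate: generate a fresh
training and an independent test dataset of the same size and distribution
(fresh pairs per replicate, matching a design in which test data are
regenerated rather than shared); estimate weights on the training data only;
fit every menu model per subgroup with CV-selected $\lambda$; and score each
on the corresponding subgroup's test rows. `run_real_data_experiment()`
replaces generation by repeated stratified splitting (training proportion
0.632, stratified by subgroup × event status, `round` per cell). A master
seed spawns per-replicate seeds, so replicates are independent, individually
reproducible, and exchangeable — permuting replicate seeds permutes records
without changing the aggregates. Failed model fits within a replicate are
recorded as missing and excluded pairwise from summaries; a run with more
than 20% failed replicates errors. Besides per-record C-indexes the result
carries mean inclusion frequencies (MIF): the fraction of replicates in
which covariate $j$ enters the model, the standard stability summary for
lasso selections.

Default experiment size is 100 replicates. The test suite exercises the
pipeline end-to-end at reduced size — 25 replicates for the directional
comparisons (pooled vs subgroup at $\epsilon = 0$, $n = 20$, $p = 100$;
estimated weights vs both at $\epsilon = 0.5$, $n = 500$, $p = 12$), 10
seeds for the separation diagnostics at $n = p = 100$, and $10^4$–$10^5$
draws for the simulator calibration checks — sizes at which the expected
orderings are stable but a full run stays convenient on one workstation.

## Known limitations

* Only the partial likelihood is fitted: no baseline hazard estimate, hence
  no absolute survival probabilities — risk ranking only.
* Breslow tie handling only; Efron's correction would deviate from the
  likelihood as written.
* Subgroups must be pre-known and fixed; discovering latent structure is a
  clustering problem outside this package's scope.
* Harrell's C-index is censoring-dependent; IPC-weighted or time-dependent
  alternatives are intentionally not implemented.
* The weighted likelihood shares one baseline hazard across subgroups; a
  stratified baseline is a different model family.
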