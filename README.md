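# subcox

Subgroup-weighted lasso-penalized Cox regression for heterogeneous patient
cohorts.

## The problem

Clinical risk models from high-dimensional molecular data (gene expression,
`p >> n`) are usually built on cohorts pooled from several studies, centers
or clinically defined subgroups. Pooling everything inflates sample size but
averages away subgroup-specific effects; restricting to one subgroup is
unbiased but underpowered at typical subgroup sizes. `subcox` provides the
middle road: a separate lasso-penalized Cox model per subgroup whose partial
likelihood keeps **all** patients, each with an individual, data-estimated
weight measuring how much that patient resembles the target subgroup.

## The model

Coefficients maximize the penalized weighted Cox partial log-likelihood

```
l(β) = Σ_i δ_i w_i [ β'x_i − log Σ_k 1(t_i ≤ t_k) w_k exp(β'x_k) ]   −  λ Σ_j |β_j|
```

(Breslow risk sets; λ chosen by 10-fold cross-validated partial-likelihood
deviance). The weight of patient `i` in the model for subgroup `s` is the
density ratio

```
w_s(y, x) = p(y, x | s) / p(y, x) = p(s | y, x) / p(s),
```

with `p(s | y, x)` estimated out-of-fold by multi-class classification
(multinomial lasso/ridge or random forest) on the covariates plus the
survival response, and `p(s)` the empirical subgroup frequency. Patients who
look like the target subgroup count more; when subgroups are
indistinguishable every weight collapses to ≈ 1 and the model gracefully
becomes the pooled analysis. The classical baselines — subgroup-only,
pooled with subgroup indicator, and constant down-weighting
(`w ∈ {0.1, …, 0.9}`) of the other subgroups — are included as the rest of
the 14-model menu, and everything is evaluated per subgroup by Harrell's
C-index. A Weibull-based simulator with a latent two-group structure and a
tunable between-group separation `ε` generates the synthetic cohorts used by
the replicated experiment pipeline.

See `vignettes/weighted-subgroup-cox.Rmd` for the full methods account.

## Worked example

```r
library(subcox)

cfg   <- simulation_config(n_per_subgroup = 100, p = 100, epsilon = 0.5, seed = 2024)
train <- generate_dataset(cfg)
test  <- generate_dataset(simulation_config(100, 100, 0.5, seed = 2025))
train
#> subgroup_surv: n = 400 patients, p = 100 covariates, S = 4 subgroups
#>   subgroup sizes: 1A=100, 1B=100, 2A=100, 2B=100
#>   events: 192 (48.0%)

wm <- estimate_weights(train, classifier = "rf", seed = 1)
round(tapply(wm$values[, 1], train$subgroups, mean), 2)
#>    1    2    3    4
#> 1.55 1.55 0.44 0.46
```

At `ε = 0.5` the classifier tells the two latent groups apart, so in the
subgroup-1 model the patients of group 1 (subgroups 1 and 2) are weighted up
(≈ 1.55) and group-2 patients down (≈ 0.45) — the weights have rediscovered
the latent group structure from the data alone.

```r
fit <- fit_model(model_spec("estimated_weights", target_subgroup = 1, classifier = "rf"),
                 train, seed = 1, weight_matrix = wm)
fit
#> cox_lasso_fit: 23 of 100 coefficients nonzero, lambda = 0.047889
#>   model: estimated_weights (rf), target subgroup 1

sub_fit <- fit_model(model_spec("subgroup", 1), train, seed = 1)
all_fit <- fit_model(model_spec("combined", 1), train, seed = 1)
round(c(weighted = score_fit(fit, test, 1),
        subgroup = score_fit(sub_fit, test, 1),
        pooled   = score_fit(all_fit, test, 1)), 3)
#> weighted subgroup   pooled
#>    0.778    0.710    0.768
```

The weighted model predicts subgroup 1's test data better than both the
subgroup-only fit (which saw only 100 patients) and the pooled fit (which
dilutes subgroup-specific effects): C-index 0.778 vs 0.710 and 0.768.

The replicated comparison over all 14 model variants is
`run_simulation_experiment()` (fresh train/test pairs per replicate) and
`run_real_data_experiment()` (repeated 0.632 subsampling stratified by
subgroup and event status); both return per-replicate C-index records and
mean inclusion frequencies. A thin command-line interface over the same
functions lives at `inst/cli/subcox.R` (subcommands `simulate`, `weights`,
`fit`, `experiment`).

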