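make_separable <- function(n = 100, gap = 10, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * 5), n, 5)
    sg <- rep(1:2, each = n / 2)
    x[, 1] <- x[, 1] + gap * (sg - 1)
    subgroup_surv(times = rexp(n) + 0.1, events = rbinom(n, 1, 0.5),
                  subgroups = sg, covariates = x)
  })
}

test_that("well-separated subgroups get confident out-of-fold probabilities", {
  d <- make_separable(n = 100, gap = 10, seed = 41)
  for (cl in c("lasso", "ridge", "rf")) {
    pm <- estimate_subgroup_probs(d, cl, seed = 1)
    p_true <- pm[cbind(seq_len(d$n), d$subgroups)]
    # every patient is classified correctly out of fold
    expect_true(all(p_true > 0.5))
    if (cl == "lasso") {
      expect_gte(mean(p_true > 0.9), 0.95)
    } else {
      # ridge shrinkage and probability-forest leaf averaging give confident
      # but non-extreme probabilities
      expect_gt(mean(p_true), 0.8)
    }
    expect_equal(rowSums(pm), rep(1, d$n), tolerance = 1e-8)
  }
})

test_that("indistinguishable subgroups get probabilities near 1/S", {
  d <- withr::with_seed(42, {
    subgroup_surv(times = rexp(200) + 0.1, events = rbinom(200, 1, 0.5),
                  subgroups = rep(1:4, each = 50),
                  covariates = matrix(rnorm(200 * 10), 200, 10))
  })
  pm <- estimate_subgroup_probs(d, "rf", seed = 2)
  expect_true(all(abs(colMeans(pm) - 0.25) < 0.05))
})

test_that("probability estimation is deterministic given the seed", {
  d <- make_separable(n = 60, gap = 2, seed = 43)
  p1 <- estimate_subgroup_probs(d, "lasso", seed = 7)
  p2 <- estimate_subgroup_probs(d, "lasso", seed = 7)
  expect_identical(p1, p2)
  r1 <- estimate_subgroup_probs(d, "rf", seed = 7)
  r2 <- estimate_subgroup_probs(d, "rf", seed = 7)
  expect_identical(r1, r2)
})

test_that("the out-of-fold bookkeeping permutes with the patients", {
  # deterministic, row-order-invariant classifier isolates the fold machinery
  d <- make_separable(n = 40, gap = 3, seed = 44)
  foldid <- rep_len(1:5, d$n)
  pm <- estimate_subgroup_probs(d, centroid_classifier, foldid = foldid)
  perm <- withr::with_seed(9, sample.int(d$n))
  dp <- subcox:::subset_rows(d, perm)
  pmp <- estimate_subgroup_probs(dp, centroid_classifier,
                                 foldid = foldid[perm])
  expect_equal(pmp, pm[perm, ], tolerance = 1e-12)
})

test_that("weights are the probability-to-prior ratio", {
  # rows equal to the priors collapse to weight 1
  sg <- rep(1:2, c(3, 7))
  pm <- matrix(rep(c(0.3, 0.7), each = 10), 10, 2)
  wm <- compute_weight_matrix(pm, sg)
  expect_equal(unname(wm$values), matrix(1, 10, 2))
  expect_equal(wm$priors, c(0.3, 0.7))

  # a perfect classifier on 4 equal subgroups: members weight 4, others 0
  sg4 <- rep(1:4, each = 5)
  pm4 <- outer(sg4, 1:4, function(a, b) as.numeric(a == b))
  wm4 <- compute_weight_matrix(pm4, sg4)
  expect_equal(wm4$values[cbind(1:20, sg4)], rep(4, 20))
  expect_equal(sum(wm4$values == 0), 60)
})

test_that("priors and ratio identity reconstruct the probabilities", {
  d <- make_separable(n = 50, gap = 1, seed = 45)
  pm <- estimate_subgroup_probs(d, centroid_classifier, foldid = rep_len(1:5, 50))
  wm <- compute_weight_matrix(pm, d$subgroups)
  expect_equal(sweep(wm$values, 2, wm$priors, "*"), wm$prob_matrix)
  expect_true(all(wm$values >= 0))
  # an unbalanced prior: probs (0.5, 0.5) against priors (0.1, 0.9)
  sg <- rep(1:2, c(1, 9))
  pmu <- matrix(0.5, 10, 2)
  wmu <- compute_weight_matrix(pmu, sg)
  expect_equal(unname(wmu$values[1, ]), c(5, 0.5 / 0.9), tolerance = 1e-4)
})

test_that("degenerate weight-matrix inputs are rejected", {
  expect_error(compute_weight_matrix(matrix(c(0.4, 0.7), 1, 2), 1),
               "summing to 1")
  pm <- matrix(0.5, 4, 2)
  expect_error(compute_weight_matrix(pm, rep(1, 4)), "empty subgroup")
  expect_error(compute_weight_matrix(pm, rep(1, 3)), "dimension")
})

test_that("estimated weight columns are calibrated near 1 for similar subgroups", {
  cfg <- simulation_config(n_per_subgroup = 125, p = 12, epsilon = 0,
                           seed = 46)
  d <- generate_dataset(cfg)
  wm <- estimate_weights(d, "rf", seed = 3)
  expect_true(all(abs(colMeans(wm$values) - 1) < 0.1))
})

test_that("group-separation AUC matches exhaustive pair counting", {
  # no discrimination: identical scores for all patients
  d <- make_separable(n = 20, gap = 0, seed = 47)
  pm_flat <- matrix(0.5, 20, 2)
  expect_equal(group_separation_auc(d, c(1, 2), prob_matrix = pm_flat), 0.5)

  # perfect separation
  pm_perf <- cbind(as.numeric(d$subgroups == 1), as.numeric(d$subgroups == 2))
  expect_equal(group_separation_auc(d, c(1, 2), prob_matrix = pm_perf), 1)

  # 20 hand-listed scores incl. ties vs the brute-force pair oracle
  score <- c(0.9, 0.8, 0.8, 0.75, 0.7, 0.6, 0.6, 0.55, 0.5, 0.45,
             0.4, 0.6, 0.35, 0.3, 0.8, 0.25, 0.2, 0.15, 0.1, 0.05)
  pm_h <- cbind(score, 1 - score)
  expect_equal(group_separation_auc(d, c(1, 2), prob_matrix = pm_h),
               oracle_auc(score, d$subgroups == 1))
  expect_error(group_separation_auc(d, c(1, 1), prob_matrix = pm_h),
               "nonempty")
})

test_that("weight matrices round-trip to CSV with a JSON sidecar", {
  pm <- matrix(c(0.2, 0.8, 0.6, 0.4), 2, 2, byrow = TRUE)
  wm <- compute_weight_matrix(pm, c(2, 1), classifier = "rf")
  f <- withr::local_tempfile(fileext = ".csv")
  write_weight_matrix(wm, f, seed = 5)
  tab <- as.matrix(utils::read.csv(f))
  expect_equal(unname(tab), unname(wm$values))
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", f))
  expect_equal(meta$classifier, "rf")
})
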