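test_that("a large enough penalty shrinks every coefficient to exactly zero", {
  d <- random_survdata(n = 40, p = 6, seed = 21)
  w <- rep(1, d$n)
  # the top of the automatic grid is the smallest all-zero lambda
  lam <- select_lambda_cv(d, w, seed = 1)
  grid <- attr(lam, "cv_curve")$lambda
  f <- fit_weighted_cox_lasso(d, w, max(grid))
  expect_identical(unname(f$coefficients), rep(0, 6))
  expect_equal(f$n_nonzero, 0)
  f2 <- fit_weighted_cox_lasso(d, w, max(grid) * 2)
  expect_identical(unname(f2$coefficients), rep(0, 6))
})

test_that("the unpenalized fit matches an independent Newton-Raphson oracle", {
  d <- random_survdata(n = 60, p = 3, seed = 22)
  f <- fit_weighted_cox_lasso(d, rep(1, d$n), 0)
  cp <- survival::coxph(survival::Surv(d$times, d$events) ~ d$covariates,
                        ties = "breslow")
  expect_lt(max(abs(f$coefficients - coef(cp))), 1e-4)
})

test_that("rescaling all weights by a constant leaves the fit unchanged", {
  d <- random_survdata(n = 50, p = 5, seed = 23)
  w <- withr::with_seed(9, runif(d$n, 0.2, 3))
  for (lam in c(0.15, 0.05)) {
    f1 <- fit_weighted_cox_lasso(d, w, lam)
    f7 <- fit_weighted_cox_lasso(d, 7 * w, lam)
    expect_equal(f1$coefficients, f7$coefficients)
    expect_equal(f1$weights_used, f7$weights_used)  # both normalized to sum n
    expect_equal(sum(f1$weights_used), d$n)
  }
})

test_that("a zero-weight patient is equivalent to a deleted patient at every lambda", {
  d <- random_survdata(n = 45, p = 4, seed = 24)
  for (drop_i in c(which(d$events == 1)[1], which(d$events == 0)[1])) {
    w <- rep(1, d$n); w[drop_i] <- 0
    dd <- subcox:::subset_rows(d, setdiff(seq_len(d$n), drop_i))
    for (lam in c(0.2, 0.08, 0.02, 0)) {
      f0 <- fit_weighted_cox_lasso(d, w, lam)
      fdel <- fit_weighted_cox_lasso(dd, rep(1, dd$n), lam)
      expect_equal(f0$coefficients, fdel$coefficients, tolerance = 1e-8)
    }
  }
})

test_that("sparsity is non-increasing along an increasing lambda grid", {
  for (seed in 1:20) {
    d <- random_survdata(n = sample(25:40, 1), p = sample(4:8, 1),
                         seed = 300 + seed)
    w <- withr::with_seed(seed, runif(d$n, 0.5, 2))
    lam <- select_lambda_cv(d, w, seed = seed)
    grid <- sort(attr(lam, "cv_curve")$lambda)
    grid <- grid[seq(1, length(grid), by = 12)]
    nz <- vapply(grid, function(l) {
      b <- fit_weighted_cox_lasso(d, w, l)$coefficients
      sum(abs(b) > 1e-6)  # ties at the solver tolerance excluded
    }, numeric(1))
    expect_true(all(diff(nz) <= 0),
                info = sprintf("seed %d: nnz %s", seed, paste(nz, collapse = ",")))
  }
})

test_that("the returned solution satisfies the lasso KKT conditions", {
  for (seed in c(31, 32)) {
    d <- random_survdata(n = 50, p = 6, seed = seed)
    w <- withr::with_seed(seed, runif(d$n, 0.3, 2))
    lam <- 0.06
    f <- fit_weighted_cox_lasso(d, w, lam)
    wn <- f$weights_used
    v <- wn / sum(wn)
    m <- colSums(d$covariates * v)
    sdv <- sqrt(colSums(sweep(d$covariates, 2, m)^2 * v))
    xs <- sweep(sweep(d$covariates, 2, m), 2, sdv, "/")
    ds <- subgroup_surv(d$times, d$events, d$subgroups, xs)
    g <- subcox:::weighted_cox_score(f$coefficients * sdv, ds, wn) / d$n
    active <- f$coefficients != 0
    tol <- 5e-4
    expect_true(all(abs(g[!active]) <= lam + tol))
    if (any(active)) {
      expect_true(all(abs(abs(g[active]) - lam) <= tol))
      expect_equal(sign(g[active]), sign(f$coefficients[active]))
    }
  }
})

test_that("fits without usable events are rejected", {
  d <- random_survdata(n = 20, p = 3, seed = 25)
  w <- ifelse(d$events == 1, 0, 1)
  expect_error(fit_weighted_cox_lasso(d, w, 0.1), "no usable events")
  expect_error(fit_weighted_cox_lasso(d, rep(1, d$n), -0.5), "lambda")
  expect_error(fit_weighted_cox_lasso(d, rep(-1, d$n), 0.1), "nonnegative")
})

test_that("cross-validated lambda selection is deterministic and grid-valued", {
  d <- random_survdata(n = 40, p = 5, seed = 26)
  w <- rep(1, d$n)
  l1 <- select_lambda_cv(d, w, seed = 42)
  l2 <- select_lambda_cv(d, w, seed = 42)
  expect_identical(as.numeric(l1), as.numeric(l2))
  expect_true(as.numeric(l1) %in% attr(l1, "cv_curve")$lambda)
  l3 <- select_lambda_cv(d, w, seed = 43)
  expect_true(is.finite(as.numeric(l3)))
})

test_that("the CV deviance agrees with an independent cross-validation implementation", {
  d <- generate_dataset(simulation_config(50, 12, 0.5, seed = 90))
  w <- rep(1, d$n)
  lam <- select_lambda_cv(d, w, seed = 55)
  # hand cv.glmnet the identical fold partition
  foldid <- subcox:::make_folds(d$events, 10, 55)
  cv <- glmnet::cv.glmnet(d$covariates, survival::Surv(d$times, d$events),
                          family = "cox", weights = w, foldid = foldid,
                          type.measure = "deviance", grouped = TRUE)
  expect_equal(as.numeric(lam), cv$lambda.min, tolerance = 1e-10)
  curve <- attr(lam, "cv_curve")
  i <- match(round(cv$lambda, 8), round(curve$lambda, 8))
  expect_gt(stats::cor(cv$cvm, curve$deviance[i], use = "complete.obs"),
            0.999)
})

test_that("two folds on a four-patient toy set run and return a grid member", {
  d <- subgroup_surv(c(1, 2, 3, 4), c(1, 0, 1, 0), c(1, 1, 1, 1),
                     matrix(c(0.1, -0.2, 0.5, 1, 0.3, 0, -1, 0.4), 4, 2))
  lam <- suppressWarnings(select_lambda_cv(d, rep(1, 4), n_folds = 2, seed = 1))
  expect_true(as.numeric(lam) %in% attr(lam, "cv_curve")$lambda)
})

test_that("under a pure-noise truth the selected penalty yields a near-null model", {
  hits <- 0
  for (seed in 1:10) {
    d <- withr::with_seed(seed + 700, {
      subgroup_surv(rexp(100) + 0.05, rbinom(100, 1, 0.6),
                    rep(1:2, 50), matrix(rnorm(1200), 100, 12))
    })
    lam <- select_lambda_cv(d, rep(1, 100), seed = seed)
    f <- fit_weighted_cox_lasso(d, rep(1, 100), as.numeric(lam))
    if (f$n_nonzero <= 2) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("fixed weight vectors follow the target-subgroup case rule", {
  d <- random_survdata(n = 40, p = 3, S = 4, seed = 27)
  w <- fixed_weight_vector(d, 2, 0.3)
  expect_identical(w, ifelse(d$subgroups == 2, 1, 0.3))
  expect_equal(sum(w == 1), 10)
  expect_equal(sum(w == 0.3), 30)
  expect_error(fixed_weight_vector(d, 2, 1.2), "\\[0, 1\\]")
  expect_error(fixed_weight_vector(d, 9, 0.5), "target_subgroup")
})

test_that("fit_model dispatches the four model modes correctly", {
  cfg <- simulation_config(n_per_subgroup = 15, p = 12, epsilon = 0.5,
                           seed = 77)
  d <- generate_dataset(cfg)

  fsub <- fit_model(model_spec("subgroup", 2), d, seed = 5)
  expect_length(fsub$coefficients, 12)
  expect_identical(fsub$mode, "subgroup")
  # subgroup fit uses exactly the target subgroup rows
  expect_length(fsub$weights_used, 15)

  fall <- fit_model(model_spec("combined", 1), d, seed = 5)
  expect_length(fall$coefficients, 12 + 3)  # S-1 dummy columns
  expect_identical(names(fall$coefficients)[13:15],
                   c("subgroup2", "subgroup3", "subgroup4"))

  fw0 <- fit_model(model_spec("fixed_weights", 2, fixed_w = 0), d, seed = 5)
  expect_equal(fw0$coefficients, fsub$coefficients, tolerance = 1e-8)

  # w = 1 is the pooled fit without the subgroup indicator
  fw1 <- fit_model(model_spec("fixed_weights", 2, fixed_w = 1), d, seed = 5)
  fpool <- fit_model(model_spec("combined", 2,
                                include_subgroup_indicator = FALSE),
                     d, seed = 5)
  expect_equal(fw1$coefficients, fpool$coefficients, tolerance = 1e-10)
})

test_that("model specifications are validated", {
  expect_error(model_spec("fixed_weights", 1), "fixed_w")
  expect_error(model_spec("subgroup", 1, fixed_w = 0.5), "fixed_w")
  expect_error(model_spec("estimated_weights", 1), "classifier")
  expect_error(model_spec("subgroup", 1, classifier = "rf"), "classifier")
})

test_that("fits round-trip to CSV with a JSON sidecar", {
  d <- random_survdata(n = 40, p = 4, seed = 28)
  f <- fit_weighted_cox_lasso(d, rep(1, d$n), 0.05)
  f$mode <- "subgroup"
  csv <- withr::local_tempfile(fileext = ".csv")
  write_fit(f, csv, seed = 1)
  tab <- utils::read.csv(csv)
  expect_equal(tab$coefficient, unname(f$coefficients))
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", csv))
  expect_equal(meta$lambda, 0.05)
  expect_equal(meta$mode, "subgroup")
})
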