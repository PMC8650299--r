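# The replicated experiment loop: generate (or split) data, estimate weights
# on the training part, fit every model variant for every subgroup, and
# evaluate each on the corresponding subgroup's test rows.

#' Stratified train/test split
#'
#' Splits within each (subgroup x event) cell so that subgroup sizes and
#' censoring proportions are preserved: `round(train_fraction * cell size)`
#' rows of every cell go to the training set.
#'
#' @param data A [subgroup_surv] object with every (subgroup x event) cell
#'   nonempty.
#' @param train_fraction Proportion assigned to training (default 0.632).
#' @param seed Integer seed; the split is deterministic given it.
#' @return List with `train`, `test` (both `subgroup_surv`; `test` may have
#'   zero rows at the boundary `train_fraction = 1`), and the row indices
#'   `train_idx`, `test_idx`.
#' @export
stratified_split <- function(data, train_fraction = 0.632, seed = 1) {
  stopifnot(inherits(data, "subgroup_surv"))
  if (train_fraction <= 0 || train_fraction > 1)
    stop("validation error: train_fraction must lie in (0, 1]")
  cell <- interaction(data$subgroups, data$events, drop = TRUE)
  train_idx <- integer(0)
  with_seed(seed, {
    for (lev in levels(cell)) {
      idx <- which(cell == lev)
      if (length(idx) < 2) {
        warning(sprintf("stratum %s has fewer than 2 rows; assigned wholly to training", lev))
        train_idx <- c(train_idx, idx)
        next
      }
      k <- round(train_fraction * length(idx))
      train_idx <- c(train_idx, idx[sample.int(length(idx), k)])
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(data$n), train_idx)
  list(train = subset_rows(data, train_idx),
       test = subset_rows(data, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' The standard 14-model menu
#'
#' Estimated-weights models for each classifier (`lasso`, `ridge`, `rf`),
#' fixed-weight models at `w = 0.1, ..., 0.9`, the subgroup-only model
#' (`sub`) and the pooled model with subgroup indicator (`all`).
#'
#' @return Named list of model templates (mode plus `fixed_w`/`classifier`);
#'   [run_simulation_experiment()] instantiates each per target subgroup.
#' @export
model_menu <- function() {
  menu <- list(
    lasso = list(mode = "estimated_weights", classifier = "lasso"),
    ridge = list(mode = "estimated_weights", classifier = "ridge"),
    rf    = list(mode = "estimated_weights", classifier = "rf"))
  for (w in seq(0.1, 0.9, by = 0.1))
    menu[[sprintf("w%.1f", w)]] <- list(mode = "fixed_weights", fixed_w = w)
  menu$sub <- list(mode = "subgroup")
  menu$all <- list(mode = "combined")
  menu
}

template_spec <- function(tpl, target_subgroup) {
  model_spec(mode = tpl$mode, target_subgroup = target_subgroup,
             fixed_w = tpl$fixed_w, classifier = tpl$classifier)
}

# Fit and evaluate every (model, subgroup) combination for one train/test
# pair. Weight matrices are estimated once per classifier on a fold partition
# shared across classifiers; the pooled fit is computed once and scored per
# subgroup. Only training rows ever reach weight estimation or fitting.
run_replicate <- function(train, test, models, seed, n_folds = 10,
                          keep_coefficients = FALSE, verbose = FALSE,
                          replicate_id = 1L) {
  S <- train$S
  p0 <- train$p
  model_names <- names(models)
  classifiers <- unique(unlist(lapply(models, function(m)
    if (m$mode == "estimated_weights") m$classifier)))
  shared_foldid <- make_folds(train$subgroups, n_folds, derive_seed(seed, 11L))
  wms <- list()
  for (cl in classifiers)
    wms[[cl]] <- estimate_weights(train, classifier = cl, n_folds = n_folds,
                                  seed = derive_seed(seed, 13L),
                                  foldid = shared_foldid)
  fit_seed <- derive_seed(seed, 17L)
  combined_fit <- NULL
  records <- vector("list", length(models) * S)
  selection <- array(NA, dim = c(p0, length(models), S),
                     dimnames = list(colnames(train$covariates), model_names,
                                     NULL))
  coefs <- if (keep_coefficients)
    array(NA_real_, dim = dim(selection), dimnames = dimnames(selection))
  failed <- FALSE
  ri <- 0L
  for (s in seq_len(S)) {
    for (m in seq_along(models)) {
      ri <- ri + 1L
      rec <- data.frame(replicate = replicate_id, subgroup = s,
                        model = model_names[m], cindex = NA_real_,
                        n_nonzero = NA_integer_, lambda = NA_real_)
      res <- tryCatch({
        tpl <- models[[m]]
        spec <- template_spec(tpl, s)
        fit <- if (tpl$mode == "combined") {
          # the pooled fit does not depend on the target subgroup: fit once
          if (is.null(combined_fit))
            combined_fit <- fit_model(spec, train, seed = fit_seed,
                                      n_folds = n_folds)
          combined_fit
        } else {
          fit_model(spec, train, seed = fit_seed,
                    weight_matrix = if (tpl$mode == "estimated_weights")
                      wms[[tpl$classifier]],
                    n_folds = n_folds)
        }
        ci <- score_fit(fit, test, s)
        list(fit = fit, ci = ci)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed <- TRUE
        if (verbose)
          message(sprintf("replicate %d subgroup %d model %s failed: %s",
                          replicate_id, s, model_names[m],
                          conditionMessage(res)))
      } else {
        b <- res$fit$coefficients[seq_len(p0)]
        rec$cindex <- res$ci
        rec$n_nonzero <- res$fit$n_nonzero
        rec$lambda <- res$fit$lambda
        selection[, m, s] <- b != 0
        if (keep_coefficients) coefs[, m, s] <- b
        if (verbose)
          message(sprintf("replicate %d subgroup %d model %-5s CI %.3f (%d nonzero)",
                          replicate_id, s, model_names[m], res$ci,
                          res$fit$n_nonzero))
      }
      records[[ri]] <- rec
    }
  }
  list(records = do.call(rbind, records), selection = selection,
       coefficients = coefs, failed = failed)
}

assemble_experiment <- function(reps_out, models, config, seed, rep_seeds,
                                keep_coefficients, kind) {
  records <- do.call(rbind, lapply(reps_out, `[[`, "records"))
  sel_list <- lapply(reps_out, `[[`, "selection")
  sel_sum <- Reduce(`+`, lapply(sel_list, function(a) {
    a[is.na(a)] <- 0
    a
  }))
  n_ok <- Reduce(`+`, lapply(sel_list, function(a)
    matrix(!is.na(a[1, , , drop = FALSE]), dim(a)[2], dim(a)[3])))
  failed_reps <- which(vapply(reps_out, `[[`, logical(1), "failed"))
  structure(list(records = records, selection_counts = sel_sum, n_ok = n_ok,
                 model_names = names(models), config = config, seed = seed,
                 rep_seeds = rep_seeds, n_reps = length(reps_out),
                 failed_replicates = failed_reps,
                 coefficients = if (keep_coefficients)
                   lapply(reps_out, `[[`, "coefficients"),
                 kind = kind),
            class = "subgroup_experiment")
}

#' Run the replicated simulation experiment
#'
#' For each replicate a fresh training and an independent test dataset are
#' generated from the same scenario ([generate_dataset()]); individual
#' weights are estimated on the training data only; every model of the menu
#' is fitted per target subgroup (penalty by 10-fold CV) and evaluated by
#' Harrell's C-index on the corresponding subgroup's test rows. A master seed
#' spawns per-replicate seeds so replicates are independent and individually
#' reproducible.
#'
#' @param config A [simulation_config()] (its own `seed` field is ignored
#'   here; the per-replicate seeds control generation).
#' @param n_reps Number of replicates (default 100).
#' @param models Model menu as in [model_menu()] (any nonempty subset).
#' @param seed Master integer seed.
#' @param n_folds CV folds for weight estimation and penalty selection.
#' @param keep_coefficients Keep the per-replicate coefficient arrays
#'   (memory-heavy; default `FALSE`).
#' @param verbose Emit a progress line per (replicate, subgroup, model).
#' @param rep_seeds Optional explicit vector of `n_reps` replicate seeds,
#'   overriding the derived ones.
#' @return A `subgroup_experiment` object; see [summary.subgroup_experiment()]
#'   and [mif()]. Replicate-level failures are recorded as missing values; if
#'   more than 20\% of replicates fail the run errors.
#' @export
run_simulation_experiment <- function(config, n_reps = 100,
                                      models = model_menu(), seed = 1,
                                      n_folds = 10,
                                      keep_coefficients = FALSE,
                                      verbose = FALSE, rep_seeds = NULL) {
  stopifnot(inherits(config, "simulation_config"), n_reps >= 1,
            length(models) >= 1)
  rep_seeds <- rep_seeds %||% vapply(seq_len(n_reps), function(r)
    derive_seed(seed, r), integer(1))
  stopifnot(length(rep_seeds) == n_reps)
  reps_out <- lapply(seq_len(n_reps), function(r) {
    rs <- rep_seeds[r]
    cfg_train <- config; cfg_train$seed <- rs
    cfg_test <- config; cfg_test$seed <- derive_seed(rs, 555L)
    train <- generate_dataset(cfg_train)
    test <- generate_dataset(cfg_test)
    run_replicate(train, test, models, seed = rs, n_folds = n_folds,
                  keep_coefficients = keep_coefficients, verbose = verbose,
                  replicate_id = r)
  })
  out <- assemble_experiment(reps_out, models, config, seed, rep_seeds,
                             keep_coefficients, kind = "simulation")
  if (length(out$failed_replicates) > 0.2 * n_reps)
    stop(sprintf("run-level error: %d of %d replicates failed",
                 length(out$failed_replicates), n_reps))
  out
}

#' Run the repeated-split experiment on a fixed dataset
#'
#' The real-data analogue of [run_simulation_experiment()]: the complete data
#' are repeatedly split into training (proportion `train_fraction`) and test
#' sets, stratified by subgroup and event indicator, and the same
#' fit-and-evaluate loop is run per split.
#'
#' @param data A [subgroup_surv] object or a path to a CSV/TSV file in the
#'   [read_subgroup_surv()] dialect.
#' @param n_splits Number of random splits (default 100).
#' @param train_fraction Training proportion (default 0.632).
#' @inheritParams run_simulation_experiment
#' @return A `subgroup_experiment` object.
#' @export
run_real_data_experiment <- function(data, n_splits = 100,
                                     models = model_menu(),
                                     train_fraction = 0.632, seed = 1,
                                     n_folds = 10,
                                     keep_coefficients = FALSE,
                                     verbose = FALSE, rep_seeds = NULL) {
  if (is.character(data)) data <- read_subgroup_surv(data)
  stopifnot(inherits(data, "subgroup_surv"), n_splits >= 1)
  rep_seeds <- rep_seeds %||% vapply(seq_len(n_splits), function(r)
    derive_seed(seed, r), integer(1))
  reps_out <- lapply(seq_len(n_splits), function(r) {
    sp <- stratified_split(data, train_fraction, seed = rep_seeds[r])
    run_replicate(sp$train, sp$test, models, seed = rep_seeds[r],
                  n_folds = n_folds, keep_coefficients = keep_coefficients,
                  verbose = verbose, replicate_id = r)
  })
  out <- assemble_experiment(reps_out, models, NULL, seed, rep_seeds,
                             keep_coefficients, kind = "real_data")
  if (length(out$failed_replicates) > 0.2 * n_splits)
    stop(sprintf("run-level error: %d of %d splits failed",
                 length(out$failed_replicates), n_splits))
  out
}

#' Mean inclusion frequencies
#'
#' MIF of covariate `j` under a model (and target subgroup) is the fraction
#' of successful replicates in which the fitted coefficient is nonzero.
#'
#' @param result A `subgroup_experiment`.
#' @return A 3-d array `covariate x model x subgroup` of frequencies in
#'   `[0, 1]`.
#' @export
mif <- function(result) {
  stopifnot(inherits(result, "subgroup_experiment"))
  out <- result$selection_counts
  d <- dim(out)
  for (s in seq_len(d[3])) for (m in seq_len(d[2]))
    out[, m, s] <- out[, m, s] / max(result$n_ok[m, s], 1)
  out
}

#' Summarize an experiment
#'
#' @param object A `subgroup_experiment`.
#' @param ... Unused.
#' @return List with `mean_cindex` (per model, averaged over subgroups and
#'   replicates, missing records excluded pairwise), `cindex_by_subgroup`
#'   (model x subgroup matrix) and `n_failed_replicates`.
#' @export
summary.subgroup_experiment <- function(object, ...) {
  rec <- object$records
  rec$model <- factor(rec$model, levels = object$model_names)
  overall <- tapply(rec$cindex, rec$model, mean, na.rm = TRUE)
  bysub <- tapply(rec$cindex, list(rec$model, rec$subgroup), mean,
                  na.rm = TRUE)
  list(mean_cindex = overall, cindex_by_subgroup = bysub,
       n_failed_replicates = length(object$failed_replicates))
}

#' @export
print.subgroup_experiment <- function(x, ...) {
  cat(sprintf("subgroup_experiment (%s): %d replicates, %d models, %d record rows\n",
              x$kind, x$n_reps, length(x$model_names), nrow(x$records)))
  s <- summary(x)
  cat("mean C-index per model:\n")
  print(round(s$mean_cindex, 4))
  if (length(x$failed_replicates))
    cat(sprintf("failed replicates: %d\n", length(x$failed_replicates)))
  invisible(x)
}

#' Write experiment outputs
#'
#' Writes the tidy per-record table (`records.csv`), the long-format MIF
#' table (`mif.csv`) and a summary JSON (`summary.json`) into a directory.
#'
#' @param result A `subgroup_experiment`.
#' @param dir Output directory (created if missing).
#' @export
write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  m <- mif(result)
  long <- do.call(rbind, lapply(seq_len(dim(m)[3]), function(s) {
    data.frame(covariate = rep(rownames(m), times = dim(m)[2]),
               model = rep(colnames(m), each = dim(m)[1]),
               subgroup = s, mif = as.vector(m[, , s]))
  }))
  utils::write.csv(long, file.path(dir, "mif.csv"), row.names = FALSE)
  s <- summary(result)
  jsonlite::write_json(
    list(kind = result$kind, n_reps = result$n_reps, seed = result$seed,
         models = result$model_names,
         mean_cindex = as.list(s$mean_cindex),
         n_failed_replicates = s$n_failed_replicates),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
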