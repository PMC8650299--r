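#' Subgrouped survival data
#'
#' The universal input container: per patient an observed time \eqn{t_i > 0},
#' an event indicator \eqn{\delta_i \in \{0,1\}} (1 = event, 0 = right
#' censored), an integer subgroup label \eqn{s_i \in \{1,\dots,S\}}, and a row
#' of the \eqn{n \times p} covariate matrix \eqn{x_i}.
#'
#' @param times Positive numeric vector of observed times.
#' @param events Binary (0/1) event indicators, same length.
#' @param subgroups Integer subgroup labels in `1..S`; every label in the range
#'   must occur at least once.
#' @param covariates Numeric matrix with one row per patient; column names are
#'   kept (defaults `x1..xp`).
#' @param subgroup_names Optional character vector of length `S` naming the
#'   labels (e.g. cohort identifiers).
#'
#' @return An object of class `subgroup_surv`: a list with elements `times`,
#'   `events`, `subgroups`, `covariates`, `n`, `p`, `S`, `subgroup_names`.
#' @export
#' @examples
#' d <- subgroup_surv(times = c(1, 2, 3, 4), events = c(1, 0, 1, 1),
#'                    subgroups = c(1, 1, 2, 2),
#'                    covariates = matrix(rnorm(8), 4, 2))
#' d$S
subgroup_surv <- function(times, events, subgroups, covariates,
                          subgroup_names = NULL) {
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  n <- length(times)
  if (length(events) != n || length(subgroups) != n || nrow(covariates) != n)
    stop("dimension mismatch: times, events, subgroups and covariate rows must share length n")
  if (anyNA(times) || anyNA(events) || anyNA(subgroups) || anyNA(covariates))
    stop("validation error: missing values are not allowed")
  if (!all(is.finite(times)) || any(times <= 0))
    stop("validation error: times must be strictly positive and finite")
  if (!all(events %in% c(0, 1)))
    stop("validation error: events must be 0/1")
  if (!all(is.finite(covariates)))
    stop("validation error: nonfinite covariates")
  subgroups <- as.integer(subgroups)
  S <- max(subgroups)
  if (min(subgroups) < 1L || !all(seq_len(S) %in% subgroups))
    stop("validation error: subgroup labels must cover 1..S with every label present")
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  if (!is.null(subgroup_names) && length(subgroup_names) != S)
    stop("validation error: subgroup_names must have length S")
  structure(list(times = as.double(times), events = as.integer(events),
                 subgroups = subgroups, covariates = covariates,
                 n = n, p = ncol(covariates), S = S,
                 subgroup_names = subgroup_names),
            class = "subgroup_surv")
}

#' @export
print.subgroup_surv <- function(x, ...) {
  cat(sprintf("subgroup_surv: n = %d patients, p = %d covariates, S = %d subgroups\n",
              x$n, x$p, x$S))
  tab <- table(x$subgroups)
  lab <- if (!is.null(x$subgroup_names)) x$subgroup_names else names(tab)
  cat(sprintf("  subgroup sizes: %s\n",
              paste(sprintf("%s=%d", lab, tab), collapse = ", ")))
  cat(sprintf("  events: %d (%.1f%%)\n", sum(x$events),
              100 * mean(x$events)))
  invisible(x)
}

# Row subset preserving structure; drop_relabel = TRUE remaps the remaining
# labels to 1..S' (needed when whole subgroups are removed).
subset_rows <- function(data, idx, drop_relabel = FALSE) {
  sg <- data$subgroups[idx]
  nm <- data$subgroup_names
  if (drop_relabel) {
    lev <- sort(unique(sg))
    if (!is.null(nm)) nm <- nm[lev]
    sg <- match(sg, lev)
  }
  structure(list(times = data$times[idx], events = data$events[idx],
                 subgroups = sg,
                 covariates = data$covariates[idx, , drop = FALSE],
                 n = length(idx), p = data$p,
                 S = if (drop_relabel) max(sg) else data$S,
                 subgroup_names = nm),
            class = "subgroup_surv")
}

#' Read subgrouped survival data from a delimited text file
#'
#' Expects a header row with columns `time`, `status` (0/1) and `subgroup`;
#' all remaining columns are taken as numeric covariates. Subgroup labels may
#' be arbitrary (strings, cohort accessions); they are mapped to integers
#' `1..S` in sorted order and the originals kept as `subgroup_names`.
#'
#' @param file Path to a CSV or TSV file (delimiter auto-detected from the
#'   extension; `.tsv`/`.txt` are read as tab-separated).
#' @param sep Field delimiter, overriding auto-detection.
#' @return A [subgroup_surv] object.
#' @export
read_subgroup_surv <- function(file, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", file, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("time", "status", "subgroup")
  if (!all(need %in% names(df)))
    stop("validation error: file must contain named columns time, status, subgroup")
  lab <- df$subgroup
  lev <- sort(unique(lab))
  covars <- df[, setdiff(names(df), need), drop = FALSE]
  subgroup_surv(times = df$time, events = df$status,
                subgroups = match(lab, lev),
                covariates = as.matrix(covars),
                subgroup_names = as.character(lev))
}

#' Write subgrouped survival data to CSV
#'
#' Inverse of [read_subgroup_surv()]: columns `time`, `status`, `subgroup`
#' followed by the covariates.
#'
#' @param data A [subgroup_surv] object.
#' @param file Output path.
#' @export
write_subgroup_surv <- function(data, file) {
  sg <- if (!is.null(data$subgroup_names))
    data$subgroup_names[data$subgroups] else data$subgroups
  df <- data.frame(time = data$times, status = data$events, subgroup = sg,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(data$covariates, check.names = FALSE))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
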