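#' Restrict cohorts to their common probes
#'
#' 27K-platform exports carry (roughly) a subset of the 450K probe set, so a
#' model trained across platforms can only use probes measured everywhere.
#' All matrices are restricted to the probes present in every input, ordered
#' as in the first matrix; sample axes are untouched.
#'
#' @param matrices List of [beta_matrix()] objects (at least one).
#' @return List of [beta_matrix()] objects on the shared probe set.
#' @export
intersect_features <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  common <- Reduce(intersect, lapply(matrices, rownames))
  # preserve first matrix's order
  common <- rownames(matrices[[1]])[rownames(matrices[[1]]) %in% common]
  if (length(common) == 0) {
    stop("no probes shared by all cohorts (empty feature intersection)",
         call. = FALSE)
  }
  lapply(matrices, align_to_features, cpg_ids = common)
}

#' Remove CpGs with a high fraction of missing values
#'
#' A probe is removed iff its missing fraction strictly exceeds
#' `max_missing_frac` ("more than 20 percent" by default, so exactly-20%
#' probes survive). Survivor order is preserved.
#'
#' @param x A [beta_matrix()].
#' @param max_missing_frac Maximum tolerated missing fraction, in \[0, 1).
#' @return List with `matrix` (filtered [beta_matrix()]) and `removed`
#'   (character vector of dropped probe ids).
#' @export
filter_missing_cpgs <- function(x, max_missing_frac = 0.2) {
  stopifnot(inherits(x, "beta_matrix"),
            max_missing_frac >= 0, max_missing_frac < 1)
  frac <- rowMeans(is.na(x))
  drop <- frac > max_missing_frac
  if (all(drop)) {
    stop("all probes exceed the missing-value threshold of ",
         max_missing_frac, call. = FALSE)
  }
  list(matrix = beta_matrix(unclass(x)[!drop, , drop = FALSE]),
       removed = rownames(x)[drop])
}

#' Fit an imputation model for missing beta values
#'
#' Median (default) and mean imputation store one per-probe fill statistic
#' over the observed values. KNN imputation stores the training matrix
#' itself: a missing entry is filled with the unweighted mean of that probe
#' over the `k` training samples nearest to the target sample, where
#' nearness is root-mean-square difference over mutually observed probes and
#' only training samples observed at the target probe are candidates.
#'
#' @param x A [beta_matrix()] (typically the pooled labelled cohorts).
#' @param strategy One of `"median"`, `"mean"`, `"knn"`.
#' @param k_neighbors Neighbour count for `"knn"`.
#' @return An object of class `imputation_model`.
#' @export
fit_imputer <- function(x, strategy = c("median", "mean", "knn"),
                        k_neighbors = 5) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(x, "beta_matrix"))
  n_obs <- rowSums(!is.na(x))
  if (any(n_obs == 0)) {
    stop("probe(s) with zero observed values: ",
         paste(utils::head(rownames(x)[n_obs == 0], 10), collapse = ", "),
         call. = FALSE)
  }
  model <- list(strategy = strategy, cpg_ids = rownames(x))
  if (strategy == "knn") {
    stopifnot(k_neighbors >= 1)
    model$k_neighbors <- as.integer(k_neighbors)
    model$reference <- unclass(x)
  } else {
    fun <- if (strategy == "median") stats::median else mean
    model$fill <- apply(unclass(x), 1, fun, na.rm = TRUE)
  }
  structure(model, class = "imputation_model")
}

#' @export
print.imputation_model <- function(x, ...) {
  cat(sprintf("<imputation_model> strategy=%s, %d probes%s\n",
              x$strategy, length(x$cpg_ids),
              if (x$strategy == "knn")
                sprintf(", k=%d, %d reference samples",
                        x$k_neighbors, ncol(x$reference)) else ""))
  invisible(x)
}

#' Fill missing beta values with a fitted imputation model
#'
#' Observed entries are never altered; after imputation no missing entries
#' remain and all filled values lie in \[0, 1\]. Every probe of `x` must be
#' covered by the model.
#'
#' @param model An `imputation_model` from [fit_imputer()].
#' @param x A [beta_matrix()].
#' @return A complete [beta_matrix()].
#' @export
apply_imputer <- function(model, x) {
  stopifnot(inherits(model, "imputation_model"), inherits(x, "beta_matrix"))
  absent <- setdiff(rownames(x), model$cpg_ids)
  if (length(absent) > 0) {
    stop("probe(s) not covered by imputation model: ",
         paste(utils::head(absent, 10), collapse = ", "), call. = FALSE)
  }
  vals <- unclass(x)
  miss <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(miss) == 0) return(x)
  if (model$strategy == "knn") {
    orig <- unclass(x)  # fills must not feed later neighbour searches
    for (r in seq_len(nrow(miss))) {
      i <- miss[r, 1]; j <- miss[r, 2]
      vals[i, j] <- knn_fill(model, rownames(x)[i], orig[, j])
    }
  } else {
    vals[miss] <- model$fill[rownames(x)[miss[, 1]]]
  }
  beta_matrix(vals)
}

# Fill one missing entry: probe `probe`, target sample profile `target`
# (named by that matrix's probes). Candidates are reference samples observed
# at `probe`; distance is RMS difference over probes observed in both
# profiles; ties broken by candidate column order.
knn_fill <- function(model, probe, target) {
  ref <- model$reference
  shared <- intersect(names(target), rownames(ref))
  tgt <- target[shared]
  candidates <- which(!is.na(ref[probe, ]))
  d <- vapply(candidates, function(j) {
    both <- !is.na(tgt) & !is.na(ref[shared, j])
    if (!any(both)) return(Inf)
    sqrt(mean((tgt[both] - ref[shared, j][both])^2))
  }, numeric(1))
  ord <- order(d, candidates)
  take <- candidates[ord][seq_len(min(model$k_neighbors, length(candidates)))]
  mean(ref[probe, take])
}

#' Preprocess labelled and unlabelled cohorts into one shared feature space
#'
#' The pipeline used before any training: (1) intersect probes across all
#' cohorts; (2) apply the missing-value filter per cohort and keep only
#' probes surviving in every cohort; (3) fit the imputer on the pooled
#' labelled cohorts only, so no fill statistic leaks from unlabelled or test
#' data; (4) impute every cohort with that one model.
#'
#' @param labeled List of [beta_matrix()] cohorts with labels available
#'   (at least one).
#' @param unlabeled Optional list of unlabelled [beta_matrix()] cohorts.
#' @param max_missing_frac Per-probe missing-fraction cutoff
#'   (see [filter_missing_cpgs()]).
#' @param strategy Imputation strategy (see [fit_imputer()]).
#' @param k_neighbors Neighbour count when `strategy = "knn"`.
#'
#' @return List with `labeled` and `unlabeled` (lists of complete
#'   [beta_matrix()] objects), `imputer` (the fitted `imputation_model`) and
#'   `report` (one-row tibble: `n_common_features`,
#'   `n_removed_by_missing_filter`, `n_final_features`, `strategy`).
#' @export
preprocess_cohorts <- function(labeled, unlabeled = list(),
                               max_missing_frac = 0.2,
                               strategy = c("median", "mean", "knn"),
                               k_neighbors = 5) {
  strategy <- match.arg(strategy)
  stopifnot(is.list(labeled), length(labeled) >= 1, is.list(unlabeled))
  n_lab <- length(labeled)
  all_mats <- intersect_features(c(labeled, unlabeled))
  n_common <- nrow(all_mats[[1]])

  survivors <- lapply(all_mats, function(m) {
    rownames(filter_missing_cpgs(m, max_missing_frac)$matrix)
  })
  keep <- Reduce(intersect, survivors)
  keep <- rownames(all_mats[[1]])[rownames(all_mats[[1]]) %in% keep]
  if (length(keep) == 0) {
    stop("no probes survive the missing-value filter in every cohort",
         call. = FALSE)
  }
  all_mats <- lapply(all_mats, align_to_features, cpg_ids = keep)

  pooled <- beta_matrix(do.call(cbind, lapply(all_mats[seq_len(n_lab)],
                                              unclass)))
  imputer <- fit_imputer(pooled, strategy = strategy,
                         k_neighbors = k_neighbors)
  all_mats <- lapply(all_mats, apply_imputer, model = imputer)

  report <- tibble::tibble(
    n_common_features = n_common,
    n_removed_by_missing_filter = n_common - length(keep),
    n_final_features = length(keep),
    strategy = strategy)
  list(labeled = all_mats[seq_len(n_lab)],
       unlabeled = if (length(unlabeled) > 0)
         all_mats[-seq_len(n_lab)] else list(),
       imputer = imputer,
       report = report)
}
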