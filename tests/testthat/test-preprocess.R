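make_bm <- function(vals, probes, samples) {
  beta_matrix(matrix(vals, nrow = length(probes), byrow = TRUE,
                     dimnames = list(probes, samples)))
}

test_that("feature intersection keeps only shared probes in first-input order", {
  m1 <- make_bm(runif(6), c("a", "b", "c"), c("s1", "s2"))
  m2 <- make_bm(runif(6), c("b", "c", "d"), c("t1", "t2"))
  out <- intersect_features(list(m1, m2))
  expect_identical(cpg_ids(out[[1]]), c("b", "c"))
  expect_identical(cpg_ids(out[[2]]), c("b", "c"))
  expect_identical(sample_ids(out[[2]]), c("t1", "t2"))
  expect_identical(unclass(out[[1]]), unclass(m1)[c("b", "c"), ])

  expect_identical(unclass(intersect_features(list(m1))[[1]]), unclass(m1))
  m3 <- make_bm(runif(2), "z", c("u1", "u2"))
  expect_error(intersect_features(list(m1, m3)), "intersection")
})

test_that("missing-value filter removes strictly-above-threshold probes only", {
  # 5 samples: p1 missing in 2/5 (40%) -> removed; p2 in exactly 1/5 (20%)
  # -> retained under the strict 'more than 20%' rule; p3 complete
  vals <- rbind(c(NA, NA, 0.2, 0.3, 0.4),
                c(NA, 0.1, 0.2, 0.3, 0.4),
                c(0.5, 0.5, 0.5, 0.5, 0.5))
  bm <- make_bm(as.vector(t(vals)), c("p1", "p2", "p3"), paste0("s", 1:5))
  res <- filter_missing_cpgs(bm, max_missing_frac = 0.2)
  expect_identical(res$removed, "p1")
  expect_identical(cpg_ids(res$matrix), c("p2", "p3"))

  # idempotence: filtering the filtered matrix removes nothing
  again <- filter_missing_cpgs(res$matrix, max_missing_frac = 0.2)
  expect_length(again$removed, 0)
  expect_identical(unclass(again$matrix), unclass(res$matrix))

  # monotonicity: higher tolerance never removes more probes
  set.seed(7)
  noisy <- inject_missing(toy_beta_matrix(30, 10, seed = 7), 0.1, seed = 8)
  survivors <- sapply(c(0, 0.1, 0.2, 0.4, 0.8), function(f) {
    nrow(filter_missing_cpgs(noisy, f)$matrix)
  })
  expect_true(all(diff(survivors) >= 0))

  all_missing <- make_bm(c(NA, NA), "p1", c("s1", "s2"))
  expect_error(filter_missing_cpgs(all_missing), "all probes")
})

test_that("median and mean imputers fit per-probe statistics over observed values", {
  bm <- make_bm(c(0.1, 0.3, 0.5,
                  0.0, 1.0, NA,
                  0.2, 0.4, NA),
                c("p1", "p2", "p3"), c("s1", "s2", "s3"))
  med <- fit_imputer(bm, "median")
  expect_equal(unname(med$fill["p1"]), 0.3)
  expect_equal(unname(med$fill["p2"]), 0.5)
  mn <- fit_imputer(bm, "mean")
  expect_equal(unname(mn$fill["p2"]), 0.5)
  expect_equal(unname(mn$fill["p3"]), 0.3)

  # fitting on unfiltered input with heavy missingness still succeeds
  wide <- make_bm(c(0.2, 0.4, NA, NA, NA, NA), "p1", paste0("s", 1:6))
  expect_equal(unname(fit_imputer(wide, "median")$fill["p1"]), 0.3)

  none <- make_bm(c(NA, NA), "p1", c("s1", "s2"))
  expect_error(fit_imputer(none, "median"), "p1")
})

test_that("imputation fills every gap without touching observed entries", {
  set.seed(11)
  bm <- inject_missing(toy_beta_matrix(12, 8, seed = 11), 0.15, seed = 12)
  for (strat in c("median", "mean", "knn")) {
    model <- fit_imputer(bm, strat, k_neighbors = 3)
    out <- apply_imputer(model, bm)
    expect_identical(sum(is.na(out)), 0L)
    obs <- !is.na(bm)
    expect_identical(unclass(out)[obs], unclass(bm)[obs])
    expect_true(all(out >= 0 & out <= 1))
  }
  # no-missing input is returned unchanged
  complete <- toy_beta_matrix(4, 3, seed = 2)
  model <- fit_imputer(complete, "median")
  expect_identical(unclass(apply_imputer(model, complete)),
                   unclass(complete))
  # single missing cell under a median model gets exactly the fitted median
  one <- make_bm(c(0.1, 0.3, 0.5, NA), c("p1", "p2"), c("s1", "s2"))
  filled <- apply_imputer(fit_imputer(one, "median"), one)
  expect_equal(filled["p2", "s2"], 0.5)
  # probes outside the model are an error
  other <- make_bm(runif(2), "pX", c("s1", "s2"))
  expect_error(apply_imputer(model, other), "pX")
})

test_that("knn imputation matches a brute-force neighbour search", {
  set.seed(21)
  bm <- inject_missing(toy_beta_matrix(10, 9, seed = 21), 0.2, seed = 22)
  k <- 3
  model <- fit_imputer(bm, "knn", k_neighbors = k)
  out <- apply_imputer(model, bm)
  vals <- unclass(bm)
  miss <- which(is.na(vals), arr.ind = TRUE)
  expect_gt(nrow(miss), 3)
  for (r in seq_len(nrow(miss))) {
    i <- miss[r, 1]; j <- miss[r, 2]
    # exhaustive pairwise RMS distance from sample j to all candidates
    cand <- setdiff(which(!is.na(vals[i, ])), integer(0))
    d <- sapply(cand, function(jj) {
      both <- !is.na(vals[, j]) & !is.na(vals[, jj])
      sqrt(mean((vals[both, j] - vals[both, jj])^2))
    })
    nn <- cand[order(d, cand)][seq_len(min(k, length(cand)))]
    expect_equal(unclass(out)[i, j], mean(vals[i, nn]))
  }
})

test_that("cohort preprocessing follows intersect/filter/fit/apply order", {
  # probe q is 40% missing in the unlabeled cohort only -> dropped everywhere
  lab <- make_bm(c(0.1, 0.2, 0.3, 0.4,
                   0.5, 0.6, 0.7, 0.8,
                   0.2, 0.2, 0.2, 0.2,
                   0.9, 0.9, 0.9, 0.9,
                   0.3, 0.3, 0.3, 0.3,
                   0.1, 0.1, 0.1, 0.1),
                 c("a", "b", "c", "d", "e", "q"), paste0("s", 1:4))
  unl <- make_bm(c(0.1, 0.2, 0.3, 0.4, 0.5,
                   0.5, 0.6, 0.7, 0.8, 0.9,
                   0.2, 0.2, 0.2, NA, 0.2,
                   0.9, 0.9, 0.9, 0.9, 0.9,
                   0.3, 0.3, 0.3, 0.3, 0.3,
                   NA, NA, 0.1, 0.1, 0.1),
                 c("a", "b", "c", "d", "e", "q"), paste0("u", 1:5))
  res <- preprocess_cohorts(list(lab), list(unl), max_missing_frac = 0.2)
  expect_false("q" %in% cpg_ids(res$labeled[[1]]))
  expect_false("q" %in% cpg_ids(res$unlabeled[[1]]))
  expect_identical(res$report$n_common_features, 6L)
  expect_identical(res$report$n_removed_by_missing_filter, 1L)
  expect_identical(res$report$n_final_features, 5L)
  # conservation
  expect_identical(res$report$n_final_features,
                   res$report$n_common_features -
                     res$report$n_removed_by_missing_filter)
  # imputer fitted on labelled data only: the unlabeled gap at (c, u4) is
  # filled with the labelled median of c (0.2), untouched by unlabeled values
  expect_equal(unclass(res$unlabeled[[1]])["c", "u4"], 0.2)
  expect_identical(sum(is.na(res$labeled[[1]])), 0L)
  expect_identical(sum(is.na(res$unlabeled[[1]])), 0L)
})

test_that("clean identical cohorts pass through preprocessing unchanged", {
  m1 <- toy_beta_matrix(6, 4, seed = 5)
  m2 <- toy_beta_matrix(6, 4, seed = 6)
  colnames(m2) <- paste0("t", 1:4)
  res <- preprocess_cohorts(list(m1), list(m2))
  expect_identical(unclass(res$labeled[[1]]), unclass(m1))
  expect_identical(unclass(res$unlabeled[[1]]), unclass(m2))
  expect_identical(res$report$n_removed_by_missing_filter, 0L)
})
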