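#' Specification for a synthetic class-conditional methylome
#'
#' Emulates the data regime the classifier is built for: each subtype owns a
#' disjoint block of informative CpGs whose beta values are drawn from a
#' hypermethylated (`Beta(8, 2)`) or hypomethylated (`Beta(2, 8)`)
#' distribution in members of that subtype, against a `Beta(2, 2)`
#' background everywhere else — mirroring the bimodality of array beta
#' values. Classes alternate hyper/hypo direction. Missingness is injected
#' completely at random; the unlabelled cohort can be mean-shifted on the
#' beta scale (then clipped to \[0, 1\]) as a deliberately crude batch-effect
#' proxy. The defaults are the package's benchmark conditions: 3 subtypes,
#' 300 CpGs with 30 informative per class, 40 labelled / 400 unlabelled /
#' 200 test samples, cohort shift 0.05, no missingness.
#'
#' @param n_classes Number of subtypes (>= 2).
#' @param n_cpgs Total CpG probes.
#' @param n_informative_per_class Informative CpGs per subtype (disjoint
#'   blocks; `n_classes * n_informative_per_class <= n_cpgs`).
#' @param background_shape Two positive shape parameters of the background
#'   beta distribution.
#' @param hyper_shape,hypo_shape Shapes for informative blocks of
#'   hyper-/hypomethylated classes.
#' @param class_proportions Sampling proportions over subtypes (normalised;
#'   default uniform).
#' @param n_labeled,n_unlabeled,n_test Cohort sizes.
#' @param missing_rate Per-entry missingness probability in \[0, 1).
#' @param cohort_shift Additive beta-scale mean shift applied to the
#'   unlabelled cohort (>= 0).
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 3, n_cpgs = 300,
                           n_informative_per_class = 30,
                           background_shape = c(2, 2),
                           hyper_shape = c(8, 2), hypo_shape = c(2, 8),
                           class_proportions = NULL,
                           n_labeled = 40, n_unlabeled = 400, n_test = 200,
                           missing_rate = 0, cohort_shift = 0.05,
                           seed = 0) {
  stopifnot(n_classes >= 2, n_cpgs >= 1, n_informative_per_class >= 0,
            n_labeled >= 0, n_unlabeled >= 0, n_test >= 0,
            missing_rate >= 0, missing_rate < 1, cohort_shift >= 0,
            all(background_shape > 0), all(hyper_shape > 0),
            all(hypo_shape > 0))
  if (n_classes * n_informative_per_class > n_cpgs) {
    stop("informative blocks exceed n_cpgs: need at least ",
         n_classes * n_informative_per_class, " CpGs", call. = FALSE)
  }
  if (is.null(class_proportions)) {
    class_proportions <- rep(1 / n_classes, n_classes)
  }
  stopifnot(length(class_proportions) == n_classes,
            all(class_proportions > 0))
  structure(list(n_classes = as.integer(n_classes),
                 n_cpgs = as.integer(n_cpgs),
                 n_informative_per_class = as.integer(n_informative_per_class),
                 background_shape = background_shape,
                 hyper_shape = hyper_shape, hypo_shape = hypo_shape,
                 class_proportions = class_proportions /
                   sum(class_proportions),
                 n_labeled = as.integer(n_labeled),
                 n_unlabeled = as.integer(n_unlabeled),
                 n_test = as.integer(n_test),
                 missing_rate = missing_rate,
                 cohort_shift = cohort_shift,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# one cohort: samples x classes drawn from proportions, probes x samples betas
simulate_cohort <- function(spec, n, prefix) {
  classes <- sample.int(spec$n_classes, n, replace = TRUE,
                        prob = spec$class_proportions)
  vals <- matrix(stats::rbeta(spec$n_cpgs * n, spec$background_shape[1],
                              spec$background_shape[2]),
                 nrow = spec$n_cpgs, ncol = n)
  blk <- spec$n_informative_per_class
  if (blk > 0) {
    for (c in seq_len(spec$n_classes)) {
      rows <- ((c - 1) * blk + 1):(c * blk)
      members <- which(classes == c)
      if (length(members) == 0) next
      shp <- if (c %% 2 == 1) spec$hyper_shape else spec$hypo_shape
      vals[rows, members] <- stats::rbeta(blk * length(members),
                                          shp[1], shp[2])
    }
  }
  list(matrix = beta_matrix(vals,
                            cpg_ids = sprintf("cg%05d", seq_len(spec$n_cpgs)),
                            sample_ids = sprintf("%s%04d", prefix,
                                                 seq_len(n))),
       classes = classes)
}

#' Generate labelled, unlabelled and test cohorts
#'
#' Draws the three cohorts from the class-conditional model of
#' [synthetic_spec()], injects missingness, applies the cohort shift to the
#' unlabelled matrix, and returns the unlabelled cohort's ground-truth
#' subtypes as a separate vector — never inside the `unlabeled_dataset`
#' itself, so benchmarks cannot leak labels by construction.
#'
#' @param spec A [synthetic_spec()].
#' @return List: `labeled` (`labeled_dataset`), `unlabeled`
#'   (`unlabeled_dataset`), `test` (`labeled_dataset`),
#'   `unlabeled_truth` (character subtype names for the unlabelled
#'   samples), `vocabulary`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  vocabulary <- sprintf("subtype%d", seq_len(spec$n_classes))
  with_seed(spec$seed, {
    lab <- simulate_cohort(spec, spec$n_labeled, "train")
    unl <- simulate_cohort(spec, spec$n_unlabeled, "unlab")
    tst <- simulate_cohort(spec, spec$n_test, "test")

    if (spec$cohort_shift > 0 && spec$n_unlabeled > 0) {
      shifted <- unclass(unl$matrix) + spec$cohort_shift
      shifted[shifted > 1] <- 1
      shifted[shifted < 0] <- 0
      unl$matrix <- beta_matrix(shifted)
    }
    if (spec$missing_rate > 0) {
      lab$matrix <- inject_missing(lab$matrix, spec$missing_rate)
      unl$matrix <- inject_missing(unl$matrix, spec$missing_rate)
      tst$matrix <- inject_missing(tst$matrix, spec$missing_rate)
    }

    as_labeled <- function(cohort) {
      labeled_dataset(cohort$matrix,
                      stats::setNames(vocabulary[cohort$classes],
                                      sample_ids(cohort$matrix)),
                      vocabulary = vocabulary)
    }
    list(labeled = as_labeled(lab),
         unlabeled = unlabeled_dataset(unl$matrix),
         test = as_labeled(tst),
         unlabeled_truth = vocabulary[unl$classes],
         vocabulary = vocabulary)
  })
}

#' Replace entries with missing values completely at random
#'
#' Each entry is independently set to `NA` with probability `rate`. When
#' `seed` is given the pattern is reproducible; otherwise the surrounding
#' RNG stream is used (as inside [generate_synthetic()]).
#'
#' @param x A [beta_matrix()].
#' @param rate Missingness probability in \[0, 1).
#' @param seed Optional integer seed.
#' @return A [beta_matrix()] with injected `NA`s.
#' @export
inject_missing <- function(x, rate, seed = NULL) {
  stopifnot(inherits(x, "beta_matrix"), rate >= 0, rate < 1)
  if (rate == 0) return(x)
  run <- function() {
    vals <- unclass(x)
    vals[stats::runif(length(vals)) < rate] <- NA_real_
    beta_matrix(vals)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Write synthetic cohorts in the package's exchange formats
#'
#' Beta matrices as TSV, labels and the unlabelled ground truth as
#' two-column TSVs, so command-line runs can consume the simulation exactly
#' like real cohorts.
#'
#' @param sim Result of [generate_synthetic()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(labeled = file.path(dir, "labeled.tsv"),
             labels = file.path(dir, "labels.tsv"),
             unlabeled = file.path(dir, "unlabeled.tsv"),
             unlabeled_truth = file.path(dir, "unlabeled_truth.tsv"),
             test = file.path(dir, "test.tsv"),
             test_labels = file.path(dir, "test_labels.tsv"))
  write_beta_matrix(sim$labeled$matrix, paths[["labeled"]])
  write_labels(labels_tbl(sim$labeled), paths[["labels"]])
  write_beta_matrix(sim$unlabeled$matrix, paths[["unlabeled"]])
  write_labels(tibble::tibble(sample_id = sample_ids(sim$unlabeled$matrix),
                              subtype = sim$unlabeled_truth),
               paths[["unlabeled_truth"]])
  write_beta_matrix(sim$test$matrix, paths[["test"]])
  write_labels(labels_tbl(sim$test), paths[["test_labels"]])
  invisible(paths)
}
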