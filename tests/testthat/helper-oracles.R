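# Independent oracle implementations used to cross-check the package.
# These deliberately take the naive route (explicit loops, textbook
# formulas) and never call the code paths they verify.

# -- metrics ------------------------------------------------------------

# one-hot indicator matrix, n x C
oracle_onehot <- function(y, C) {
  M <- matrix(0, length(y), C)
  for (i in seq_along(y)) M[i, y[i]] <- 1
  M
}

# loop-based per-class precision/recall/F1 with the zero-division -> 0
# convention, macro means over all C classes, support-weighted F1
oracle_metrics <- function(y_true, y_pred, C) {
  n <- length(y_true)
  prec <- rec <- f1 <- sup <- numeric(C)
  for (c in seq_len(C)) {
    tp <- sum(y_true == c & y_pred == c)
    fp <- sum(y_true != c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    prec[c] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c] <- if (prec[c] + rec[c] > 0)
      2 * prec[c] * rec[c] / (prec[c] + rec[c]) else 0
    sup[c] <- sum(y_true == c)
  }
  # multiclass MCC as the correlation between one-hot encodings
  Yt <- oracle_onehot(y_true, C)
  Yp <- oracle_onehot(y_pred, C)
  covs <- function(A, B) sum(sapply(seq_len(C), function(k) {
    stats::cov(A[, k], B[, k]) * (n - 1)
  }))
  den <- sqrt(covs(Yt, Yt)) * sqrt(covs(Yp, Yp))
  mcc <- if (den > 0) covs(Yt, Yp) / den else 0
  p_o <- mean(y_true == y_pred)
  p_e <- sum(sapply(seq_len(C), function(c) {
    mean(y_true == c) * mean(y_pred == c)
  }))
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 0
  list(accuracy = p_o, precision_macro = mean(prec),
       recall_macro = mean(rec), f1_weighted = sum(sup * f1) / n,
       mcc = mcc, kappa = kappa)
}

# -- losses -------------------------------------------------------------

# brute-force double sum over samples and classes with one-hot targets
oracle_finetune_loss <- function(Pl, y, Pu, y_pseudo, alpha, eps = 1e-12) {
  C <- ncol(Pl)
  lab <- 0
  for (j in seq_len(nrow(Pl))) {
    for (i in seq_len(C)) {
      yij <- as.numeric(y[j] == i)
      lab <- lab - yij * log(max(Pl[j, i], eps))
    }
  }
  lab <- lab / nrow(Pl)
  unl <- 0
  if (!is.null(Pu) && nrow(Pu) > 0) {
    for (j in seq_len(nrow(Pu))) {
      for (i in seq_len(C)) {
        yij <- as.numeric(y_pseudo[j] == i)
        unl <- unl - yij * log(max(Pu[j, i], eps))
      }
    }
    unl <- unl / nrow(Pu)
  }
  lab + alpha * unl
}

# -- parameter vectorisation for finite-difference gradient checks ------

flatten_params <- function(params) {
  unlist(c(params$weights, params$biases))
}

unflatten_params <- function(vec, template) {
  out <- template
  pos <- 0
  for (l in seq_along(template$weights)) {
    k <- length(template$weights[[l]])
    out$weights[[l]] <- matrix(vec[pos + seq_len(k)],
                               nrow = nrow(template$weights[[l]]))
    pos <- pos + k
  }
  for (l in seq_along(template$biases)) {
    k <- length(template$biases[[l]])
    out$biases[[l]] <- vec[pos + seq_len(k)]
    pos <- pos + k
  }
  out
}

numeric_gradient <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    up <- x; up[i] <- up[i] + eps
    dn <- x; dn[i] <- dn[i] - eps
    g[i] <- (f(up) - f(dn)) / (2 * eps)
  }
  g
}

# -- nearest-centroid reference classifier ------------------------------

# trains per-class feature means on (X, y), predicts by closest centroid;
# the separability oracle for synthetic benchmarks
nearest_centroid_accuracy <- function(X_train, y_train, X_test, y_test) {
  classes <- sort(unique(y_train))
  centroids <- t(sapply(classes, function(c) {
    colMeans(X_train[y_train == c, , drop = FALSE])
  }))
  pred <- apply(X_test, 1, function(x) {
    classes[which.min(rowSums((centroids - rep(x, each = nrow(centroids)))^2))]
  })
  mean(pred == y_test)
}

# -- small fixture builders ---------------------------------------------

toy_beta_matrix <- function(n_probes = 4, n_samples = 3, seed = 1,
                            missing = integer(0)) {
  set.seed(seed)
  vals <- matrix(round(runif(n_probes * n_samples), 4), n_probes,
                 dimnames = list(sprintf("cg%02d", seq_len(n_probes)),
                                 sprintf("s%02d", seq_len(n_samples))))
  vals[missing] <- NA_real_
  beta_matrix(vals)
}

write_tsv_text <- function(lines, path) {
  writeLines(lines, path)
  path
}

small_benchmark <- function(seed = 1, n_classes = 2) {
  generate_synthetic(synthetic_spec(
    n_classes = n_classes, n_cpgs = 80, n_informative_per_class = 15,
    n_labeled = 30, n_unlabeled = 40, n_test = 30, cohort_shift = 0,
    seed = seed))
}

fast_config <- function(...) {
  defaults <- list(lr_pretrain = 1e-3, epochs_pretrain = 40,
                   lr_finetune = 1e-3, epochs_finetune = 40,
                   hidden_sizes = c(8, 4),
                   ramp = ramp_schedule(5, 15, 0.05))
  do.call(training_config, utils::modifyList(defaults, list(...)))
}
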