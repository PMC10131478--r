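#' Training configuration
#'
#' Bundles every tunable of the two-phase optimisation. The defaults are the
#' reference settings: Adam with learning rate 1e-5 for 1500 pre-training
#' epochs and 1e-3 for 3000 fine-tuning epochs, dropout 0.7 on hidden
#' activations, L2 penalty on weights, ramp `t1 = 100`, `t2 = 200`,
#' `alpha_f = 0.05`, confidence threshold disabled, full-batch updates.
#'
#' @param lr_pretrain,lr_finetune Adam learning rates (> 0).
#' @param epochs_pretrain,epochs_finetune Epoch budgets (>= 0); no early
#'   stopping.
#' @param dropout_rate Hidden-unit dropout probability in \[0, 1).
#' @param l2_coefficient L2 weight-penalty strength (the stated
#'   regulariser; its magnitude is a package default, 1e-4).
#' @param ramp A [ramp_schedule()].
#' @param confidence_threshold Posterior cutoff for pseudo-label inclusion,
#'   or `NULL` (disabled, the default).
#' @param batch_size Samples per update, or `NULL` for full-batch (the
#'   default; one update per epoch, so "epoch" and "weight update"
#'   coincide). With mini-batches, pseudo-labels are recomputed before
#'   every batch step and the ramp still advances per epoch.
#' @param hidden_sizes Hidden-layer widths for [init_params()].
#' @param oversample Optional named integer vector (subtype name ->
#'   replication factor) duplicating labelled samples of small classes
#'   before training; a crude stand-in for generative augmentation of rare
#'   subtypes.
#' @param seed Integer master seed; initialisation uses `seed`,
#'   pre-training `seed + 1`, fine-tuning `seed + 2`.
#' @return An object of class `training_config`.
#' @export
training_config <- function(lr_pretrain = 1e-5, epochs_pretrain = 1500,
                            lr_finetune = 1e-3, epochs_finetune = 3000,
                            dropout_rate = 0.7, l2_coefficient = 1e-4,
                            ramp = ramp_schedule(),
                            confidence_threshold = NULL,
                            batch_size = NULL,
                            hidden_sizes = c(1000, 500),
                            oversample = NULL,
                            seed = 0) {
  stopifnot(lr_pretrain > 0, lr_finetune > 0,
            epochs_pretrain >= 0, epochs_finetune >= 0,
            dropout_rate >= 0, dropout_rate < 1, l2_coefficient >= 0,
            inherits(ramp, "ramp_schedule"),
            is.null(batch_size) || batch_size >= 1)
  structure(list(lr_pretrain = lr_pretrain,
                 epochs_pretrain = as.integer(epochs_pretrain),
                 lr_finetune = lr_finetune,
                 epochs_finetune = as.integer(epochs_finetune),
                 dropout_rate = dropout_rate,
                 l2_coefficient = l2_coefficient,
                 ramp = ramp,
                 confidence_threshold = confidence_threshold,
                 batch_size = if (is.null(batch_size)) NULL
                              else as.integer(batch_size),
                 hidden_sizes = as.integer(hidden_sizes),
                 oversample = oversample,
                 seed = as.integer(seed)),
            class = "training_config")
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(x) lapply(x, function(p) p * 0)
  list(mw = zero_like(params$weights), vw = zero_like(params$weights),
       mb = zero_like(params$biases), vb = zero_like(params$biases),
       t = 0L)
}

# one Adam update; conventional beta1/beta2/eps defaults
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  for (l in seq_along(params$weights)) {
    r <- upd(params$weights[[l]], grads$weights[[l]],
             state$mw[[l]], state$vw[[l]])
    params$weights[[l]] <- r$p; state$mw[[l]] <- r$m; state$vw[[l]] <- r$v
    r <- upd(params$biases[[l]], grads$biases[[l]],
             state$mb[[l]], state$vb[[l]])
    params$biases[[l]] <- r$p; state$mb[[l]] <- r$m; state$vb[[l]] <- r$v
  }
  list(params = params, state = state)
}

# ---- shared helpers --------------------------------------------------------

design_matrix <- function(x) {
  m <- if (inherits(x, "beta_matrix")) x else x$matrix
  if (anyNA(m)) {
    stop("matrix contains missing values; run preprocessing first",
         call. = FALSE)
  }
  t(unclass(m))  # samples x features
}

onehot <- function(labels, n_classes) {
  Y <- matrix(0, nrow = length(labels), ncol = n_classes)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}

batch_index_sets <- function(n, batch_size) {
  if (is.null(batch_size) || batch_size >= n) return(list(seq_len(n)))
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

history_tibble <- function(epoch, phase, labeled_loss, unlabeled_loss,
                           alpha, n_pseudo_included) {
  tibble::tibble(epoch = as.integer(epoch), phase = phase,
                 labeled_loss = labeled_loss,
                 unlabeled_loss = unlabeled_loss,
                 alpha = alpha,
                 n_pseudo_included = as.integer(n_pseudo_included))
}

empty_history <- function() {
  history_tibble(integer(0), character(0), numeric(0), numeric(0),
                 numeric(0), integer(0))
}

check_features <- function(params, X) {
  if (ncol(X) != params$n_features) {
    stop(sprintf("feature mismatch: model expects %d features, data has %d",
                 params$n_features, ncol(X)), call. = FALSE)
  }
}

# ---- pre-training ----------------------------------------------------------

#' Supervised pre-training on labelled cohorts
#'
#' Runs `epochs_pretrain` epochs of Adam on the labelled cross-entropy plus
#' the L2 penalty, with dropout active on hidden activations. Full-batch by
#' default, so each epoch is exactly one weight update. Deterministic given
#' `config$seed`. A vocabulary class with no labelled samples is recorded as
#' a warning in the history attributes (training proceeds).
#'
#' @param params A `model_params` object (see [init_params()]).
#' @param labeled A `labeled_dataset` with a fully imputed matrix.
#' @param config A [training_config()].
#' @return List with `params` (updated) and `history` (tibble, one row per
#'   epoch: `epoch`, `phase`, `labeled_loss`, `unlabeled_loss`, `alpha`,
#'   `n_pseudo_included`; `alpha` is 0 throughout pre-training).
#' @export
pretrain <- function(params, labeled, config = training_config()) {
  X <- design_matrix(labeled)
  check_features(params, X)
  y <- unname(labeled$labels)
  warn <- character(0)
  absent <- setdiff(seq_along(labeled$vocabulary), unique(y))
  if (length(absent) > 0) {
    warn <- sprintf("no labelled samples for subtype(s): %s",
                    paste(labeled$vocabulary[absent], collapse = ", "))
    warning(warn, call. = FALSE)
  }
  E <- config$epochs_pretrain
  losses <- numeric(E)
  if (E > 0) {
    Y <- onehot(y, params$n_classes)
    batches <- batch_index_sets(nrow(X), config$batch_size)
    params <- with_seed(config$seed + 1L, {
      state <- adam_init(params)
      for (ep in seq_len(E)) {
        batch_losses <- numeric(length(batches))
        for (b in seq_along(batches)) {
          idx <- batches[[b]]
          fw <- nn_forward(params, X[idx, , drop = FALSE],
                           config$dropout_rate, training = TRUE)
          P <- softmax(fw$logits)
          batch_losses[b] <- cross_entropy(P, y[idx])
          d_logits <- (P - Y[idx, , drop = FALSE]) / length(idx)
          grads <- nn_backward(params, fw, d_logits, config$l2_coefficient)
          res <- adam_step(params, grads, state, config$lr_pretrain)
          params <- res$params; state <- res$state
        }
        losses[ep] <- mean(batch_losses)
      }
      params
    })
  }
  history <- history_tibble(seq_len(E) - 1L, rep("pretrain", E), losses,
                            rep(0, E), rep(0, E), rep(0L, E))
  attr(history, "warnings") <- warn
  list(params = params, history = history)
}

# ---- fine-tuning -----------------------------------------------------------

#' Pseudo-label fine-tuning on labelled plus unlabelled cohorts
#'
#' For each fine-tuning epoch `t` (counted from 0): pseudo-labels for the
#' unlabelled samples are recomputed from the current parameters in
#' inference mode, the ramp weight `alpha(t)` is evaluated, and an Adam step
#' is taken on the weighted loss ([finetune_loss()]) plus the L2 penalty.
#' Pseudo-labels are therefore fresh at every weight update; with
#' mini-batches they are recomputed before every batch step. The unlabelled
#' forward/backward pass is skipped whenever its weight is zero or no sample
#' passes the confidence mask, so an `alpha_f = 0` schedule reproduces
#' supervised training exactly. Optimiser state is fresh (not carried over
#' from pre-training).
#'
#' @param params A `model_params` object (typically pre-trained).
#' @param labeled A `labeled_dataset` (fully imputed).
#' @param unlabeled An `unlabeled_dataset`, or `NULL` for none; probe order
#'   must match the labelled matrix.
#' @param config A [training_config()].
#' @param pseudo_log If `TRUE`, attach the per-epoch pseudo-label vectors as
#'   `attr(history, "pseudo_log")` (diagnostics; memory grows with epochs).
#' @return List with `params` and `history` (see [pretrain()]); fine-tuning
#'   rows carry the realised `alpha` and `n_pseudo_included` per epoch.
#' @export
finetune <- function(params, labeled, unlabeled = NULL,
                     config = training_config(), pseudo_log = FALSE) {
  X <- design_matrix(labeled)
  check_features(params, X)
  y <- unname(labeled$labels)
  Y <- onehot(y, params$n_classes)
  Xu <- NULL
  if (!is.null(unlabeled)) {
    Xu <- design_matrix(unlabeled)
    check_features(params, Xu)
  }
  m <- if (is.null(Xu)) 0L else nrow(Xu)
  E <- config$epochs_finetune
  lab_loss <- unl_loss <- alphas <- numeric(E)
  n_inc <- integer(E)
  plog <- if (pseudo_log) vector("list", E) else NULL
  batches <- batch_index_sets(nrow(X), config$batch_size)

  params <- with_seed(config$seed + 2L, {
    state <- adam_init(params)
    for (ep in seq_len(E)) {
      t <- ep - 1L
      a <- alpha_schedule(t, config$ramp)
      pseudo <- NULL
      if (m > 0) {
        pseudo <- assign_pseudo_labels(params, Xu,
                                       config$confidence_threshold, epoch = t)
        n_inc[ep] <- sum(pseudo$mask)
        if (pseudo_log) plog[[ep]] <- pseudo$labels
      }
      batch_lab <- numeric(length(batches))
      batch_unl <- 0
      for (b in seq_along(batches)) {
        if (b > 1 && m > 0) {  # fresh pseudo-labels before every update
          pseudo <- assign_pseudo_labels(params, Xu,
                                         config$confidence_threshold,
                                         epoch = t)
        }
        idx <- batches[[b]]
        fw <- nn_forward(params, X[idx, , drop = FALSE],
                         config$dropout_rate, training = TRUE)
        P <- softmax(fw$logits)
        batch_lab[b] <- cross_entropy(P, y[idx])
        d_logits <- (P - Y[idx, , drop = FALSE]) / length(idx)
        grads <- nn_backward(params, fw, d_logits, config$l2_coefficient)
        if (m > 0 && a > 0 && any(pseudo$mask)) {
          keep <- which(pseudo$mask)
          fwu <- nn_forward(params, Xu[keep, , drop = FALSE],
                            config$dropout_rate, training = TRUE)
          Pu <- softmax(fwu$logits)
          ce_u <- cross_entropy(Pu, pseudo$labels[keep])
          if (b == 1) batch_unl <- ce_u
          Yu <- onehot(pseudo$labels[keep], params$n_classes)
          du <- a * (Pu - Yu) / length(keep)
          gu <- nn_backward(params, fwu, du, l2_coefficient = 0)
          for (l in seq_along(grads$weights)) {
            grads$weights[[l]] <- grads$weights[[l]] + gu$weights[[l]]
            grads$biases[[l]] <- grads$biases[[l]] + gu$biases[[l]]
          }
        }
        res <- adam_step(params, grads, state, config$lr_finetune)
        params <- res$params; state <- res$state
      }
      lab_loss[ep] <- mean(batch_lab)
      unl_loss[ep] <- batch_unl
      alphas[ep] <- a
    }
    params
  })
  history <- history_tibble(seq_len(E) - 1L, rep("finetune", E),
                            lab_loss, unl_loss, alphas, n_inc)
  if (pseudo_log) attr(history, "pseudo_log") <- plog
  list(params = params, history = history)
}

# ---- full pipeline ---------------------------------------------------------

#' Fit the semi-supervised subtype classifier
#'
#' The complete pipeline: initialise parameters, pre-train on the labelled
#' cohort, then fine-tune on labelled plus pseudo-labelled unlabelled
#' samples under the ramped weighting. Returns a model bundle carrying the
#' fitted parameters together with the ordered CpG feature list and the
#' subtype vocabulary, so later predictions can validate and align new
#' matrices and report named subtypes.
#'
#' @param labeled A `labeled_dataset` (fully imputed; see
#'   [preprocess_cohorts()]).
#' @param unlabeled An `unlabeled_dataset` on the same probe set, or `NULL`.
#' @param config A [training_config()].
#' @return An object of class `methsemi_fit`: `params`, `cpg_ids`,
#'   `vocabulary`, `config`, `history` (pre-training and fine-tuning rows
#'   combined).
#' @export
#'
#' @examples
#' sim <- generate_synthetic(synthetic_spec(n_cpgs = 60,
#'                                          n_informative_per_class = 10,
#'                                          n_labeled = 30,
#'                                          n_unlabeled = 20, n_test = 10))
#' cfg <- training_config(epochs_pretrain = 5, epochs_finetune = 5,
#'                        hidden_sizes = c(8, 4), lr_pretrain = 1e-3)
#' fit <- methsemi_fit(sim$labeled, sim$unlabeled, cfg)
#' predict(fit, sim$test$matrix)
methsemi_fit <- function(labeled, unlabeled = NULL,
                         config = training_config()) {
  stopifnot(inherits(labeled, "labeled_dataset"))
  if (!is.null(unlabeled)) {
    stopifnot(inherits(unlabeled, "unlabeled_dataset"))
    if (!identical(rownames(labeled$matrix), rownames(unlabeled$matrix))) {
      stop("labelled and unlabelled cohorts must share an identical ",
           "ordered probe list (run preprocess_cohorts first)",
           call. = FALSE)
    }
  }
  if (!is.null(config$oversample)) {
    labeled <- oversample_classes(labeled, config$oversample)
  }
  params <- init_params(n_features = nrow(labeled$matrix),
                        hidden_sizes = config$hidden_sizes,
                        n_classes = length(labeled$vocabulary),
                        seed = config$seed)
  pre <- pretrain(params, labeled, config)
  fin <- finetune(pre$params, labeled, unlabeled, config)
  history <- dplyr::bind_rows(pre$history, fin$history)
  attr(history, "warnings") <- attr(pre$history, "warnings")
  structure(list(params = fin$params,
                 cpg_ids = rownames(labeled$matrix),
                 vocabulary = labeled$vocabulary,
                 config = config,
                 history = history),
            class = "methsemi_fit")
}

#' Duplicate labelled samples of small subtypes
#'
#' @param labeled A `labeled_dataset`.
#' @param factors Named integer vector, subtype name -> replication factor
#'   (1 = unchanged). Replicated samples get suffixed ids.
#' @return A `labeled_dataset` with replicated columns.
#' @export
oversample_classes <- function(labeled, factors) {
  stopifnot(inherits(labeled, "labeled_dataset"),
            !is.null(names(factors)),
            all(names(factors) %in% labeled$vocabulary), all(factors >= 1))
  idx <- seq_along(labeled$labels)
  extra <- unlist(lapply(names(factors), function(cl) {
    members <- idx[labeled$vocabulary[labeled$labels] == cl]
    rep(members, times = factors[[cl]] - 1)
  }))
  if (length(extra) == 0) return(labeled)
  all_idx <- c(idx, extra)
  vals <- unclass(labeled$matrix)[, all_idx, drop = FALSE]
  ids <- make.unique(colnames(labeled$matrix)[all_idx], sep = "_rep")
  colnames(vals) <- ids
  labs <- stats::setNames(labeled$vocabulary[labeled$labels[all_idx]], ids)
  labeled_dataset(beta_matrix(vals), labs, vocabulary = labeled$vocabulary)
}

#' @export
print.methsemi_fit <- function(x, ...) {
  cat(sprintf(
    "<methsemi_fit> %d CpG features -> %s -> %d subtypes (%s)\n",
    length(x$cpg_ids), paste(x$config$hidden_sizes, collapse = " -> "),
    length(x$vocabulary), paste(x$vocabulary, collapse = ", ")))
  ph <- table(x$history$phase)
  cat("  epochs:", paste(sprintf("%s=%d", names(ph), ph), collapse = ", "),
      "\n")
  invisible(x)
}

#' Predict subtypes for new samples
#'
#' Aligns the incoming matrix to the model's CpG list (erroring on absent
#' probes) and returns posterior probabilities plus the argmax subtype.
#'
#' @param object A `methsemi_fit`.
#' @param newdata A [beta_matrix()] (probes x samples) with no missing
#'   values.
#' @param ... Unused.
#' @return Tibble: `sample_id`, `predicted` (subtype name), `max_prob`, and
#'   one posterior column per subtype prefixed `p_`.
#' @export
predict.methsemi_fit <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "beta_matrix"))
  aligned <- align_to_features(newdata, object$cpg_ids)
  X <- design_matrix(aligned)
  pred <- predict_proba(object$params, X)
  post <- pred$posteriors
  colnames(post) <- paste0("p_", object$vocabulary)
  dplyr::bind_cols(
    tibble::tibble(sample_id = sample_ids(aligned),
                   predicted = object$vocabulary[pred$predicted],
                   max_prob = pred$max_prob),
    tibble::as_tibble(post))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fitted model
#'
#' @param x A `methsemi_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `phase`, `labeled_loss`,
#'   `unlabeled_loss`, `alpha`, `n_pseudo_included`.
#' @method tidy methsemi_fit
#' @export
tidy.methsemi_fit <- function(x, ...) {
  out <- x$history
  attributes(out)[c("warnings", "pseudo_log")] <- NULL
  out
}

#' One-row summary of a fitted model
#'
#' @param x A `methsemi_fit`.
#' @param ... Unused.
#' @return One-row tibble: dimensions, epoch counts, final losses.
#' @method glance methsemi_fit
#' @export
glance.methsemi_fit <- function(x, ...) {
  h <- x$history
  fin <- h[h$phase == "finetune", ]
  pre <- h[h$phase == "pretrain", ]
  tibble::tibble(
    n_features = length(x$cpg_ids),
    n_classes = length(x$vocabulary),
    epochs_pretrain = nrow(pre),
    epochs_finetune = nrow(fin),
    final_pretrain_loss = if (nrow(pre)) pre$labeled_loss[nrow(pre)] else NA_real_,
    final_labeled_loss = if (nrow(fin)) fin$labeled_loss[nrow(fin)] else NA_real_,
    final_alpha = if (nrow(fin)) fin$alpha[nrow(fin)] else NA_real_,
    n_parameters = sum(vapply(x$params$weights, length, 1L)) +
      sum(vapply(x$params$biases, length, 1L)))
}

#' Plot training curves of a fitted model
#'
#' Loss per epoch by phase, with the ramp weight on a second panel.
#'
#' @param object A `methsemi_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot methsemi_fit
#' @export
autoplot.methsemi_fit <- function(object, ...) {
  h <- tidy(object)
  h$global_epoch <- seq_len(nrow(h)) - 1L
  long <- tidyr::pivot_longer(
    h, cols = c("labeled_loss", "unlabeled_loss", "alpha"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$global_epoch, y = .data$value,
                               colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch (pre-training then fine-tuning)", y = NULL,
                  colour = "phase") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# ---- persistence -----------------------------------------------------------

#' Save a fitted model as JSON
#'
#' Writes parameters, architecture, the ordered CpG feature list and the
#' subtype vocabulary with full double precision, so save/load round-trips
#' reproduce predictions bit-exactly.
#'
#' @param fit A `methsemi_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "methsemi_fit"))
  # doubles stored as %.17g strings: 17 significant digits round-trip
  # IEEE-754 exactly, so reloaded models predict bit-identically
  payload <- list(
    format = "methsemi_model_v1",
    hidden_sizes = fit$params$hidden_sizes,
    n_features = fit$params$n_features,
    n_classes = fit$params$n_classes,
    weights = lapply(fit$params$weights, function(w) {
      list(dim = dim(w), data = sprintf("%.17g", w))
    }),
    biases = lapply(fit$params$biases, function(b) sprintf("%.17g", b)),
    cpg_ids = fit$cpg_ids,
    vocabulary = fit$vocabulary)
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Path to a model JSON file.
#' @return A `methsemi_fit` (with empty history and no config).
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (!identical(p$format, "methsemi_model_v1")) {
    stop("not a methsemi model file: ", path, call. = FALSE)
  }
  params <- structure(list(
    weights = lapply(p$weights, function(w) {
      matrix(as.numeric(w$data), nrow = w$dim[1], ncol = w$dim[2])
    }),
    biases = lapply(p$biases, as.numeric),
    hidden_sizes = as.integer(p$hidden_sizes),
    n_features = as.integer(p$n_features),
    n_classes = as.integer(p$n_classes)), class = "model_params")
  structure(list(params = params,
                 cpg_ids = as.character(p$cpg_ids),
                 vocabulary = as.character(p$vocabulary),
                 config = NULL,
                 history = empty_history()),
            class = "methsemi_fit")
}
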