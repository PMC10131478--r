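#' Ramp schedule for the unlabelled-loss weight
#'
#' The coefficient multiplying the pseudo-labelled cross-entropy term rises
#' from 0 to `alpha_f` between fine-tuning epochs `t1` and `t2`, so early
#' optimisation is driven by the labelled data alone and unreliable early
#' pseudo-labels cannot pull the model into poor local minima.
#'
#' @param t1 Epoch at which the ramp starts (default 100).
#' @param t2 Epoch at which the ramp reaches `alpha_f` (default 200).
#' @param alpha_f Final unlabelled-loss weight (default 0.05).
#' @return An object of class `ramp_schedule`.
#' @export
ramp_schedule <- function(t1 = 100, t2 = 200, alpha_f = 0.05) {
  stopifnot(t1 >= 0, t1 < t2, alpha_f >= 0)
  structure(list(t1 = t1, t2 = t2, alpha_f = alpha_f),
            class = "ramp_schedule")
}

#' Unlabelled-loss weight at a fine-tuning epoch
#'
#' Piecewise-linear: 0 for `t < t1`, `alpha_f * (t - t1) / (t2 - t1)` for
#' `t1 <= t < t2`, `alpha_f` for `t >= t2`. Continuous and non-decreasing.
#' The epoch counter starts at 0 at the beginning of fine-tuning.
#'
#' @param t Epoch (scalar or vector, >= 0).
#' @param schedule A [ramp_schedule()].
#' @return Numeric weight(s).
#' @export
alpha_schedule <- function(t, schedule = ramp_schedule()) {
  stopifnot(all(t >= 0))
  ifelse(t < schedule$t1, 0,
         ifelse(t < schedule$t2,
                (t - schedule$t1) / (schedule$t2 - schedule$t1) *
                  schedule$alpha_f,
                schedule$alpha_f))
}

# posterior floor inside log() so saturated predictions cannot produce -Inf
CE_EPS <- 1e-12

#' Mean cross-entropy of posteriors against hard labels
#'
#' Mean over samples of `-log` posterior of the true class (the double sum
#' over samples and classes with one-hot targets collapses to this). The log
#' argument is floored at 1e-12.
#'
#' @param posteriors Numeric matrix, samples x classes, rows summing to 1.
#' @param labels Integer class indices (1-based), one per row.
#' @return Scalar loss (>= 0; 0 iff every true-class posterior is 1).
#' @export
cross_entropy <- function(posteriors, labels) {
  if (is.vector(posteriors)) posteriors <- matrix(posteriors, nrow = 1)
  stopifnot(nrow(posteriors) >= 1, length(labels) == nrow(posteriors))
  if (any(labels < 1 | labels > ncol(posteriors))) {
    stop("label index outside 1..C", call. = FALSE)
  }
  p <- posteriors[cbind(seq_len(nrow(posteriors)), labels)]
  -mean(log(pmax(p, CE_EPS)))
}

#' Weighted fine-tuning loss over labelled and pseudo-labelled samples
#'
#' The labelled cross-entropy plus `alpha` times the cross-entropy of the
#' unlabelled posteriors against their pseudo-labels. With confidence
#' thresholding, the unlabelled term is the mean over the mask-included
#' samples only; with no samples included (or no unlabelled data) the term
#' is 0 and the total reduces to the labelled pre-training loss.
#'
#' @param labeled_posteriors Samples x classes posterior matrix (labelled).
#' @param labels Integer class indices for the labelled samples.
#' @param unlabeled_posteriors Samples x classes posterior matrix
#'   (unlabelled), or `NULL`.
#' @param pseudo A [pseudo_labels()] object for the unlabelled samples, or
#'   `NULL`.
#' @param alpha Non-negative unlabelled-loss weight (see
#'   [alpha_schedule()]).
#' @return List: `total`, `labeled_term`, `unlabeled_term` (unweighted).
#' @export
finetune_loss <- function(labeled_posteriors, labels,
                          unlabeled_posteriors = NULL, pseudo = NULL,
                          alpha = 0) {
  stopifnot(alpha >= 0)
  labeled_term <- cross_entropy(labeled_posteriors, labels)
  unlabeled_term <- 0
  if (!is.null(unlabeled_posteriors) && !is.null(pseudo) &&
      nrow(unlabeled_posteriors) > 0 && any(pseudo$mask)) {
    keep <- pseudo$mask
    unlabeled_term <- cross_entropy(
      unlabeled_posteriors[keep, , drop = FALSE], pseudo$labels[keep])
  }
  list(total = labeled_term + alpha * unlabeled_term,
       labeled_term = labeled_term,
       unlabeled_term = unlabeled_term)
}

#' Pseudo-label container
#'
#' @param labels Integer class indices (1-based), one per unlabelled sample.
#' @param mask Logical inclusion flags (same length); masked-out samples are
#'   excluded from the unlabelled loss term.
#' @param source_epoch Fine-tuning epoch at which the labels were computed.
#' @return An object of class `pseudo_labels`.
#' @export
pseudo_labels <- function(labels, mask = rep(TRUE, length(labels)),
                          source_epoch = NA_integer_) {
  stopifnot(length(labels) == length(mask), is.logical(mask))
  structure(list(labels = as.integer(labels), mask = mask,
                 source_epoch = source_epoch),
            class = "pseudo_labels")
}

#' Assign pseudo-subtypes to an unlabelled cohort
#'
#' Each unlabelled sample receives the subtype with the highest posterior
#' probability under the current parameters, computed in inference mode so
#' the targets are deterministic. With a confidence threshold `tau`, only
#' samples whose top posterior strictly exceeds `tau` are flagged for
#' inclusion in the unlabelled loss; the flags are recomputed at every
#' update, so samples excluded early re-enter once the model grows
#' confident about them.
#'
#' @param params A `model_params` object.
#' @param X Numeric matrix (samples x features) or an `unlabeled_dataset`
#'   whose probes match the model feature order.
#' @param confidence_threshold Numeric in \[0, 1\] or `NULL` (disabled;
#'   the default, matching the reference experiments).
#' @param epoch Epoch tag recorded in the result.
#' @return A [pseudo_labels()] object.
#' @export
assign_pseudo_labels <- function(params, X, confidence_threshold = NULL,
                                 epoch = NA_integer_) {
  if (inherits(X, "unlabeled_dataset")) X <- t(unclass(X$matrix))
  pred <- predict_proba(params, X)
  mask <- if (is.null(confidence_threshold)) rep(TRUE, length(pred$predicted))
          else pred$max_prob > confidence_threshold
  pseudo_labels(pred$predicted, mask, source_epoch = epoch)
}
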