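#' Confusion matrix over a fixed class vocabulary
#'
#' Entry (i, j) counts samples with true class i predicted as class j; rows
#' therefore sum to the per-class supports and the whole matrix to the
#' sample count. All `n_classes` vocabulary classes appear even when absent
#' from the data, so reports stay comparable across folds.
#'
#' @param y_true,y_pred Integer class indices (1-based), equal length >= 1.
#' @param n_classes Number of classes C (>= 2).
#' @return Integer C x C matrix.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  if (any(c(y_true, y_pred) < 1 | c(y_true, y_pred) > n_classes)) {
    stop("class index outside 1..C", call. = FALSE)
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (k in seq_along(y_true)) {
    cm[y_true[k], y_pred[k]] <- cm[y_true[k], y_pred[k]] + 1L
  }
  cm
}

#' Multiclass classification metrics
#'
#' The six headline statistics used to score subtype predictions, all
#' computed from the C x C confusion matrix:
#' accuracy; macro (unweighted-mean) precision and recall over all
#' vocabulary classes; F1 combined weighted by true-class support;
#' the Gorodkin multiclass generalisation of the Matthews correlation
#' coefficient (reducing to the familiar binary form at C = 2); and Cohen's
#' kappa with chance agreement from the marginals. Per-class statistics with
#' a zero denominator contribute 0, and a zero MCC/kappa denominator yields
#' 0, so degenerate (e.g. constant) predictors score deterministically.
#'
#' @param y_true,y_pred Integer class indices (1-based) or character
#'   subtype names resolved against `vocabulary`.
#' @param n_classes Number of classes; inferred from `vocabulary` when
#'   given.
#' @param vocabulary Optional character vector of subtype names (fixes C
#'   and maps names to indices).
#' @return An object of class `metrics_report`: list with the six scalars
#'   (`accuracy`, `precision_macro`, `recall_macro`, `f1_weighted`, `mcc`,
#'   `kappa`), the `confusion` matrix, and `per_class` (tibble: `class`,
#'   `support`, `precision`, `recall`, `f1`).
#' @export
#'
#' @examples
#' evaluate_predictions(c(1, 1, 2, 2), c(1, 2, 2, 2), n_classes = 2)
evaluate_predictions <- function(y_true, y_pred, n_classes = NULL,
                                 vocabulary = NULL) {
  if (!is.null(vocabulary)) {
    n_classes <- length(vocabulary)
    if (is.character(y_true)) y_true <- match(y_true, vocabulary)
    if (is.character(y_pred)) y_pred <- match(y_pred, vocabulary)
    if (anyNA(y_true) || anyNA(y_pred)) {
      stop("subtype name not in vocabulary", call. = FALSE)
    }
  }
  if (is.null(n_classes)) n_classes <- max(y_true, y_pred)
  cm <- confusion_matrix(y_true, y_pred, n_classes)
  n <- sum(cm)
  support <- rowSums(cm)     # true-class counts
  predicted <- colSums(cm)   # predicted-class counts
  tp <- diag(cm)

  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, predicted)
  recall <- safe_div(tp, support)
  f1 <- safe_div(2 * precision * recall, precision + recall)

  accuracy <- sum(tp) / n
  # Gorodkin / Rk form of the multiclass MCC
  mcc_num <- sum(tp) * n - sum(support * predicted)
  mcc_den <- sqrt(n^2 - sum(predicted^2)) * sqrt(n^2 - sum(support^2))
  mcc <- if (mcc_den > 0) mcc_num / mcc_den else 0
  p_e <- sum(support * predicted) / n^2
  kappa <- if (1 - p_e > 0) (accuracy - p_e) / (1 - p_e) else 0

  cls <- if (!is.null(vocabulary)) vocabulary else
    as.character(seq_len(n_classes))
  structure(list(
    accuracy = accuracy,
    precision_macro = mean(precision),
    recall_macro = mean(recall),
    f1_weighted = sum(support * f1) / n,
    mcc = mcc,
    kappa = kappa,
    confusion = cm,
    per_class = tibble::tibble(class = cls, support = as.integer(support),
                               precision = precision, recall = recall,
                               f1 = f1)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(glance(x))
  invisible(x)
}

#' Per-class metric table
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Tibble: `class`, `support`, `precision`, `recall`, `f1`.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' One-row summary of a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return One-row tibble with the six headline statistics.
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 precision_macro = x$precision_macro,
                 recall_macro = x$recall_macro,
                 f1_weighted = x$f1_weighted,
                 mcc = x$mcc,
                 kappa = x$kappa)
}

#' Plot a metrics report
#'
#' Confusion-matrix heatmap with per-cell counts.
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  cm <- object$confusion
  cls <- object$per_class$class
  df <- tidyr::expand_grid(true = cls, predicted = cls)
  df$count <- as.vector(t(cm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev(cls)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted subtype", y = "true subtype") +
    ggplot2::theme_minimal()
}

#' Write a metrics report to disk
#'
#' Headline statistics as a flat key-value TSV; the per-class table beside
#' it when `per_class_path` is given.
#'
#' @param x A `metrics_report`.
#' @param path Output TSV path for the headline metrics.
#' @param per_class_path Optional output TSV path for the per-class table.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(x, path, per_class_path = NULL) {
  g <- glance(x)
  readr::write_tsv(tibble::tibble(metric = names(g),
                                  value = as.numeric(g[1, ])), path)
  if (!is.null(per_class_path)) readr::write_tsv(tidy(x), per_class_path)
  invisible(path)
}
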