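#' Beta-value matrix container
#'
#' A `beta_matrix` is a numeric matrix of DNA methylation beta values in the
#' canonical probes-by-samples layout used by public array exports
#' (series-matrix convention): one row per CpG probe, one column per sample,
#' every non-missing entry in \[0, 1\], missing entries stored as `NA`.
#'
#' @param values Numeric matrix (probes in rows, samples in columns).
#' @param cpg_ids Character vector of unique probe identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to `colnames(values)`.
#'
#' @return An object of class `beta_matrix` (a numeric matrix with dimnames).
#' @export
#'
#' @examples
#' m <- matrix(c(0.1, 0.9, NA, 0.5), nrow = 2,
#'             dimnames = list(c("cg01", "cg02"), c("s1", "s2")))
#' beta_matrix(m)
beta_matrix <- function(values, cpg_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(cpg_ids) || is.null(sample_ids)) {
    stop("`values` must carry probe and sample identifiers ",
         "(rownames/colnames or explicit `cpg_ids`/`sample_ids`).",
         call. = FALSE)
  }
  cpg_ids <- as.character(cpg_ids)
  sample_ids <- as.character(sample_ids)
  if (length(cpg_ids) != nrow(values)) {
    stop("length(cpg_ids) != nrow(values)", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length(sample_ids) != ncol(values)", call. = FALSE)
  }
  check_unique_ids(cpg_ids, "probe")
  check_unique_ids(sample_ids, "sample")
  storage.mode(values) <- "double"
  check_beta_range(values, cpg_ids, sample_ids)
  dimnames(values) <- list(cpg_ids, sample_ids)
  class(values) <- c("beta_matrix", class(matrix()))
  values
}

check_unique_ids <- function(ids, axis) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s id(s): %s", axis,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}

check_beta_range <- function(values, cpg_ids, sample_ids) {
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "beta value out of [0, 1]: probe '%s', sample '%s', value %g (%d offending entr%s)",
      cpg_ids[i], sample_ids[j], values[i, j], nrow(bad),
      if (nrow(bad) == 1) "y" else "ies"), call. = FALSE)
  }
  invisible(values)
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d probes x %d samples, %d missing (%.1f%%)\n",
              nrow(x), ncol(x), sum(is.na(x)),
              100 * mean(is.na(x))))
  n_r <- min(5L, nrow(x)); n_c <- min(5L, ncol(x))
  if (n_r > 0 && n_c > 0) print(unclass(x)[seq_len(n_r), seq_len(n_c), drop = FALSE])
  invisible(x)
}

#' Probe and sample identifiers of a beta matrix
#'
#' @param x A [beta_matrix()].
#' @return Character vector of ids, in matrix order.
#' @export
cpg_ids <- function(x) rownames(x)

#' @rdname cpg_ids
#' @export
sample_ids <- function(x) colnames(x)

# tokens treated as missing when parsing delimited text (case-insensitive)
MISSING_TOKENS <- c("", "na", "nan", "null")

infer_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a beta-value matrix from delimited text
#'
#' Reads a TSV/CSV export (one header row, first column of ids) into the
#' canonical probes-by-samples [beta_matrix()]. Files shipped with samples in
#' rows are handled by `orientation = "samples_as_rows"`; the result is
#' identical to reading the transposed file. Empty cells and the tokens
#' `NA`/`NaN`/`null` (case-insensitive) parse as missing. The delimiter is
#' inferred from the extension (`.csv` comma, otherwise tab).
#'
#' @param path Path to a delimited text file.
#' @param orientation `"probes_as_rows"` (default, series-matrix convention)
#'   or `"samples_as_rows"`.
#'
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path,
                             orientation = c("probes_as_rows",
                                             "samples_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(
    path, delim = infer_delim(path), col_types = readr::cols(.default = "c"),
    na = character(), trim_ws = TRUE, progress = FALSE,
    show_col_types = FALSE, name_repair = "minimal")
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    stop("empty or id-only beta matrix file: ", path, call. = FALSE)
  }
  row_ids <- as.character(raw[[1]])
  col_ids <- colnames(raw)[-1]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  vals <- parse_beta_cells(cells, row_ids, col_ids, path)
  if (orientation == "samples_as_rows") {
    vals <- t(vals)
    tmp <- row_ids; row_ids <- col_ids; col_ids <- tmp
  }
  beta_matrix(vals, cpg_ids = row_ids, sample_ids = col_ids)
}

parse_beta_cells <- function(cells, row_ids, col_ids, path) {
  flat <- as.vector(cells)
  is_missing <- tolower(trimws(flat)) %in% MISSING_TOKENS | is.na(flat)
  vals <- suppressWarnings(as.numeric(flat))
  bad_parse <- which(!is_missing & is.na(vals))
  if (length(bad_parse) > 0) {
    k <- bad_parse[1]
    i <- (k - 1) %% length(row_ids) + 1
    j <- (k - 1) %/% length(row_ids) + 1
    stop(sprintf("non-numeric cell '%s' at row id '%s', column '%s' in %s",
                 flat[k], row_ids[i], col_ids[j], path), call. = FALSE)
  }
  vals[is_missing] <- NA_real_
  matrix(vals, nrow = length(row_ids),
         dimnames = list(row_ids, col_ids))
}

#' Write a beta matrix to delimited text
#'
#' Inverse of [read_beta_matrix()] with `orientation = "probes_as_rows"`:
#' header row of sample ids, first column of probe ids, missing entries
#' written as `NA`. Round-trips ids, order, values and missingness exactly.
#'
#' @param x A [beta_matrix()].
#' @param path Output path; delimiter inferred from the extension.
#' @param id_column Name for the probe-id column header.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, id_column = "cpg_id") {
  df <- tibble::as_tibble(unclass(x), rownames = id_column, .name_repair = "minimal")
  readr::write_delim(df, path, delim = infer_delim(path), na = "NA")
  invisible(path)
}

#' Read a sample-to-subtype label table
#'
#' Reads a two-column delimited file (`sample_id`, `subtype`). When no
#' vocabulary is supplied one is built from the distinct subtype names in
#' first-appearance order; that order fixes the classifier's output-unit
#' index. Against a fixed vocabulary, unknown names are an error.
#'
#' @param path Path to a two-column TSV/CSV (header row required).
#' @param vocabulary Optional character vector of allowed subtype names.
#'
#' @return A list with `labels` (tibble: `sample_id`, `subtype`) and
#'   `vocabulary` (character vector).
#' @export
read_labels <- function(path, vocabulary = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_delim(
    path, delim = infer_delim(path),
    col_types = readr::cols(.default = "c"), trim_ws = TRUE,
    progress = FALSE, show_col_types = FALSE)
  if (ncol(tbl) < 2 || nrow(tbl) == 0) {
    stop("label file must have >= 1 row and two columns (sample id, subtype): ",
         path, call. = FALSE)
  }
  tbl <- tibble::tibble(sample_id = as.character(tbl[[1]]),
                        subtype = as.character(tbl[[2]]))
  conflicts <- tbl |>
    dplyr::distinct(.data$sample_id, .data$subtype) |>
    dplyr::count(.data$sample_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    stop("conflicting subtype assignments for sample(s): ",
         paste(conflicts$sample_id, collapse = ", "), call. = FALSE)
  }
  tbl <- dplyr::distinct(tbl)
  vocabulary <- resolve_vocabulary(tbl$subtype, vocabulary)
  list(labels = tbl, vocabulary = vocabulary)
}

resolve_vocabulary <- function(names_seen, vocabulary) {
  if (is.null(vocabulary)) {
    vocabulary <- unique(names_seen)
  } else {
    unknown <- setdiff(unique(names_seen), vocabulary)
    if (length(unknown) > 0) {
      stop("subtype name(s) not in vocabulary: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  check_unique_ids(vocabulary, "subtype")
  if (length(vocabulary) < 2) {
    stop("subtype vocabulary must contain at least 2 classes, got ",
         length(vocabulary), call. = FALSE)
  }
  vocabulary
}

#' Write a label table
#'
#' @param labels Tibble with columns `sample_id` and `subtype`.
#' @param path Output path; delimiter inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  readr::write_delim(labels[, c("sample_id", "subtype")], path,
                     delim = infer_delim(path))
  invisible(path)
}

#' Restrict and reorder a beta matrix to a fixed probe list
#'
#' Prediction-time guard: a saved model carries the ordered CpG list it was
#' trained on, and incoming matrices are aligned to it exactly. Probes absent
#' from the matrix are an error (no silent drop).
#'
#' @param x A [beta_matrix()].
#' @param cpg_ids Ordered character vector of requested probe ids.
#' @return A [beta_matrix()] with rows exactly `cpg_ids`, in that order.
#' @export
align_to_features <- function(x, cpg_ids) {
  absent <- setdiff(cpg_ids, rownames(x))
  if (length(absent) > 0) {
    stop("probe id(s) absent from matrix: ",
         paste(utils::head(absent, 20), collapse = ", "),
         if (length(absent) > 20) sprintf(" ... (%d total)", length(absent)),
         call. = FALSE)
  }
  beta_matrix(unclass(x)[cpg_ids, , drop = FALSE])
}

#' Bundle a beta matrix with subtype labels
#'
#' Pairs a [beta_matrix()] with one subtype per sample against a fixed
#' vocabulary. Labels may be given as a tibble (`sample_id`, `subtype`, as
#' returned by [read_labels()]) or a character vector named by sample id;
#' every matrix sample must be labelled.
#'
#' @param matrix A [beta_matrix()].
#' @param labels Tibble (`sample_id`, `subtype`) or named character vector.
#' @param vocabulary Optional character vector fixing class order; built from
#'   the labels in first-appearance order when absent.
#'
#' @return An object of class `labeled_dataset`: list with `matrix`,
#'   `labels` (integer class index per sample, 1-based), `vocabulary`.
#' @export
labeled_dataset <- function(matrix, labels, vocabulary = NULL) {
  stopifnot(inherits(matrix, "beta_matrix"))
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels$subtype),
                              as.character(labels$sample_id))
  }
  missing_lab <- setdiff(sample_ids(matrix), names(labels))
  if (length(missing_lab) > 0) {
    stop("no subtype label for sample(s): ",
         paste(utils::head(missing_lab, 20), collapse = ", "), call. = FALSE)
  }
  labels <- labels[sample_ids(matrix)]
  vocabulary <- resolve_vocabulary(unname(labels), vocabulary)
  idx <- match(labels, vocabulary)
  structure(list(matrix = matrix,
                 labels = stats::setNames(idx, sample_ids(matrix)),
                 vocabulary = vocabulary),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d probes, %d subtypes: %s\n",
              ncol(x$matrix), nrow(x$matrix), length(x$vocabulary),
              paste(x$vocabulary, collapse = ", ")))
  print(table(subtype = x$vocabulary[x$labels]))
  invisible(x)
}

#' Wrap a beta matrix as an unlabelled cohort
#'
#' Carries no label information by construction; ground truth for synthetic
#' benchmarks travels outside this object.
#'
#' @param matrix A [beta_matrix()].
#' @return An object of class `unlabeled_dataset`.
#' @export
unlabeled_dataset <- function(matrix) {
  stopifnot(inherits(matrix, "beta_matrix"))
  structure(list(matrix = matrix), class = "unlabeled_dataset")
}

#' @export
print.unlabeled_dataset <- function(x, ...) {
  cat(sprintf("<unlabeled_dataset> %d samples x %d probes\n",
              ncol(x$matrix), nrow(x$matrix)))
  invisible(x)
}

#' Subtype labels of a labelled dataset as a tibble
#'
#' @param x A `labeled_dataset`.
#' @return Tibble with `sample_id` and `subtype` columns.
#' @export
labels_tbl <- function(x) {
  stopifnot(inherits(x, "labeled_dataset"))
  tibble::tibble(sample_id = sample_ids(x$matrix),
                 subtype = x$vocabulary[x$labels])
}
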