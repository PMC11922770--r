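#' Construct a training matrix of methylation rates
#'
#' Bundles a samples-by-probes matrix of methylation rates (beta values in
#' `[0, 1]`, `NA` for masked loci) with per-sample class labels and optional
#' batch labels (e.g. FFPE vs frozen material). This is the substrate every
#' reference model is trained on.
#'
#' @param values Numeric matrix, samples in rows, CpG probes in columns.
#'   Column names are taken as probe IDs when `feature_ids` is missing.
#' @param class_labels Character vector, one class per sample.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to the matrix row names or `sample_1 ... sample_n`.
#' @param batch_labels Optional character vector of batch labels (one per
#'   sample), used by [correct_batch()].
#' @param feature_ids Optional character vector of unique probe IDs
#'   (overrides column names).
#'
#' @return An object of class `meth_matrix`: a list with elements `values`
#'   (the numeric matrix), `samples` (a tibble with `sample_id`,
#'   `class_label` and, when given, `batch`) and `feature_ids`.
#' @export
#' @examples
#' m <- matrix(runif(12), 3, 4, dimnames = list(NULL, paste0("cg", 1:4)))
#' meth_matrix(m, class_labels = c("A", "A", "B"))
meth_matrix <- function(values, class_labels, sample_ids = NULL,
                        batch_labels = NULL, feature_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (samples x probes).")
  }
  n <- nrow(values)
  if (n == 0L || ncol(values) == 0L) abort("`values` must be non-empty.")
  feature_ids <- feature_ids %||% colnames(values) %||%
    paste0("cg", seq_len(ncol(values)))
  if (anyDuplicated(feature_ids)) abort("Probe IDs must be unique.")
  if (length(feature_ids) != ncol(values)) {
    abort("`feature_ids` length must match ncol(values).")
  }
  sample_ids <- sample_ids %||% rownames(values) %||%
    paste0("sample_", seq_len(n))
  if (length(sample_ids) != n || anyDuplicated(sample_ids)) {
    abort("`sample_ids` must be unique and match nrow(values).")
  }
  if (length(class_labels) != n) {
    abort("`class_labels` must supply exactly one class per sample.")
  }
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    abort("Methylation rates must lie in [0, 1] (or be NA).")
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  samples <- tibble(sample_id = as.character(sample_ids),
                    class_label = as.character(class_labels))
  if (!is.null(batch_labels)) {
    if (length(batch_labels) != n) abort("One batch label per sample required.")
    samples$batch <- as.character(batch_labels)
  }
  structure(
    list(values = values, samples = samples,
         feature_ids = as.character(feature_ids)),
    class = "meth_matrix"
  )
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat("<meth_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
      " probes, ", length(unique(x$samples$class_label)), " classes\n",
      sep = "")
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) dim(x$values)

#' Read a training matrix and its sample annotation from delimited files
#'
#' The matrix file is a delimited table with a header row of probe IDs and
#' one row per sample; the first column holds sample IDs. The annotation
#' file maps `sample_id` to `class_label` and, optionally, `batch`.
#'
#' @param matrix_file Path to the samples-by-probes table (TSV or CSV,
#'   sniffed from the extension).
#' @param annotation_file Path to the sample annotation table with columns
#'   `sample_id`, `class_label` and optionally `batch`.
#' @return A [meth_matrix()].
#' @export
read_meth_matrix <- function(matrix_file, annotation_file) {
  reader <- if (grepl("\\.csv$", matrix_file)) readr::read_csv else readr::read_tsv
  tab <- reader(matrix_file, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  ann <- readr::read_tsv(annotation_file, show_col_types = FALSE,
                         progress = FALSE)
  if (!all(c("sample_id", "class_label") %in% names(ann))) {
    abort("Annotation needs `sample_id` and `class_label` columns.")
  }
  idx <- match(ids, ann$sample_id)
  if (anyNA(idx)) {
    abort(paste0("Samples missing from annotation: ",
                 paste(head(ids[is.na(idx)], 5), collapse = ", ")))
  }
  ann <- ann[idx, ]
  meth_matrix(vals, class_labels = ann$class_label, sample_ids = ids,
              batch_labels = if ("batch" %in% names(ann)) ann$batch else NULL)
}

#' Write a training matrix to delimited files
#'
#' Inverse of [read_meth_matrix()].
#'
#' @param x A [meth_matrix()].
#' @param matrix_file,annotation_file Output paths (TSV).
#' @return `x`, invisibly.
#' @export
write_meth_matrix <- function(x, matrix_file, annotation_file) {
  stopifnot(inherits(x, "meth_matrix"))
  tab <- tibble::as_tibble(x$values)
  tab <- dplyr::bind_cols(tibble(sample_id = rownames(x$values)), tab)
  readr::write_tsv(tab, matrix_file, progress = FALSE)
  readr::write_tsv(x$samples, annotation_file, progress = FALSE)
  invisible(x)
}

# Class-conditional mean imputation of missing rates. Centroids are class
# means anyway, so this leaves centroids untouched while giving downstream
# weight computations complete rows.
impute_class_means <- function(x) {
  stopifnot(inherits(x, "meth_matrix"))
  vals <- x$values
  if (!anyNA(vals)) return(x)
  cls <- x$samples$class_label
  for (cl in unique(cls)) {
    rows <- which(cls == cl)
    sub <- vals[rows, , drop = FALSE]
    na_cols <- which(colSums(is.na(sub)) > 0L)
    if (!length(na_cols)) next
    mu <- colMeans(sub[, na_cols, drop = FALSE], na.rm = TRUE)
    # class entirely missing at a feature: fall back to the overall mean
    all_na <- is.nan(mu)
    if (any(all_na)) {
      mu[all_na] <- colMeans(vals[, na_cols[all_na], drop = FALSE],
                             na.rm = TRUE)
      inform(paste0("Imputed ", sum(all_na),
                    " all-missing class/feature cells with overall means."))
    }
    for (k in seq_along(na_cols)) {
      j <- na_cols[k]
      miss <- rows[is.na(vals[rows, j])]
      vals[miss, j] <- mu[k]
    }
  }
  x$values <- vals
  x
}
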