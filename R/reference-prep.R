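#' Define probe exclusion sets
#'
#' Array probes are removed from the reference for four standard reasons:
#' they target the sex chromosomes, they overlap a common SNP near the
#' interrogated CpG, they do not map uniquely to the reference genome, or
#' they are absent from the other array platform used in the model (so that
#' 450k and EPIC cohorts share one namespace). The sets may overlap; the
#' union is what gets removed.
#'
#' @param sex_chromosome,snp_proximal,multimapping,non_shared_platform
#'   Character vectors of probe IDs (any may be empty).
#' @return A `probe_exclusions` object (named list of character vectors).
#' @export
probe_exclusions <- function(sex_chromosome = character(),
                             snp_proximal = character(),
                             multimapping = character(),
                             non_shared_platform = character()) {
  out <- list(sex_chromosome = as.character(sex_chromosome),
              snp_proximal = as.character(snp_proximal),
              multimapping = as.character(multimapping),
              non_shared_platform = as.character(non_shared_platform))
  structure(out, class = "probe_exclusions")
}

#' Read probe exclusion lists from files
#'
#' Each file holds one probe ID per line; missing arguments give empty sets.
#'
#' @param sex_chromosome,snp_proximal,multimapping,non_shared_platform
#'   Optional file paths.
#' @return A [probe_exclusions()] object.
#' @export
read_probe_exclusions <- function(sex_chromosome = NULL, snp_proximal = NULL,
                                  multimapping = NULL,
                                  non_shared_platform = NULL) {
  rd <- function(p) if (is.null(p)) character() else readr::read_lines(p)
  probe_exclusions(rd(sex_chromosome), rd(snp_proximal), rd(multimapping),
                   rd(non_shared_platform))
}

#' Remove excluded probes from a training matrix
#'
#' Drops every probe in the union of the exclusion sets; probes named in an
#' exclusion set but absent from the matrix are ignored. Column order of the
#' surviving probes is preserved and sample rows are untouched. The
#' operation is idempotent.
#'
#' @param x A [meth_matrix()].
#' @param exclusions A [probe_exclusions()] object.
#' @return A filtered [meth_matrix()].
#' @export
filter_probes <- function(x, exclusions) {
  stopifnot(inherits(x, "meth_matrix"), inherits(exclusions, "probe_exclusions"))
  drop <- unique(unlist(exclusions, use.names = FALSE))
  keep <- !(x$feature_ids %in% drop)
  if (!any(keep)) {
    counts <- vapply(exclusions,
                     function(s) sum(x$feature_ids %in% s), integer(1))
    abort(paste0(
      "No probes survive exclusion. Per-category removals: ",
      paste(names(counts), counts, sep = "=", collapse = ", ")))
  }
  x$values <- x$values[, keep, drop = FALSE]
  x$feature_ids <- x$feature_ids[keep]
  x
}

#' Remove additive batch effects from a methylation matrix
#'
#' Fits, per feature, a univariate linear model on the batch factor and
#' removes the fitted batch effect, keeping residuals plus the feature's
#' grand mean. With a two-level balanced design this re-centers both batch
#' groups on the common mean; in general the corrected between-batch mean
#' difference is exactly zero per feature while the grand mean is preserved.
#' Intended for methylated/unmethylated signal matrices when available, or
#' directly for beta matrices (then clipped back to `[0, 1]`).
#'
#' @param x A [meth_matrix()] (uses its `batch` column) or a plain numeric
#'   matrix (then `batch_labels` is required).
#' @param batch_labels Character vector of batch labels, one per sample row.
#' @param clip Clip corrected values to `[0, 1]` (default `TRUE`; set to
#'   `FALSE` for raw signal matrices).
#' @return Object of the same type as `x` with corrected values.
#' @export
correct_batch <- function(x, batch_labels = NULL, clip = TRUE) {
  is_mm <- inherits(x, "meth_matrix")
  vals <- if (is_mm) x$values else x
  if (is_mm && is.null(batch_labels)) batch_labels <- x$samples$batch
  if (is.null(batch_labels)) abort("Batch labels are required.")
  batch_labels <- as.character(batch_labels)
  if (length(batch_labels) != nrow(vals)) {
    abort("One batch label per sample row is required.")
  }
  if (length(unique(batch_labels)) < 2L) {
    inform("Single batch level: batch correction is a no-op.")
    return(x)
  }
  # Closed form of the per-feature one-way fixed-effect fit: fitted values
  # are batch-group means, so corrected = value - group mean + grand mean.
  grand <- colMeans(vals, na.rm = TRUE)
  out <- vals
  for (b in unique(batch_labels)) {
    rows <- which(batch_labels == b)
    gm <- colMeans(vals[rows, , drop = FALSE], na.rm = TRUE)
    out[rows, ] <- sweep(vals[rows, , drop = FALSE], 2, gm - grand)
  }
  if (clip) out <- pmin(pmax(out, 0), 1)
  if (is_mm) {
    x$values <- out
    x
  } else {
    out
  }
}

#' Merge training matrices from several cohorts
#'
#' Row-concatenates the input matrices restricted to the intersection of
#' their probe sets; class (and batch) labels are concatenated alongside.
#' Up to row permutation the result does not depend on the input order.
#'
#' @param matrices A list of [meth_matrix()] objects.
#' @return A merged [meth_matrix()].
#' @export
assemble_training <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1L,
            all(vapply(matrices, inherits, logical(1), "meth_matrix")))
  if (length(matrices) == 1L) return(matrices[[1]])
  shared <- Reduce(intersect, lapply(matrices, `[[`, "feature_ids"))
  if (!length(shared)) abort("Empty probe intersection across cohorts.")
  ids <- unlist(lapply(matrices, function(m) m$samples$sample_id))
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate sample IDs across cohorts: ",
                 paste(head(unique(ids[duplicated(ids)]), 5), collapse = ", ")))
  }
  vals <- do.call(rbind, lapply(matrices,
                                function(m) m$values[, shared, drop = FALSE]))
  samples <- dplyr::bind_rows(lapply(matrices, `[[`, "samples"))
  meth_matrix(vals, class_labels = samples$class_label, sample_ids = ids,
              batch_labels = if ("batch" %in% names(samples)) samples$batch else NULL,
              feature_ids = shared)
}
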