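#' Train a weighted Bernoulli naive Bayes reference model
#'
#' Builds, from a matrix of bulk methylation rates, everything needed to
#' classify sparse binary single-molecule observations: per-class centroids
#' (the Bernoulli success probabilities), class priors, and ReliefF-derived
#' class-specific feature weights.
#'
#' Centroids are the per-class mean methylation rates. Priors follow the
#' empirical class distribution (or are uniform). Feature informativeness
#' \eqn{\omega_{i,j}} is the ReliefF score: for each sample of a class, the
#' mean per-feature distance to its k nearest foreign-class centroids
#' (misses) minus the mean distance to the remaining same-class samples
#' (hits), summed over the class's samples. Scores are turned into
#' likelihood exponents by \eqn{w = e^{-\omega}} (see [transform_weights()]
#' for the sign convention and its consequences).
#'
#' @param training A [meth_matrix()]. Missing rates are imputed by
#'   class-conditional means before weight computation.
#' @param k Number of nearest foreign centroids used as ReliefF misses
#'   (default 5; must be at most `m - 1`).
#' @param priors `"empirical"` (class frequencies) or `"uniform"`.
#' @param weighting `"relieff"` (default) or `"none"` for unit weights.
#' @param weight_transform Passed to [transform_weights()]: `"exp_neg"`
#'   (the printed convention, default) or `"exp_pos"`.
#' @param omega_clip Symmetric clipping band applied to \eqn{\omega} before
#'   exponentiation (default 50).
#'
#' @return An object of class `meth_nb` with elements `centroids` and
#'   `weights` (both classes x probes), `omega`, `log_priors`, `classes`,
#'   `feature_ids`, `n_per_class` and the training options.
#' @seealso [predict.meth_nb()], [relieff_weights()], [write_meth_nb()]
#' @export
meth_nb <- function(training, k = 5L,
                    priors = c("empirical", "uniform"),
                    weighting = c("relieff", "none"),
                    weight_transform = c("exp_neg", "exp_pos"),
                    omega_clip = 50) {
  stopifnot(inherits(training, "meth_matrix"))
  priors <- match.arg(priors)
  weighting <- match.arg(weighting)
  weight_transform <- match.arg(weight_transform)
  training <- impute_class_means(training)

  centroids <- train_centroids(training)
  classes <- rownames(centroids)
  m <- length(classes)
  p <- ncol(centroids)
  log_priors <- compute_priors(training$samples$class_label, mode = priors)
  log_priors <- log_priors[classes]

  if (weighting == "relieff") {
    omega <- relieff_weights(training, centroids, k = k)
    weights <- transform_weights(omega, transform = weight_transform,
                                 clip = omega_clip)
  } else {
    omega <- matrix(0, m, p, dimnames = dimnames(centroids))
    weights <- matrix(1, m, p, dimnames = dimnames(centroids))
  }

  structure(
    list(centroids = centroids, omega = omega, weights = weights,
         log_priors = log_priors, classes = classes,
         feature_ids = colnames(centroids),
         n_per_class = table(training$samples$class_label)[classes],
         k = as.integer(k), priors = priors, weighting = weighting,
         weight_transform = weight_transform, omega_clip = omega_clip),
    class = "meth_nb"
  )
}

#' @export
print.meth_nb <- function(x, ...) {
  cat("<meth_nb> ", length(x$classes), " classes x ",
      length(x$feature_ids), " probes (k = ", x$k,
      ", weighting = ", x$weighting,
      if (x$weighting != "none") paste0("/", x$weight_transform), ")\n",
      sep = "")
  invisible(x)
}

#' Per-class mean methylation rates (centroids)
#'
#' @param training A [meth_matrix()].
#' @return Numeric matrix, classes x probes; entry `[j, i]` is the mean rate
#'   of probe `i` over the samples of class `j` (missing values excluded).
#' @export
train_centroids <- function(training) {
  stopifnot(inherits(training, "meth_matrix"))
  cls <- training$samples$class_label
  vals <- training$values
  classes <- sort(unique(cls))
  cnt <- rowsum((!is.na(vals)) * 1, cls)
  tot <- rowsum(ifelse(is.na(vals), 0, vals), cls)
  centroids <- tot / cnt
  centroids[cnt == 0] <- NA_real_
  centroids[classes, , drop = FALSE]
}

#' Log class prior probabilities
#'
#' @param class_labels Character vector of training class labels.
#' @param mode `"empirical"` (\eqn{n_j / N}) or `"uniform"` (\eqn{1/m}).
#' @return Named numeric vector of log priors summing (after
#'   exponentiation) to one.
#' @export
compute_priors <- function(class_labels, mode = c("empirical", "uniform")) {
  mode <- match.arg(mode)
  tab <- table(as.character(class_labels))
  if (mode == "empirical") {
    log(as.numeric(tab) / sum(tab)) |> setNames(names(tab))
  } else {
    setNames(rep(-log(length(tab)), length(tab)), names(tab))
  }
}

#' ReliefF-style class-specific feature informativeness
#'
#' For every class \eqn{C_j} and feature \eqn{i}:
#' \deqn{\omega_{i,j} = \sum_{x \in C_j} \left[
#'   \frac{1}{k}\sum_{m \in KNN(x),\, l(m) \ne C_j} |x_i - m_i|
#'   - \frac{1}{n_j - 1}\sum_{h \in C_j,\, h \ne x} |x_i - h_i| \right]}
#' where the k nearest foreign centroids of a sample are identified by the
#' whole-profile mean absolute per-feature difference (Manhattan distance
#' divided by the feature count), matching the per-feature distance terms.
#' Singleton classes contribute a hit term of zero. Positive
#' \eqn{\omega} marks a feature that separates the class from its nearest
#' foreign centroids better than it varies within the class.
#'
#' @param training A [meth_matrix()] (no missing values; impute first).
#' @param centroids Classes x probes matrix from [train_centroids()].
#' @param k Number of nearest foreign centroids (must be `<= m - 1`).
#' @return Matrix \eqn{\omega}, classes x probes.
#' @export
relieff_weights <- function(training, centroids, k = 5L) {
  stopifnot(inherits(training, "meth_matrix"))
  vals <- training$values
  if (anyNA(vals)) abort("relieff_weights() needs complete data; impute first.")
  cls <- training$samples$class_label
  classes <- rownames(centroids)
  m <- length(classes)
  if (k > m - 1L) {
    abort(paste0("k = ", k, " exceeds the number of foreign centroids (",
                 m - 1L, ")."))
  }
  p <- ncol(vals)
  # whole-profile distances, samples x centroids
  D <- matrix(0, nrow(vals), m)
  for (j in seq_len(m)) {
    D[, j] <- rowMeans(abs(sweep(vals, 2, centroids[j, ])))
  }
  omega <- matrix(0, m, p, dimnames = list(classes, colnames(vals)))
  for (j in seq_len(m)) {
    rows <- which(cls == classes[j])
    nj <- length(rows)
    acc <- numeric(p)
    for (s in rows) {
      d <- D[s, ]
      d[j] <- Inf
      knn <- order(d)[seq_len(k)]
      miss <- colMeans(abs(sweep(centroids[knn, , drop = FALSE], 2,
                                 vals[s, ])))
      if (nj > 1L) {
        hits <- rows[rows != s]
        hit <- colMeans(abs(sweep(vals[hits, , drop = FALSE], 2, vals[s, ])))
      } else {
        hit <- 0
      }
      acc <- acc + (miss - hit)
    }
    omega[j, ] <- acc
  }
  omega
}

#' Transform ReliefF scores into likelihood exponents
#'
#' Applies \eqn{w = e^{-\omega}} elementwise (strictly positive, strictly
#' decreasing in \eqn{\omega}), after clipping \eqn{\omega} to
#' `[-clip, clip]` to avoid overflow. Note the sign: under this convention
#' informative features (\eqn{\omega > 0}) receive exponents below one,
#' i.e. their likelihood contribution is flattened. The package implements
#' this convention as published and exposes `transform = "exp_pos"`
#' (\eqn{w = e^{+\omega}}) as the documented alternative; see the methods
#' vignette for measurements of what each does on separable synthetic data.
#'
#' @param omega Numeric matrix or vector of ReliefF scores.
#' @param transform `"exp_neg"` (default) or `"exp_pos"`.
#' @param clip Clipping band for `omega` (default 50).
#' @return Weights of the same shape as `omega`.
#' @export
transform_weights <- function(omega, transform = c("exp_neg", "exp_pos"),
                              clip = 50) {
  transform <- match.arg(transform)
  if (any(!is.finite(omega))) abort("`omega` must be finite.")
  clipped <- omega
  over <- abs(clipped) > clip
  if (any(over)) {
    inform(paste0("Clipped ", sum(over), " omega values to the +/-", clip,
                  " band before exponentiation."))
    clipped[clipped > clip] <- clip
    clipped[clipped < -clip] <- -clip
  }
  if (transform == "exp_neg") exp(-clipped) else exp(clipped)
}

#' @exportS3Method generics::tidy
tidy.meth_nb <- function(x, features = NULL, ...) {
  feats <- features %||% x$feature_ids
  idx <- match(feats, x$feature_ids)
  if (anyNA(idx)) abort("Unknown feature IDs in `features`.")
  tidyr::expand_grid(class = x$classes, feature = feats) |>
    dplyr::mutate(
      centroid = as.vector(t(x$centroids[, idx, drop = FALSE])),
      omega = as.vector(t(x$omega[, idx, drop = FALSE])),
      weight = as.vector(t(x$weights[, idx, drop = FALSE]))
    )
}

#' @exportS3Method generics::glance
glance.meth_nb <- function(x, ...) {
  tibble(n_classes = length(x$classes),
         n_features = length(x$feature_ids),
         n_samples = sum(x$n_per_class),
         k = x$k, priors = x$priors, weighting = x$weighting,
         weight_transform = x$weight_transform)
}

#' Serialize a reference model to a directory
#'
#' Writes centroid and weight matrices as Feather tables plus a JSON
#' metadata file (class labels, priors, k, options, content checksums and
#' package version), so a model round-trips bit-identically through
#' [read_meth_nb()].
#'
#' @param model A [meth_nb()] model.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_meth_nb <- function(model, dir) {
  stopifnot(inherits(model, "meth_nb"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat_tbl <- function(m) {
    tb <- as_tibble(t(m))
    tb$feature_id <- model$feature_ids
    tb
  }
  arrow::write_feather(mat_tbl(model$centroids),
                       file.path(dir, "centroids.feather"))
  arrow::write_feather(mat_tbl(model$omega), file.path(dir, "omega.feather"))
  arrow::write_feather(mat_tbl(model$weights),
                       file.path(dir, "weights.feather"))
  meta <- list(
    classes = model$classes,
    log_priors = unname(model$log_priors),
    n_per_class = as.integer(model$n_per_class),
    k = model$k, priors = model$priors, weighting = model$weighting,
    weight_transform = model$weight_transform, omega_clip = model$omega_clip,
    checksums = list(
      centroids = unname(tools::md5sum(file.path(dir, "centroids.feather"))),
      weights = unname(tools::md5sum(file.path(dir, "weights.feather")))
    ),
    package_version = as.character(utils::packageVersion("methylnb"))
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a reference model written by [write_meth_nb()]
#'
#' @param dir Model directory.
#' @return A [meth_nb()] model.
#' @export
read_meth_nb <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  rd <- function(f) {
    tb <- arrow::read_feather(file.path(dir, f))
    feats <- tb$feature_id
    m <- t(as.matrix(tb[setdiff(names(tb), "feature_id")]))
    colnames(m) <- feats
    m
  }
  centroids <- rd("centroids.feather")
  structure(
    list(centroids = centroids, omega = rd("omega.feather"),
         weights = rd("weights.feather"),
         log_priors = setNames(meta$log_priors, meta$classes),
         classes = meta$classes, feature_ids = colnames(centroids),
         n_per_class = setNames(meta$n_per_class, meta$classes),
         k = meta$k, priors = meta$priors, weighting = meta$weighting,
         weight_transform = meta$weight_transform,
         omega_clip = meta$omega_clip),
    class = "meth_nb"
  )
}
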