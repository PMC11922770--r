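#' Assemble a sample observation for posterior computation
#'
#' A sample observation is the filtered, binarized, weighted set of
#' single-molecule CpG calls that enters the likelihood: one row per call
#' with the probe ID, the binary methylation state `x`, the read weight `r`
#' (1 / number of model CpGs on the same read) and the per-call noise term
#' `eta`. Several calls may cover the same probe (different molecules);
#' each is treated as an independent observation.
#'
#' @param calls A tibble of binarized calls, minimally with columns
#'   `epic_id` and `binary_methylation`; `read_weight` and `eta` are used
#'   when present.
#' @param constant_read_weight If `TRUE`, read weights are forced to 1
#'   (the convention for synthetic profiles, where the 300/sum(r) scale
#'   is then a no-op by construction only when exactly 300 calls are
#'   present; disable scaling with `scale = FALSE` in the predictor).
#' @param uniform_noise Optional single value in `[0.05, 0.5]` overriding
#'   the per-call noise terms (synthetic-profile convention: 0.05).
#' @param base_count Base read count the log-likelihood is standardized to
#'   (default 300).
#' @return A tibble with columns `probe_id`, `x`, `r`, `eta`, carrying the
#'   scale factor `base_count / sum(r)` as attribute `scale`.
#' @export
new_observation <- function(calls, constant_read_weight = FALSE,
                            uniform_noise = NULL, base_count = 300) {
  stopifnot(is.data.frame(calls))
  if (!all(c("epic_id", "binary_methylation") %in% names(calls))) {
    abort("Calls need `epic_id` and `binary_methylation` columns.")
  }
  if (nrow(calls) == 0L) abort("no informative CpGs")
  r <- if (constant_read_weight || is.null(calls$read_weight)) {
    rep(1, nrow(calls))
  } else {
    calls$read_weight
  }
  eta <- if (!is.null(uniform_noise)) {
    rep(uniform_noise, nrow(calls))
  } else if (!is.null(calls$eta)) {
    calls$eta
  } else if (!is.null(calls$methylation)) {
    compute_noise(calls$methylation)
  } else {
    rep(0.05, nrow(calls))
  }
  obs <- tibble(probe_id = as.character(calls$epic_id),
                x = as.numeric(calls$binary_methylation),
                r = as.numeric(r), eta = pmin(pmax(eta, 0.05), 0.5))
  if (any(!obs$x %in% c(0, 1))) abort("`binary_methylation` must be 0/1.")
  attr(obs, "scale") <- base_count / sum(obs$r)
  obs
}

#' Shrink centroids toward 0.5 by per-call noise
#'
#' Applies \eqn{\mu' = \mu(1 - 2\eta) + \eta} columnwise, so that with the
#' noise floor \eqn{\eta \ge 0.05} every adjusted probability lies in
#' `[0.05, 0.95]` and both \eqn{\log\mu'} and \eqn{\log(1-\mu')} are
#' finite. \eqn{\mu = 0.5} is a fixed point for any \eqn{\eta}.
#'
#' @param mu Classes x calls matrix of centroid values (already restricted
#'   to the observed calls).
#' @param eta Noise vector, one value per call (column).
#' @return Adjusted matrix of the same shape.
#' @export
adjust_centroids_for_noise <- function(mu, eta) {
  if (length(eta) == 1L) eta <- rep(eta, ncol(mu))
  stopifnot(length(eta) == ncol(mu))
  sweep(mu, 2, 1 - 2 * eta, `*`) + rep(eta, each = nrow(mu))
}

#' Weighted Bernoulli log-likelihood per class
#'
#' For each class \eqn{j} computes
#' \deqn{L_j = \frac{s}{W_j} \sum_c r_c\, w_{j,c}\,
#'   [x_c \log \mu'_{j,c} + (1 - x_c) \log(1 - \mu'_{j,c})]}
#' over the observed calls \eqn{c}, where \eqn{s = 300/\sum_c r_c} is the
#' base-count scale and \eqn{W_j} is the class's mean observed weight, so
#' every class spends the same total weight mass. Unobserved model features
#' are simply omitted. Only classes x n-calls intermediates are
#' materialized; the full model matrices are never copied.
#'
#' @param obs A [new_observation()] tibble.
#' @param model A [meth_nb()] model.
#' @param scale Apply the base-count scale (default `TRUE`; with `FALSE`
#'   the raw weight-normalized sum is returned).
#' @param normalize Class-weight normalization: `"mean_weight"` (default,
#'   divide by the class's mean observed weight) or `"none"`.
#' @return Named vector of per-class log-likelihoods, with attribute
#'   `dims_used = c(n_classes, n_calls)` recording the only dense
#'   intermediate shape used.
#' @export
weighted_log_likelihood <- function(obs, model, scale = TRUE,
                                    normalize = c("mean_weight", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(model, "meth_nb"))
  if (nrow(obs) == 0L) abort("no informative CpGs")
  idx <- match(obs$probe_id, model$feature_ids)
  if (anyNA(idx)) {
    obs <- obs[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
    if (nrow(obs) == 0L) abort("no informative CpGs")
  }
  mu <- adjust_centroids_for_noise(model$centroids[, idx, drop = FALSE],
                                   obs$eta)
  w <- model$weights[, idx, drop = FALSE]
  ll_terms <- sweep(log(mu), 2, obs$x, `*`) +
    sweep(log1p(-mu), 2, 1 - obs$x, `*`)
  L <- as.vector((w * ll_terms) %*% obs$r)
  if (normalize == "mean_weight") L <- L / rowMeans(w)
  if (scale) L <- L * (attr(obs, "scale") %||% (300 / sum(obs$r)))
  names(L) <- model$classes
  attr(L, "dims_used") <- c(nrow(w), ncol(w))
  L
}

#' Posterior class probabilities from log-likelihoods and log-priors
#'
#' Combines \eqn{l_j = L_j + \log P(C_j)} and normalizes with the
#' log-sum-exp trick, \eqn{\log P(X) = l_{max} + \log\sum_j e^{l_j -
#' l_{max}}}, so posteriors stay finite for log-likelihoods down to
#' \eqn{-10^6}. Posteriors sum to one.
#'
#' @param log_likelihoods,log_priors Equal-length numeric vectors.
#' @return A `meth_posterior` tibble with columns `class`,
#'   `log_posterior`, `posterior`, sorted by decreasing posterior.
#' @export
posterior <- function(log_likelihoods, log_priors) {
  if (length(log_likelihoods) != length(log_priors)) {
    abort("log-likelihoods and log-priors must have equal length.")
  }
  if (anyNA(log_likelihoods) || anyNA(log_priors)) {
    abort("NaN/NA in posterior inputs.")
  }
  l <- as.numeric(log_likelihoods) + as.numeric(log_priors)
  lmax <- max(l)
  log_post <- l - (lmax + log(sum(exp(l - lmax))))
  out <- tibble(
    class = names(log_likelihoods) %||% as.character(seq_along(l)),
    log_posterior = log_post,
    posterior = exp(log_post)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$posterior), .data$class)
  class(out) <- c("meth_posterior", class(out))
  out
}

#' Certainty decision at a posterior threshold
#'
#' Returns the top class (argmax of the posterior; ties broken by
#' lexicographic class name, with a message) flagged as high certainty if
#' its posterior is at least `tau`.
#'
#' @param post A [posterior()] result.
#' @param tau Posterior threshold in `[0, 1]` (default 0.6, the operating
#'   point balancing precision and recall).
#' @return One-row tibble: `top_class`, `top_posterior`, `high_certainty`.
#' @export
classify <- function(post, tau = 0.6) {
  stopifnot(inherits(post, "meth_posterior"), tau >= 0, tau <= 1)
  top <- max(post$posterior)
  cand <- sort(post$class[post$posterior == top])
  if (length(cand) > 1L) {
    inform(paste0("Posterior tie between {", paste(cand, collapse = ", "),
                  "}; reporting the lexicographically first."))
  }
  tibble(top_class = cand[1], top_posterior = top,
         high_certainty = top >= tau)
}

#' Classify a sample from its methylation calls
#'
#' End-to-end prediction: builds an observation from binarized calls,
#' computes the weighted Bernoulli naive Bayes posterior and applies the
#' certainty decision rule.
#'
#' @param object A [meth_nb()] model.
#' @param calls Binarized calls tibble (see [new_observation()]).
#' @param tau Posterior threshold (default 0.6).
#' @param constant_read_weight,uniform_noise,base_count Passed to
#'   [new_observation()].
#' @param scale,normalize Passed to [weighted_log_likelihood()].
#' @param ... Unused.
#' @return One-row tibble with `top_class`, `top_posterior`,
#'   `high_certainty`, `n_calls`, `n_features`, `effective_read_count`
#'   (\eqn{\sum r_i}) and a `posterior` list-column holding the full
#'   posterior tibble.
#' @export
predict.meth_nb <- function(object, calls, tau = 0.6,
                            constant_read_weight = FALSE,
                            uniform_noise = NULL, base_count = 300,
                            scale = TRUE,
                            normalize = c("mean_weight", "none"), ...) {
  obs <- if (is.data.frame(calls) && all(c("probe_id", "x") %in% names(calls))) {
    calls # already an observation
  } else {
    new_observation(calls, constant_read_weight = constant_read_weight,
                    uniform_noise = uniform_noise, base_count = base_count)
  }
  ll <- weighted_log_likelihood(obs, object, scale = scale,
                                normalize = normalize)
  post <- posterior(ll, object$log_priors)
  dec <- classify(post, tau = tau)
  dplyr::mutate(dec,
                n_calls = nrow(obs),
                n_features = dplyr::n_distinct(obs$probe_id),
                effective_read_count = sum(obs$r),
                posterior = list(post))
}

#' @exportS3Method ggplot2::autoplot
autoplot.meth_posterior <- function(object, top_n = 10, ...) {
  df <- head(dplyr::arrange(object, dplyr::desc(.data$posterior)), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$class, .data$posterior),
    y = .data$posterior)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Posterior probability") +
    ggplot2::theme_minimal()
}
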