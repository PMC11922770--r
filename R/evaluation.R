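#' Define a three-tier class hierarchy
#'
#' Maps every fine training class to a broader clinical group (mid tier)
#' and to a class family (top tier); predictions can then be scored at any
#' tier, mirroring how fine tumor classes are consolidated into clinically
#' actionable groups and into families of histologically related tumors.
#'
#' @param table Data frame with columns `fine_class`, `mid_class`,
#'   `family` (one row per fine class; maps must be total).
#' @return A `class_hierarchy` tibble.
#' @export
class_hierarchy <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("fine_class", "mid_class", "family")
  if (!all(need %in% names(table))) {
    abort("Hierarchy needs `fine_class`, `mid_class`, `family` columns.")
  }
  tb <- as_tibble(table)[need]
  if (anyDuplicated(tb$fine_class)) {
    abort("Each fine class must map to exactly one mid class and family.")
  }
  structure(tb, class = c("class_hierarchy", class(tb)))
}

#' Read a class hierarchy from a delimited file
#'
#' Three tab-separated columns: fine class, mid-tier class, family.
#'
#' @param path File path (header optional; sniffed).
#' @return A [class_hierarchy()].
#' @export
read_class_hierarchy <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("fine_class", first)
  tb <- readr::read_tsv(path,
                        col_names = if (has_header) TRUE else
                          c("fine_class", "mid_class", "family"),
                        show_col_types = FALSE, progress = FALSE)
  class_hierarchy(tb)
}

#' Map class labels to a hierarchy tier
#'
#' @param labels Character vector of fine class labels.
#' @param hierarchy A [class_hierarchy()].
#' @param tier `"fine"` (identity), `"mid"` or `"family"`.
#' @return Relabeled character vector.
#' @export
map_tier <- function(labels, hierarchy, tier = c("fine", "mid", "family")) {
  tier <- match.arg(tier)
  if (tier == "fine") return(as.character(labels))
  idx <- match(labels, hierarchy$fine_class)
  if (anyNA(idx)) {
    abort(paste0("Labels missing from hierarchy: ",
                 paste(unique(labels[is.na(idx)]), collapse = ", ")))
  }
  col <- if (tier == "mid") "mid_class" else "family"
  as.character(hierarchy[[col]][idx])
}

#' Score predictions against truth at a hierarchy tier
#'
#' Computes the row-normalized confusion matrix (rows are reference
#' classes), per-class precision/recall/F1 (one-vs-rest) and per-class
#' accuracy (recall), the overall accuracy, and the median per-class
#' accuracy. When a `high_certainty` column is present, overall accuracy
#' is computed over high-certainty calls only and the no-call count is
#' reported separately. A class absent from both truth and prediction has
#' undefined (missing, not zero) F1.
#'
#' @param data Tibble with columns `truth` and `prediction`, optionally
#'   `high_certainty`.
#' @param hierarchy Optional [class_hierarchy()]; when given, both labels
#'   are mapped with [map_tier()] before scoring.
#' @param tier Tier to score at (default `"fine"`).
#' @return A `meth_eval` list: `overall_accuracy` (over called samples),
#'   `median_class_accuracy`, `n_samples`, `n_called`, `n_no_call`,
#'   `call_rate`, `per_class` tibble and `confusion` tibble (`truth`,
#'   `prediction`, `n`, `freq` with `freq` row-normalized).
#' @export
score_predictions <- function(data, hierarchy = NULL,
                              tier = c("fine", "mid", "family")) {
  tier <- match.arg(tier)
  stopifnot(all(c("truth", "prediction") %in% names(data)))
  truth <- as.character(data$truth)
  pred <- as.character(data$prediction)
  if (!is.null(hierarchy)) {
    truth <- map_tier(truth, hierarchy, tier)
    pred <- map_tier(pred, hierarchy, tier)
  }
  called <- if ("high_certainty" %in% names(data)) {
    as.logical(data$high_certainty)
  } else {
    rep(TRUE, length(truth))
  }
  n <- length(truth)
  tc <- truth[called]
  pc <- pred[called]
  classes <- sort(unique(c(tc, pc)))
  conf <- tibble(truth = tc, prediction = pc) |>
    dplyr::count(.data$truth, .data$prediction, name = "n") |>
    dplyr::group_by(.data$truth) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  per_class <- purrr::map_dfr(classes, function(cl) {
    tp <- sum(tc == cl & pc == cl)
    fp <- sum(tc != cl & pc == cl)
    fn <- sum(tc == cl & pc != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (tp + fn == 0 && tp + fp == 0) {
      NA_real_ # class absent from both truth and prediction
    } else if (tp == 0) {
      0
    } else {
      2 * prec * rec / (prec + rec)
    }
    tibble(class = cl, n_truth = tp + fn, precision = prec, recall = rec,
           f1 = f1, class_accuracy = rec)
  })
  structure(
    list(overall_accuracy = if (length(tc)) mean(tc == pc) else NA_real_,
         median_class_accuracy =
           median(per_class$class_accuracy, na.rm = TRUE),
         n_samples = n, n_called = sum(called),
         n_no_call = n - sum(called), call_rate = mean(called),
         tier = tier, per_class = per_class, confusion = conf),
    class = "meth_eval"
  )
}

#' @export
print.meth_eval <- function(x, ...) {
  cat("<meth_eval> ", x$n_called, "/", x$n_samples,
      " called; overall accuracy ", sprintf("%.4f", x$overall_accuracy),
      " (median per-class ", sprintf("%.4f", x$median_class_accuracy),
      ") at tier '", x$tier, "'\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.meth_eval <- function(x, ...) x$per_class

#' @exportS3Method generics::glance
glance.meth_eval <- function(x, ...) {
  tibble(overall_accuracy = x$overall_accuracy,
         median_class_accuracy = x$median_class_accuracy,
         n_samples = x$n_samples, n_called = x$n_called,
         n_no_call = x$n_no_call, call_rate = x$call_rate, tier = x$tier)
}

#' @exportS3Method ggplot2::autoplot
autoplot.meth_eval <- function(object, ...) {
  ggplot2::ggplot(object$confusion,
                  ggplot2::aes(x = .data$prediction, y = .data$truth,
                               fill = .data$freq)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Predicted class", y = "Reference class",
                  fill = "Relative\nfrequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Sweep the posterior decision threshold
#'
#' For each threshold, samples whose top posterior reaches it are
#' "called"; precision is accuracy over the called subset, recall the
#' fraction of all samples called correctly, and the call rate the called
#' fraction.
#'
#' @param predictions Tibble with `truth`, `top_class`, `top_posterior`.
#' @param grid Thresholds (default 0 to 1 in increments of 0.1).
#' @return Tibble: `tau`, `n_called`, `call_rate`, `precision`, `recall`.
#' @export
threshold_sweep <- function(predictions, grid = seq(0, 1, by = 0.1)) {
  stopifnot(all(c("truth", "top_class", "top_posterior") %in%
                  names(predictions)))
  purrr::map_dfr(grid, function(tau) {
    called <- predictions$top_posterior >= tau
    correct <- called & (predictions$truth == predictions$top_class)
    tibble(tau = tau, n_called = sum(called),
           call_rate = mean(called),
           precision = if (any(called)) sum(correct) / sum(called)
                       else NA_real_,
           recall = sum(correct) / nrow(predictions))
  })
}

#' Classification accuracy along a sequencing time course
#'
#' Replays a call table as if sequencing had been stopped at each grid
#' point: calls with `start_time` up to t are binarized, filtered,
#' weighted and classified. The default grid is 5, 10, 15, 30 and 45
#' minutes and 1, 3, 5, 12, 24, 48 and 72 hours.
#'
#' @param calls Raw calls tibble (with `start_time`).
#' @param model A [meth_nb()] model.
#' @param truth Optional true class label of the sample.
#' @param grid Time points in seconds.
#' @param config An [ingest_config()].
#' @param tau Posterior threshold (default 0.6).
#' @return Tibble per grid point: `t`, `n_calls`, `n_cpgs`, `top_class`,
#'   `top_posterior`, `high_certainty` and, when truth is given,
#'   `correct`. Time points with no usable calls yield a no-call row.
#' @export
time_course <- function(calls, model, truth = NULL,
                        grid = c(c(5, 10, 15, 30, 45) * 60,
                                 c(1, 3, 5, 12, 24, 48, 72) * 3600),
                        config = ingest_config(), tau = 0.6) {
  purrr::map_dfr(grid, function(t) {
    sub <- filter_time_window(calls, t)
    base <- tibble(t = t, n_calls = 0L, n_cpgs = 0L,
                   top_class = NA_character_, top_posterior = NA_real_,
                   high_certainty = FALSE)
    if (nrow(sub) == 0L) return(base)
    pred <- tryCatch({
      ready <- filter_and_weight_reads(binarize_calls(sub, config), config)
      predict(model, ready, tau = tau, base_count = config$base_count)
    }, error = function(e) NULL)
    if (is.null(pred)) return(base)
    tibble(t = t, n_calls = pred$n_calls, n_cpgs = pred$n_features,
           top_class = pred$top_class, top_posterior = pred$top_posterior,
           high_certainty = pred$high_certainty)
  }) |>
    (\(tb) if (is.null(truth)) tb else
      dplyr::mutate(tb, correct = .data$top_class == truth))()
}

#' Compare paired per-class F1 vectors between two models
#'
#' Two-sided Wilcoxon signed-rank test on paired per-class F1 scores. For
#' up to 12 informative pairs the null distribution is enumerated exactly
#' over all sign assignments (average ranks for tied magnitudes, zero
#' differences dropped); beyond that [stats::wilcox.test()] is used.
#' All-zero differences give p = 1 by convention.
#'
#' @param f1_a,f1_b Equal-length numeric vectors of per-class F1 scores
#'   (pairs with missing values are dropped).
#' @return The two-sided p-value.
#' @export
compare_f1 <- function(f1_a, f1_b) {
  stopifnot(length(f1_a) == length(f1_b))
  keep <- !(is.na(f1_a) | is.na(f1_b))
  d <- f1_a[keep] - f1_b[keep]
  d <- d[d != 0]
  if (!length(d)) {
    inform("All paired differences are zero; p = 1 by convention.")
    return(1)
  }
  if (length(d) <= 12L) {
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
    v_null <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(v_null <= v_obs), mean(v_null >= v_obs)))
    return(p)
  }
  suppressWarnings(
    stats::wilcox.test(f1_a[keep], f1_b[keep], paired = TRUE,
                       alternative = "two.sided")$p.value)
}
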