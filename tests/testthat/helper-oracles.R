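# Independent brute-force oracles and small fixture builders shared across
# the suite. The oracles deliberately use plain double loops and never call
# the package's vectorized code paths.

tiny_matrix <- function(values, classes, batches = NULL, probes = NULL) {
  meth_matrix(values, class_labels = classes, batch_labels = batches,
              feature_ids = probes %||% colnames(values))
}

random_matrix <- function(n, p, m, seed, sigma = 0.1) {
  withr::with_seed(seed, {
    classes <- rep(LETTERS[seq_len(m)], length.out = n)
    centers <- matrix(runif(m * p, 0.1, 0.9), m, p)
    vals <- t(vapply(seq_len(n), function(i) {
      pmin(pmax(centers[match(classes[i], LETTERS), ] + rnorm(p, 0, sigma),
                0.02), 0.98)
    }, numeric(p)))
    colnames(vals) <- sprintf("cg%04d", seq_len(p))
    meth_matrix(vals, class_labels = classes)
  })
}

oracle_centroids <- function(vals, classes) {
  cls <- sort(unique(classes))
  out <- matrix(NA_real_, length(cls), ncol(vals),
                dimnames = list(cls, colnames(vals)))
  for (j in seq_along(cls)) {
    for (i in seq_len(ncol(vals))) {
      v <- vals[classes == cls[j], i]
      out[j, i] <- mean(v[!is.na(v)])
    }
  }
  out
}

# direct double-loop evaluation of the ReliefF score: for each sample of a
# class, mean |x_i - m_i| over its k nearest foreign centroids (nearest by
# whole-profile mean absolute difference) minus mean |x_i - h_i| over the
# other same-class samples, summed over the class
oracle_relieff <- function(vals, classes, centroids, k) {
  cls <- rownames(centroids)
  p <- ncol(vals)
  omega <- matrix(0, length(cls), p, dimnames = list(cls, colnames(vals)))
  for (j in seq_along(cls)) {
    rows <- which(classes == cls[j])
    for (s in rows) {
      d <- vapply(seq_along(cls),
                  function(c) mean(abs(vals[s, ] - centroids[c, ])),
                  numeric(1))
      d[j] <- Inf
      knn <- order(d)[seq_len(k)]
      for (i in seq_len(p)) {
        miss <- mean(abs(vals[s, i] - centroids[knn, i]))
        hit <- if (length(rows) > 1L) {
          mean(abs(vals[s, i] - vals[setdiff(rows, s), i]))
        } else 0
        omega[j, i] <- omega[j, i] + (miss - hit)
      }
    }
  }
  omega
}

# direct evaluation of the weighted Bernoulli log-likelihood and posterior,
# one scalar term at a time
oracle_weighted_posterior <- function(obs, centroids, weights, log_priors,
                                      scale = FALSE,
                                      normalize = TRUE) {
  cls <- rownames(centroids)
  L <- numeric(length(cls))
  for (j in seq_along(cls)) {
    acc <- 0
    wsum <- 0
    for (c in seq_len(nrow(obs))) {
      mu <- centroids[j, obs$probe_id[c]]
      mup <- mu - mu * 2 * obs$eta[c] + obs$eta[c]
      w <- weights[j, obs$probe_id[c]]
      acc <- acc + obs$r[c] * w *
        (obs$x[c] * log(mup) + (1 - obs$x[c]) * log(1 - mup))
      wsum <- wsum + w
    }
    if (normalize) acc <- acc / (wsum / nrow(obs))
    if (scale) acc <- acc * 300 / sum(obs$r)
    L[j] <- acc + log_priors[j]
  }
  lmax <- max(L)
  post <- exp(L - (lmax + log(sum(exp(L - lmax)))))
  names(post) <- cls
  post
}

# textbook (unweighted) Bernoulli naive Bayes on noise-adjusted success
# probabilities
oracle_textbook_nb <- function(x, probe_ids, mu_adj, log_priors) {
  cls <- rownames(mu_adj)
  L <- numeric(length(cls))
  for (j in seq_along(cls)) {
    for (c in seq_along(x)) {
      mu <- mu_adj[j, probe_ids[c]]
      L[j] <- L[j] + x[c] * log(mu) + (1 - x[c]) * log(1 - mu)
    }
    L[j] <- L[j] + log_priors[j]
  }
  lmax <- max(L)
  setNames(exp(L - (lmax + log(sum(exp(L - lmax))))), cls)
}

toy_hierarchy <- function() {
  class_hierarchy(tibble::tibble(
    fine_class = c("gbm_rtk1", "gbm_rtk2", "gbm_mes", "mb_shh", "mb_wnt",
                   "epn_pf"),
    mid_class = c("gbm", "gbm", "gbm", "mb", "mb", "epn"),
    family = c("glioma", "glioma", "glioma", "embryonal", "embryonal",
               "ependymal")))
}

# calls tibble builder for read-level tests that do not need a BAM
make_calls <- function(probe, m, read, t = 0, len = 300L, qs = 20,
                       mapq = 60L, run = "run1") {
  n <- length(probe)
  tibble::tibble(
    epic_id = probe, methylation = m,
    scores_per_read = as.integer(ave(seq_len(n), read, FUN = length)),
    binary_methylation = NA_real_, read_id = read,
    start_time = rep_len(t, n), run_id = rep_len(run, n),
    QS = rep_len(qs, n), read_length = rep_len(len, n),
    map_qs = rep_len(mapq, n))
}
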