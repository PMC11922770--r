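test_that("centroids are per-class feature means", {
  vals <- matrix(c(0.2, 0.4, 0.9, 0.1, 0.3, 0.7), 3, 2,
                 dimnames = list(NULL, c("p1", "p2")))
  mm <- tiny_matrix(vals, c("A", "A", "B"))
  mu <- train_centroids(mm)
  expect_equal(mu["A", "p1"], 0.3)
  expect_equal(mu["B", ], c(p1 = 0.9, p2 = 0.7)) # singleton class = sample
})

test_that("centroids match a brute-force double loop on random data", {
  mm <- random_matrix(30, 50, 3, seed = 11)
  expect_equal(train_centroids(mm),
               oracle_centroids(mm$values, mm$samples$class_label),
               tolerance = 1e-12)
})

test_that("priors follow the empirical class distribution or are uniform", {
  lp <- compute_priors(c("A", "A", "B"))
  expect_equal(exp(lp), c(A = 2 / 3, B = 1 / 3))
  lu <- compute_priors(letters[1:4], mode = "uniform")
  expect_equal(unname(exp(lu)), rep(0.25, 4))
  many <- sample(paste0("c", 1:91), 2801, replace = TRUE)
  expect_equal(sum(exp(compute_priors(many))), 1, tolerance = 1e-12)
})

test_that("ReliefF scores match the printed formula evaluated by brute force", {
  mm <- random_matrix(12, 8, 3, seed = 5, sigma = 0.15)
  mu <- train_centroids(mm)
  omega <- relieff_weights(mm, mu, k = 2)
  expect_equal(omega, oracle_relieff(mm$values, mm$samples$class_label,
                                     mu, k = 2),
               tolerance = 1e-12)
})

test_that("ReliefF hand example and degenerate cases evaluate correctly", {
  # 2 classes x 2 samples; the feature is 0 in A and 1 in B, k = 1:
  # each A sample has miss |0-1| = 1 and hit |0-0| = 0, so omega_A = 2
  vals <- matrix(c(0, 0, 1, 1, 0.5, 0.5, 0.5, 0.5), 4, 2,
                 dimnames = list(NULL, c("f_sep", "f_const")))
  mm <- tiny_matrix(vals, c("A", "A", "B", "B"))
  omega <- relieff_weights(mm, train_centroids(mm), k = 1)
  expect_equal(omega["A", "f_sep"], 2)
  expect_equal(omega["B", "f_sep"], 2)
  # constant feature: all per-feature distances are zero
  expect_equal(unname(omega[, "f_const"]), c(0, 0))
  expect_error(relieff_weights(mm, train_centroids(mm), k = 2),
               "foreign centroids")
})

test_that("weight transform is the printed exponential with clipping", {
  expect_equal(transform_weights(0), 1)
  expect_equal(transform_weights(log(2)), 0.5)
  withr::with_seed(1, {
    o <- sort(rnorm(50, sd = 3))
    w <- transform_weights(o)
    expect_true(all(diff(w) < 0)) # strictly decreasing in omega
    expect_true(all(w > 0))
  })
  expect_message(w <- transform_weights(c(-100, 100)), "Clipped")
  expect_equal(w, c(exp(50), exp(-50)))
  expect_equal(transform_weights(log(2), transform = "exp_pos"), 2)
})

test_that("noise adjustment shrinks centroids into [0.05, 0.95]", {
  expect_equal(adjust_centroids_for_noise(matrix(0.8), 0.05),
               matrix(0.77))
  expect_equal(adjust_centroids_for_noise(matrix(0.5), 0.3), matrix(0.5))
  expect_equal(adjust_centroids_for_noise(matrix(0), 0.05), matrix(0.05))
  withr::with_seed(2, {
    mu <- matrix(runif(60), 3, 20)
    eta <- runif(20, 0.05, 0.5)
    adj <- adjust_centroids_for_noise(mu, eta)
    expect_true(all(adj >= 0.05 & adj <= 0.95))
  })
})

test_that("weighted log-likelihood reduces to single-term and oracle values", {
  # one feature, x = 1, mu' = 0.9, unit weight and read weight, no scale
  mu0 <- (0.9 - 0.05) / (1 - 2 * 0.05) # adjusts to exactly 0.9 at eta 0.05
  model <- meth_nb(tiny_matrix(matrix(c(mu0, mu0), 1, 2,
                                      dimnames = list(NULL, c("p1", "p2"))),
                               "A"),
                   weighting = "none", k = 0)
  obs <- tibble::tibble(probe_id = "p1", x = 1, r = 1, eta = 0.05)
  ll <- weighted_log_likelihood(obs, model, scale = FALSE)
  expect_equal(as.numeric(ll), log(0.9), tolerance = 1e-12)
})

test_that("weighted posterior equals direct evaluation on random instances", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      m <- sample(2:5, 1)
      p <- sample(5:20, 1)
      mm <- random_matrix(4 * m, p, m, seed = seed + 100, sigma = 0.2)
      model <- meth_nb(mm, k = min(2, m - 1))
      n_obs <- sample(3:p, 1)
      obs <- tibble::tibble(
        probe_id = sample(model$feature_ids, n_obs),
        x = rbinom(n_obs, 1, 0.5),
        r = 1 / sample(1:4, n_obs, replace = TRUE),
        eta = runif(n_obs, 0.05, 0.5))
      attr(obs, "scale") <- 300 / sum(obs$r)
      got <- posterior(weighted_log_likelihood(obs, model, scale = TRUE),
                       model$log_priors)
      want <- oracle_weighted_posterior(obs, model$centroids,
                                        model$weights, model$log_priors,
                                        scale = TRUE)
      expect_equal(setNames(got$posterior, got$class)[names(want)], want,
                   tolerance = 1e-10)
    })
  }
})

test_that("unit weights and singleton reads recover the textbook Bernoulli NB", {
  withr::with_seed(9, {
    mm <- random_matrix(20, 20, 4, seed = 42, sigma = 0.2)
    model <- meth_nb(mm, weighting = "none")
    n <- 300
    obs <- tibble::tibble(
      probe_id = sample(model$feature_ids, n, replace = TRUE),
      x = rbinom(n, 1, 0.5), r = 1, eta = 0.05)
    attr(obs, "scale") <- 1
    got <- posterior(weighted_log_likelihood(obs, model, scale = FALSE),
                     model$log_priors)
    mu_adj <- adjust_centroids_for_noise(model$centroids,
                                         rep(0.05, ncol(model$centroids)))
    colnames(mu_adj) <- model$feature_ids
    want <- oracle_textbook_nb(obs$x, obs$probe_id, mu_adj,
                               model$log_priors)
    expect_equal(setNames(got$posterior, got$class)[names(want)], want,
                 tolerance = 1e-10)
  })
})

test_that("posterior normalizes, is shift-invariant and underflow-safe", {
  ll <- c(a = log(0.9), b = log(0.1))
  pri <- compute_priors(c("a", "b"), "uniform")
  p <- posterior(ll, pri)
  expect_equal(setNames(p$posterior, p$class)[c("a", "b")],
               c(a = 0.9, b = 0.1), tolerance = 1e-12)
  # equal evidence, equal priors
  p2 <- posterior(c(x = -5, y = -5), c(-log(2), -log(2)))
  expect_equal(p2$posterior, c(0.5, 0.5))
  withr::with_seed(3, {
    for (i in 1:10) {
      l <- rnorm(6) * 10
      pr <- log(prop.table(runif(6)))
      names(l) <- names(pr) <- letters[1:6]
      a <- posterior(l, pr)
      b <- posterior(l + 123.456, pr)
      expect_equal(a$posterior, b$posterior, tolerance = 1e-12)
      expect_equal(sum(a$posterior), 1, tolerance = 1e-9)
    }
  })
  deep <- posterior(c(a = -1e6, b = -1e6 + 2), c(-log(2), -log(2)))
  expect_equal(sum(deep$posterior), 1, tolerance = 1e-9)
  expect_gt(deep$posterior[deep$class == "b"], 0.8)
  expect_error(posterior(c(NaN, 1), c(0, 0)), "NaN")
})

test_that("the decision rule applies the threshold and lexicographic ties", {
  p <- posterior(c(a = log(0.61), b = log(0.39)),
                 c(-log(2), -log(2)))
  expect_true(classify(p, tau = 0.6)$high_certainty)
  p2 <- posterior(c(a = log(0.59), b = log(0.41)), c(-log(2), -log(2)))
  expect_false(classify(p2, tau = 0.6)$high_certainty)
  expect_true(classify(p2, tau = 0)$high_certainty) # tau 0 calls everything
  tie <- posterior(c(zeta = 0, alpha = 0), c(-log(2), -log(2)))
  expect_message(dec <- classify(tie), "lexicographically")
  expect_identical(dec$top_class, "alpha")
})

test_that("posteriors are invariant under feature-order permutation", {
  mm <- random_matrix(12, 15, 3, seed = 21, sigma = 0.2)
  model <- meth_nb(mm, k = 2)
  withr::with_seed(4, {
    obs <- tibble::tibble(probe_id = sample(model$feature_ids, 10),
                          x = rbinom(10, 1, 0.5), r = 1, eta = 0.05)
    perm <- obs[sample(nrow(obs)), ]
    a <- predict(model, obs, scale = FALSE)
    b <- predict(model, perm, scale = FALSE)
    expect_equal(a$posterior[[1]], b$posterior[[1]], tolerance = 1e-12)
  })
})

test_that("a posterior from observed features equals the a-priori restricted model", {
  mm <- random_matrix(16, 30, 4, seed = 31, sigma = 0.2)
  model <- meth_nb(mm, k = 2)
  withr::with_seed(5, {
    keep <- sample(model$feature_ids, 12)
    obs <- tibble::tibble(probe_id = keep, x = rbinom(12, 1, 0.5),
                          r = 1, eta = 0.05)
    full <- predict(model, obs, scale = FALSE)
    restricted <- model
    idx <- match(keep, model$feature_ids)
    for (f in c("centroids", "omega", "weights")) {
      restricted[[f]] <- model[[f]][, idx, drop = FALSE]
    }
    restricted$feature_ids <- keep
    sub <- predict(restricted, obs, scale = FALSE)
    expect_equal(full$posterior[[1]], sub$posterior[[1]], tolerance = 1e-12)
  })
})

test_that("models round-trip bit-identically through serialization", {
  mm <- random_matrix(12, 10, 3, seed = 51)
  model <- meth_nb(mm, k = 2)
  dir <- withr::local_tempdir()
  write_meth_nb(model, dir)
  back <- read_meth_nb(dir)
  expect_equal(back$centroids, model$centroids)
  expect_equal(back$weights, model$weights)
  expect_equal(back$log_priors, model$log_priors)
  expect_identical(back$classes, model$classes)
  # retraining on identical input reproduces the model exactly
  expect_equal(meth_nb(mm, k = 2)$weights, model$weights)
})

test_that("training scales near-linearly in features and quadratically in class size", {
  # operation-count proxies asserted as ratio bounds on scaled fixtures
  time_of <- function(n_per, p) {
    mm <- random_matrix(3 * n_per, p, 3, seed = 61, sigma = 0.1)
    system.time(meth_nb(mm, k = 2))[["elapsed"]]
  }
  t_base <- max(time_of(10, 200), 0.02)
  t_p4 <- time_of(10, 800)     # 4x features
  t_n3 <- time_of(30, 200)     # 3x samples per class
  expect_lt(t_p4 / t_base, 16)  # ~linear in p (generous 4x headroom)
  expect_lt(t_n3 / t_base, 27)  # at most quadratic in per-class n
})
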