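#' Simulate a binary single-molecule methylation profile
#'
#' Draws one binary methylation state per CpG by independent Bernoulli
#' sampling with success probabilities equal to the bulk methylation rates,
#' emulating what shallow single-molecule sequencing observes of a bulk
#' methylome.
#'
#' @param beta_row Named numeric vector of methylation rates in `[0, 1]`
#'   (names are probe IDs).
#' @param seed Integer seed; the draw is reproducible from it.
#' @param source_sample_id,replicate Optional provenance annotations.
#' @return Tibble with `probe_id` and binary `x`, plus attributes
#'   `source_sample_id`, `replicate` and `seed`.
#' @export
simulate_profile <- function(beta_row, seed = NULL,
                             source_sample_id = NA_character_,
                             replicate = NA_integer_) {
  stopifnot(is.numeric(beta_row), all(beta_row >= 0 & beta_row <= 1))
  ids <- names(beta_row) %||% paste0("cg", seq_along(beta_row))
  x <- with_seed(seed, rbinom(length(beta_row), 1L, beta_row))
  out <- tibble(probe_id = ids, x = as.numeric(x))
  attr(out, "source_sample_id") <- source_sample_id
  attr(out, "replicate") <- replicate
  attr(out, "seed") <- seed
  out
}

#' Subsample CpGs from a full synthetic profile
#'
#' Picks `n` distinct features uniformly without replacement and converts
#' them into a sample observation with singleton reads (read weight 1) and
#' uniform noise, the convention used when scoring synthetic profiles.
#'
#' @param profile A [simulate_profile()] tibble.
#' @param n Number of CpGs to keep (`n <= nrow(profile)`).
#' @param seed Integer seed.
#' @param uniform_noise Noise term applied to every call (default 0.05).
#' @return Observation tibble (`probe_id`, `x`, `r`, `eta`) as produced by
#'   [new_observation()].
#' @export
subsample_cpgs <- function(profile, n, seed = NULL, uniform_noise = 0.05) {
  if (n > nrow(profile)) {
    abort(paste0("Cannot subsample ", n, " CpGs from ", nrow(profile), "."))
  }
  idx <- with_seed(seed, sample.int(nrow(profile), n))
  obs <- tibble(probe_id = profile$probe_id[idx], x = profile$x[idx],
                r = 1, eta = uniform_noise)
  attr(obs, "scale") <- 300 / sum(obs$r)
  obs
}

#' Flip binary methylation calls at a fixed error rate
#'
#' Each call is flipped independently with the given probability,
#' emulating methylation-calling errors.
#'
#' @param obs Observation tibble with a binary `x` column.
#' @param rate Flip probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return The observation with flipped calls.
#' @export
inject_errors <- function(obs, rate, seed = NULL) {
  stopifnot(rate >= 0, rate < 0.5)
  if (rate == 0) return(obs)
  flip <- with_seed(seed, runif(nrow(obs)) < rate)
  obs$x[flip] <- 1 - obs$x[flip]
  obs
}

#' Sample whole reads until a target CpG coverage is reached
#'
#' Draws reads uniformly without replacement, keeping each read's calls
#' together (so read context and read weights are preserved), until the
#' number of distinct covered model CpGs reaches the target; the read that
#' crosses the target is kept in full. This post hoc emulates short,
#' low-coverage sequencing from a complete run.
#'
#' @param calls Calls tibble with `read_id` and `epic_id`.
#' @param target_n_cpgs Target number of distinct CpG sites (`>= 1`).
#' @param seed Integer seed.
#' @return The sampled calls; if the input covers fewer distinct CpGs than
#'   the target, everything is returned with a warning.
#' @export
sample_reads_to_target <- function(calls, target_n_cpgs, seed = NULL) {
  stopifnot(target_n_cpgs >= 1)
  total <- dplyr::n_distinct(calls$epic_id)
  if (total < target_n_cpgs) {
    warn(paste0("Only ", total, " distinct CpGs available; returning all."))
    return(calls)
  }
  reads <- unique(calls$read_id)
  order <- with_seed(seed, sample(reads))
  cpgs_per_read <- split(calls$epic_id, calls$read_id)[order]
  covered <- character()
  n_take <- 0L
  for (r in seq_along(order)) {
    covered <- union(covered, cpgs_per_read[[r]])
    n_take <- r
    if (length(covered) >= target_n_cpgs) break
  }
  dplyr::filter(calls, .data$read_id %in% order[seq_len(n_take)])
}

#' Draw per-read model-CpG counts (read context)
#'
#' Truncated geometric sampler for the number of model CpGs on a read,
#' used to give synthetic data a realistic mix of read densities so that
#' read weights differ from 1.
#'
#' @param n Number of reads.
#' @param mean Target mean count (default 1.5).
#' @param max Upper truncation (default 10).
#' @param seed Integer seed.
#' @return Integer vector of counts in `[1, max]`.
#' @export
simulate_read_context <- function(n, mean = 1.5, max = 10L, seed = NULL) {
  stopifnot(mean > 1)
  p <- 1 / mean
  with_seed(seed, {
    k <- stats::rgeom(n, p) + 1L
    pmin(k, as.integer(max))
  })
}

#' Generate a fully synthetic class-separated training matrix
#'
#' Builds a reference beta matrix with known structure: a baseline beta
#' vector shared across classes (Uniform(0.05, 0.95)), per class a random
#' set of informative features shifted by plus or minus `delta` (clipped to
#' `[0.02, 0.98]`), and per-sample truncated-Gaussian jitter creating
#' within-class variance. Everything downstream of the seed is
#' deterministic, so the fixture regenerates identically.
#'
#' @param m Number of classes.
#' @param p Number of features.
#' @param n_per_class Samples per class.
#' @param n_informative Informative (shifted) features per class.
#' @param delta Shift magnitude in `(0, 1)`; `delta = 0` gives identical
#'   classes (chance-level classification by construction).
#' @param sigma Within-class jitter standard deviation (default 0.05).
#' @param seed Integer seed.
#' @return A [meth_matrix()]; attribute `class_beta` holds the true
#'   per-class beta matrix (classes x features) and `informative` the
#'   per-class informative feature indices.
#' @export
generate_reference_fixture <- function(m = 10L, p = 5000L, n_per_class = 20L,
                                       n_informative = round(0.05 * p),
                                       delta = 0.4, sigma = 0.05,
                                       seed = 1L) {
  stopifnot(n_informative <= p, delta >= 0, delta < 1)
  with_seed(seed, {
    classes <- sprintf("class_%02d", seq_len(m))
    probes <- sprintf("cg%06d", seq_len(p))
    base <- runif(p, 0.05, 0.95)
    informative <- lapply(seq_len(m), function(j) sample.int(p, n_informative))
    class_beta <- matrix(rep(base, each = m), m, p,
                         dimnames = list(classes, probes))
    for (j in seq_len(m)) {
      idx <- informative[[j]]
      shift <- ifelse(runif(n_informative) < 0.5, delta, -delta)
      class_beta[j, idx] <- pmin(pmax(class_beta[j, idx] + shift, 0.02), 0.98)
    }
    n <- m * n_per_class
    labels <- rep(classes, each = n_per_class)
    vals <- matrix(0, n, p)
    for (s in seq_len(n)) {
      vals[s, ] <- pmin(pmax(class_beta[labels[s], ] + rnorm(p, 0, sigma),
                             0.02), 0.98)
    }
    out <- meth_matrix(vals, class_labels = labels,
                       sample_ids = sprintf("%s_s%02d", labels,
                                            rep(seq_len(n_per_class), m)),
                       feature_ids = probes)
    attr(out, "class_beta") <- class_beta
    attr(out, "informative") <- informative
    out
  })
}

#' Generate a probe manifest and matching reference sequence
#'
#' Lays out `n_probes` CpG sites at a fixed spacing on one synthetic
#' chromosome: a random background sequence with a `CG` dinucleotide
#' planted at every probe position. Used together with
#' [generate_synthetic_bam()] to test read ingestion end to end.
#'
#' @param n_probes Number of probes.
#' @param spacing Distance between consecutive CpG sites in bases
#'   (default 50).
#' @param chrom Chromosome name (default `"chrS"`).
#' @param probe_ids Optional probe IDs (default `cg000001 ...`).
#' @param seed Integer seed.
#' @return List with `manifest` (tibble `chrom`, `start`, `end`,
#'   `probe_id`; 0-based starts of the forward-strand C) and `reference`
#'   (single character string).
#' @export
generate_manifest <- function(n_probes, spacing = 50L, chrom = "chrS",
                              probe_ids = NULL, seed = 1L) {
  stopifnot(spacing >= 4L)
  probe_ids <- probe_ids %||% sprintf("cg%06d", seq_len(n_probes))
  starts0 <- 100L + (seq_len(n_probes) - 1L) * spacing
  len <- max(starts0) + 200L
  ref <- with_seed(seed,
                   sample(c("A", "C", "G", "T"), len, replace = TRUE))
  for (s in starts0) {
    ref[s + 1L] <- "C"  # 1-based position of the CpG cytosine
    ref[s + 2L] <- "G"
  }
  list(manifest = tibble(chrom = chrom, start = starts0, end = starts0 + 2L,
                         probe_id = probe_ids),
       reference = paste(ref, collapse = ""))
}

#' Write a synthetic MM/ML-tagged BAM encoding a binary profile
#'
#' Turns a binary methylation profile into aligned reads over the
#' synthetic reference from [generate_manifest()]: probes are grouped onto
#' reads (consecutive sites share a read), each read carries MM/ML tags
#' with methylation probabilities drawn near 0 or 1 consistent with the
#' binary values (a configurable fraction lands in the discard band), and
#' a fraction of reads is written as reverse-strand alignments to exercise
#' strand collapsing. Used to test the ingest path end to end.
#'
#' @param profile Tibble with `probe_id` and binary `x` for the probes to
#'   cover (subset of the manifest).
#' @param layout The list returned by [generate_manifest()].
#' @param bam_path Output path (without or with `.bam`).
#' @param features_per_read `NULL` for the truncated-geometric context
#'   sampler, or a fixed integer.
#' @param discard_frac Fraction of calls given probabilities inside the
#'   discard band (default 0).
#' @param frac_reverse Fraction of reads written as reverse-strand
#'   alignments (default 0.3).
#' @param mapq Mapping quality for every read (default 60).
#' @param flag_extra Extra FLAG bits OR-ed onto every read (e.g. 256 to
#'   write secondary alignments; default 0).
#' @param run_id Read-group / run identifier.
#' @param duration Run duration in seconds; read start times are uniform
#'   over `[0, duration]` (default 900).
#' @param seed Integer seed.
#' @return Path of the written BAM file.
#' @export
generate_synthetic_bam <- function(profile, layout, bam_path,
                                   features_per_read = NULL,
                                   discard_frac = 0, frac_reverse = 0.3,
                                   mapq = 60L, flag_extra = 0L,
                                   run_id = "run1", duration = 900,
                                   seed = 1L) {
  manifest <- layout$manifest
  ref <- layout$reference
  idx <- match(profile$probe_id, manifest$probe_id)
  if (anyNA(idx)) abort("Profile contains probes absent from the manifest.")
  ord <- order(idx)
  probe_idx <- idx[ord]
  x <- profile$x[ord]
  n <- length(probe_idx)
  with_seed(seed, {
    sizes <- if (is.null(features_per_read)) {
      simulate_read_context(n, seed = NULL)
    } else {
      rep(as.integer(features_per_read), ceiling(n / features_per_read))
    }
    groups <- rep(seq_along(sizes), times = sizes)[seq_len(n)]
    n_reads <- max(groups)
    start_times <- sort(round(runif(n_reads, 0, duration), 2))
    lines <- character(n_reads)
    for (g in seq_len(n_reads)) {
      in_read <- which(groups == g)
      sites0 <- manifest$start[probe_idx[in_read]]     # 0-based C positions
      r_start1 <- max(1L, min(sites0) + 1L - 10L)      # 1-based read start
      r_end1 <- max(sites0) + 2L + 10L
      seq_fwd <- substr(ref, r_start1, r_end1)
      len <- nchar(seq_fwd)
      c_off1 <- sites0 + 1L - r_start1 + 1L            # C position in read
      prob <- ifelse(x[in_read] == 1, runif(length(in_read), 0.85, 0.999),
                     runif(length(in_read), 0.001, 0.15))
      in_band <- runif(length(in_read)) < discard_frac
      prob[in_band] <- runif(sum(in_band), 0.35, 0.65)
      reverse <- runif(1) < frac_reverse
      if (reverse) {
        orig <- revcomp(seq_fwd)                        # sequencing orientation
        mod_pos_orig <- len - (c_off1 + 1L) + 1L        # C pairing the ref G
        flag <- bitwOr(16L, as.integer(flag_extra))
      } else {
        orig <- seq_fwd
        mod_pos_orig <- c_off1
        flag <- as.integer(flag_extra)
      }
      o <- order(mod_pos_orig)
      mod_pos_orig <- mod_pos_orig[o]
      prob_o <- prob[o]
      c_pos <- which(strsplit(orig, "", fixed = TRUE)[[1]] == "C")
      ordinal <- match(mod_pos_orig, c_pos)
      stopifnot(!anyNA(ordinal))
      deltas <- diff(c(0L, ordinal)) - 1L
      mm <- paste0("C+m?,", paste(deltas, collapse = ","), ";")
      ml <- paste0("ML:B:C,", paste(pmin(254L, round(prob_o * 255)),
                                    collapse = ","))
      lines[g] <- paste(
        sprintf("read_%04d", g), flag, manifest$chrom[1], r_start1, mapq,
        paste0(len, "M"), "*", 0, 0, seq_fwd,
        paste(rep("I", len), collapse = ""),
        paste0("MM:Z:", mm), ml, paste0("st:f:", start_times[g]),
        paste0("RG:Z:", run_id), sep = "\t")
    }
    sam_path <- sub("\\.bam$", "", bam_path)
    sam_file <- paste0(sam_path, ".sam")
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                paste0("@SQ\tSN:", manifest$chrom[1], "\tLN:", nchar(ref)),
                paste0("@RG\tID:", run_id))
    writeLines(c(header, lines), sam_file)
    out <- suppressMessages(
      Rsamtools::asBam(sam_file, destination = sam_path, overwrite = TRUE,
                       indexDestination = FALSE))
    unlink(sam_file)
    out
  })
}

#' Parameter-recovery experiment on a synthetic fixture
#'
#' Generates a class-separated reference fixture, trains a model on it and
#' classifies sparse Bernoulli-sampled profiles of freshly drawn,
#' out-of-sample methylomes (the class's true beta row plus new
#' within-class jitter), reporting top-1 accuracy. Out-of-sample draws
#' keep the experiment unbiased: replicating training samples themselves
#' would pull every profile toward its own class through the centroid and
#' inflate accuracy even for uninformative fixtures. Profiles are scored
#' with the synthetic-data conventions: constant read weights, uniform
#' noise 0.05, no posterior threshold.
#'
#' By default the experiment runs the unweighted Bernoulli core
#' (`weighting = "none"`): the fixture's features are conditionally
#' independent by construction, which is exactly the regime in which the
#' unweighted naive Bayes model is correct, whereas the ReliefF weighting
#' exists to compensate inter-feature correlation in real methylomes (and,
#' under the published `exp_neg` transform, suppresses the fixture's
#' discriminative features; see the methods vignette).
#'
#' @param m,p,n_per_class,n_informative,delta,sigma Passed to
#'   [generate_reference_fixture()].
#' @param n_cpgs Observed CpGs per classified profile (default 1000).
#' @param n_draws Number of classified profiles (default 1000).
#' @param weighting,weight_transform Model options (defaults `"none"` /
#'   `"exp_neg"`).
#' @param seed Master seed; all randomness is split from it.
#' @return One-row tibble: `accuracy`, `n_draws`, `n_cpgs`, `m`, `p`,
#'   `delta`, `weighting`.
#' @export
parameter_recovery <- function(m = 10L, p = 5000L, n_per_class = 20L,
                               n_informative = round(0.05 * p), delta = 0.4,
                               sigma = 0.05, n_cpgs = 1000L,
                               n_draws = 1000L,
                               weighting = c("none", "relieff"),
                               weight_transform = c("exp_neg", "exp_pos"),
                               seed = 1L) {
  weighting <- match.arg(weighting)
  weight_transform <- match.arg(weight_transform)
  fixture <- generate_reference_fixture(m = m, p = p,
                                        n_per_class = n_per_class,
                                        n_informative = n_informative,
                                        delta = delta, sigma = sigma,
                                        seed = seed)
  model <- meth_nb(fixture, weighting = weighting,
                   weight_transform = weight_transform)
  class_beta <- attr(fixture, "class_beta")
  seeds <- split_seed(seed, 3L * n_draws, stream = 1L)
  truth <- with_seed(split_seed(seed, 1L, stream = 2L),
                     sample(model$classes, n_draws, replace = TRUE))
  hits <- 0L
  for (d in seq_len(n_draws)) {
    beta <- with_seed(seeds[3L * d - 2L],
                      pmin(pmax(class_beta[truth[d], ] + rnorm(p, 0, sigma),
                                0.02), 0.98))
    prof <- simulate_profile(beta, seed = seeds[3L * d - 1L])
    obs <- subsample_cpgs(prof, n_cpgs, seed = seeds[3L * d])
    pred <- predict(model, obs, tau = 0, scale = FALSE)
    hits <- hits + (pred$top_class == truth[d])
  }
  tibble(accuracy = hits / n_draws, n_draws = n_draws, n_cpgs = n_cpgs,
         m = m, p = p, delta = delta, weighting = weighting,
         weight_transform = weight_transform)
}

#' Synthetic shallow-coverage evaluation study
#'
#' Implements the synthetic evaluation protocol: for every training sample,
#' draw binary replicate profiles from its beta row, subsample a grid of
#' CpG counts, optionally inject call errors, classify with constant read
#' weights and uniform noise 0.05 and no posterior threshold, and score
#' top-1 accuracy per condition.
#'
#' @param training The [meth_matrix()] the model was trained on.
#' @param model A [meth_nb()] model.
#' @param subset_sizes CpG counts to evaluate (default the standard grid
#'   1000 / 2500 / 5000 / 7500 / 10000 / 15000 / 20000, truncated to the
#'   feature count).
#' @param error_rates Call-flip rates to evaluate (default 0).
#' @param replicates_per_sample Binary replicates per training sample
#'   (default 100; use fewer for smoke-scale runs).
#' @param seed Master seed.
#' @return Tibble with one row per (subset size, error rate): `accuracy`
#'   over all predictions plus a `predictions` list-column with per-draw
#'   truth and top class.
#' @export
simulation_study <- function(training, model,
                             subset_sizes = c(1000, 2500, 5000, 7500,
                                              10000, 15000, 20000),
                             error_rates = 0,
                             replicates_per_sample = 100L, seed = 1L) {
  stopifnot(inherits(training, "meth_matrix"), inherits(model, "meth_nb"))
  p <- ncol(training$values)
  subset_sizes <- subset_sizes[subset_sizes <= p]
  n <- nrow(training$values)
  labels <- training$samples$class_label
  grid <- tidyr::expand_grid(subset_size = subset_sizes,
                             error_rate = error_rates)
  res <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    sz <- grid$subset_size[g]
    er <- grid$error_rate[g]
    seeds <- split_seed(seed, 3L * n * replicates_per_sample,
                        stream = g)
    preds <- character(n * replicates_per_sample)
    truths <- character(n * replicates_per_sample)
    k <- 0L
    for (s in seq_len(n)) {
      for (r in seq_len(replicates_per_sample)) {
        k <- k + 1L
        prof <- simulate_profile(training$values[s, ],
                                 seed = seeds[3L * k - 2L])
        obs <- subsample_cpgs(prof, sz, seed = seeds[3L * k - 1L])
        if (er > 0) obs <- inject_errors(obs, er, seed = seeds[3L * k])
        pr <- predict(model, obs, tau = 0, scale = FALSE)
        preds[k] <- pr$top_class
        truths[k] <- labels[s]
      }
    }
    res[[g]] <- tibble(subset_size = sz, error_rate = er,
                       accuracy = mean(preds == truths),
                       n_predictions = k,
                       predictions = list(tibble(truth = truths,
                                                 prediction = preds)))
  }
  dplyr::bind_rows(res)
}
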