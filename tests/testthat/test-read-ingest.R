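layout_for_tests <- function(n = 40, seed = 8) {
  generate_manifest(n_probes = n, spacing = 60, seed = seed)
}

test_that("a synthetic BAM round-trips binary calls through extraction", {
  layout <- layout_for_tests(50)
  profile <- withr::with_seed(1, tibble::tibble(
    probe_id = layout$manifest$probe_id,
    x = rbinom(50, 1, 0.5)))
  bam <- generate_synthetic_bam(profile, layout,
                                file.path(withr::local_tempdir(), "t"),
                                features_per_read = 1, frac_reverse = 0.4,
                                seed = 2)
  calls <- extract_calls(bam, layout$manifest)
  expect_equal(nrow(calls), 50)
  expect_setequal(calls$epic_id, profile$probe_id)
  bin <- binarize_calls(calls)
  expect_equal(
    bin$binary_methylation[match(profile$probe_id, bin$epic_id)],
    profile$x)
  # one call per (read, probe); singleton reads here
  expect_equal(anyDuplicated(paste(bin$read_id, bin$epic_id)), 0L)
})

test_that("multi-CpG reads survive the round trip with correct read context", {
  layout <- layout_for_tests(60)
  profile <- withr::with_seed(3, tibble::tibble(
    probe_id = layout$manifest$probe_id, x = rbinom(60, 1, 0.4)))
  bam <- generate_synthetic_bam(profile, layout,
                                file.path(withr::local_tempdir(), "m"),
                                features_per_read = 5, frac_reverse = 0.5,
                                seed = 4)
  calls <- extract_calls(bam, layout$manifest)
  expect_equal(nrow(calls), 60)
  expect_true(all(calls$scores_per_read == 5))
  ready <- filter_and_weight_reads(binarize_calls(calls))
  expect_true(all(ready$read_weight == 1 / ready$features_on_read))
  bin <- binarize_calls(calls)
  expect_equal(bin$binary_methylation[match(profile$probe_id, bin$epic_id)],
               profile$x)
})

test_that("ML byte values decode as ml/255 on a constructed record", {
  # single forward read over one probe with a hand-written ML byte of 230
  layout <- layout_for_tests(3)
  dir <- withr::local_tempdir()
  s0 <- layout$manifest$start[1]
  seq <- substr(layout$reference, s0 - 9, s0 + 12) # C at offset 11 (1-based)
  c_in_seq <- which(strsplit(seq, "")[[1]] == "C")
  ordinal <- match(11L, c_in_seq)
  sam <- file.path(dir, "one.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:chrS\tLN:", nchar(layout$reference)),
    paste("r1", 0, "chrS", s0 - 9, 60, paste0(nchar(seq), "M"), "*", 0, 0,
          seq, paste(rep("I", nchar(seq)), collapse = ""),
          paste0("MM:Z:C+m?,", ordinal - 1, ";"), "ML:B:C,230",
          sep = "\t")), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "one"),
                          indexDestination = FALSE)
  calls <- extract_calls(bam, layout$manifest)
  expect_equal(nrow(calls), 1)
  expect_identical(calls$epic_id, layout$manifest$probe_id[1])
  expect_equal(calls$methylation, 230 / 255, tolerance = 1e-12)
  expect_equal(round(calls$methylation, 3), 0.902)
})

test_that("low-MAPQ and secondary alignments yield zero calls", {
  layout <- layout_for_tests(20)
  profile <- tibble::tibble(probe_id = layout$manifest$probe_id,
                            x = rep(1, 20))
  dir <- withr::local_tempdir()
  low <- generate_synthetic_bam(profile, layout, file.path(dir, "low"),
                                features_per_read = 1, mapq = 5, seed = 5)
  expect_equal(nrow(extract_calls(low, layout$manifest)), 0)
  sec <- generate_synthetic_bam(profile, layout, file.path(dir, "sec"),
                                features_per_read = 1, flag_extra = 256,
                                seed = 5)
  expect_equal(nrow(extract_calls(sec, layout$manifest)), 0)
  cnt <- attr(extract_calls(sec, layout$manifest), "counters")
  expect_equal(unname(cnt["not_primary"]), unname(cnt["seen"]))
})

test_that("binarization applies the published cutpoints and is idempotent", {
  calls <- make_calls(paste0("cg", 1:7),
                      m = c(0.15, 0.85, 0.5, 0.2, 0.8, 0.25, 0.75),
                      read = paste0("r", 1:7))
  bin <- binarize_calls(calls)
  expect_equal(setNames(bin$binary_methylation, bin$epic_id),
               c(cg1 = 0, cg2 = 1, cg4 = 0, cg5 = 1)) # band discarded
  expect_identical(binarize_calls(bin), bin)
  # R10 mode widens the discard band to (0.3, 0.7), inclusive cutpoints
  r10 <- binarize_calls(calls, ingest_config(mode = "r10"))
  expect_setequal(r10$epic_id, c("cg1", "cg2", "cg4", "cg5", "cg6", "cg7"))
  expect_equal(r10$binary_methylation[r10$epic_id == "cg6"], 0)
  expect_equal(r10$binary_methylation[r10$epic_id == "cg7"], 1)
})

test_that("noise terms follow eta = max(floor, 0.5 - |m - 0.5|)", {
  expect_equal(compute_noise(0.9), 0.1)
  expect_equal(compute_noise(0.98), 0.05)
  expect_equal(compute_noise(0.5), 0.5)
  expect_equal(compute_noise(c(0, 1)), c(0.05, 0.05))
})

test_that("dense reads are excluded and weights are reciprocal feature counts", {
  calls <- make_calls(
    probe = paste0("cg", 1:15),
    m = rep(0.9, 15),
    read = c(rep("dense", 11), rep("r2", 4)))
  ready <- filter_and_weight_reads(binarize_calls(calls))
  expect_false(any(ready$read_id == "dense")) # 11 features: all removed
  expect_equal(ready$read_weight, rep(0.25, 4))
  # sum over calls of r equals the number of retained reads
  expect_equal(sum(ready$read_weight), 1)
  expect_error(
    filter_and_weight_reads(
      binarize_calls(make_calls(paste0("cg", 1:11), rep(0.9, 11),
                                rep("dense", 11)))),
    "no usable reads")
})

test_that("300 singleton reads give unit base-count scale", {
  calls <- make_calls(paste0("cg", 1:300), rep(0.9, 300),
                      paste0("r", 1:300))
  ready <- filter_and_weight_reads(binarize_calls(calls))
  obs <- new_observation(ready)
  expect_equal(sum(obs$r), 300)
  expect_equal(attr(obs, "scale"), 1)
})

test_that("time-window filtering is monotone and supports the standard grid", {
  calls <- make_calls(paste0("cg", 1:2), c(0.9, 0.1), c("r1", "r2"),
                      t = c(200, 1000))
  expect_identical(filter_time_window(calls, 900)$read_id, "r1")
  expect_identical(filter_time_window(calls, Inf), calls)
  withr::with_seed(6, {
    times <- runif(100, 0, 7200)
    cc <- make_calls(paste0("cg", 1:100), runif(100), paste0("r", 1:100),
                     t = times)
    grid <- sort(runif(5, 0, 7200))
    sizes <- vapply(grid, function(t) nrow(filter_time_window(cc, t)),
                    numeric(1))
    expect_true(!is.unsorted(sizes))
  })
})

test_that("cfDNA length filtering uses inclusive 50-700 bounds", {
  calls <- make_calls(paste0("cg", 1:4), rep(0.9, 4), paste0("r", 1:4),
                      len = c(167L, 40L, 700L, 701L))
  kept <- filter_cfdna_lengths(calls)
  expect_setequal(kept$read_length, c(167L, 700L))
})

test_that("chunked processing equals one-shot processing", {
  withr::with_seed(7, {
    calls <- make_calls(paste0("cg", 1:30), runif(30),
                        rep(paste0("r", 1:10), each = 3))
  })
  one <- filter_and_weight_reads(binarize_calls(calls))
  reads <- unique(calls$read_id)
  chunks <- split(seq_along(reads), rep(1:2, length.out = length(reads)))
  parts <- lapply(chunks, function(ix) {
    filter_and_weight_reads(
      binarize_calls(calls[calls$read_id %in% reads[ix], ]))
  })
  merged <- dplyr::arrange(dplyr::bind_rows(parts), epic_id)
  expect_equal(merged, dplyr::arrange(one, epic_id))
})

test_that("call tables round-trip through the Feather contract", {
  calls <- make_calls(paste0("cg", 1:5), runif(5), paste0("r", 1:5),
                      t = c(5, 3, 1, 4, 2))
  path <- withr::local_tempfile(fileext = ".feather")
  write_calls_feather(calls, path)
  back <- arrow::read_feather(path)
  expect_identical(names(back),
                   c("epic_id", "methylation", "scores_per_read",
                     "binary_methylation", "read_id", "start_time",
                     "run_id", "QS", "read_length", "map_qs"))
  expect_true(!is.unsorted(back$start_time))
})
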