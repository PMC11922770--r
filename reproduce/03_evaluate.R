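#!/usr/bin/env Rscript
# Replicate protocol: Bernoulli replicates per sample, CpG subsampling,
# constant read weights, uniform noise 0.05, no posterior threshold,
# tiered scoring. --replicates 100 for the full run, 5 for the smoke run.

suppressPackageStartupMessages(library(methylnb))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(f, d = NULL) {
  i <- match(f, args); if (is.na(i)) d else args[i + 1]
}
work <- arg("--work", "work")
model <- read_meth_nb(arg("--model", file.path(work, "model")))
replicates <- as.integer(arg("--replicates", "100"))
seed <- as.integer(arg("--seed", "1"))
training <- read_meth_matrix(file.path(work, "training.tsv"),
                             file.path(work, "annotation.tsv"))

study <- simulation_study(training, model,
                          subset_sizes = c(1000, 2500, 5000, 7500, 10000,
                                           15000, 20000),
                          error_rates = c(0, 0.01, 0.025, 0.05, 0.1),
                          replicates_per_sample = replicates, seed = seed)
readr::write_csv(dplyr::select(study, -predictions),
                 file.path(work, "synthetic_accuracy.csv"))

hier_file <- file.path(work, "hierarchy.tsv")
if (file.exists(hier_file)) {
  hier <- read_class_hierarchy(hier_file)
  tiers <- lapply(c("fine", "mid", "family"), function(tier) {
    do.call(rbind, lapply(seq_len(nrow(study)), function(i) {
      sc <- score_predictions(study$predictions[[i]], hier, tier)
      data.frame(subset_size = study$subset_size[i],
                 error_rate = study$error_rate[i], tier = tier,
                 overall_accuracy = sc$overall_accuracy,
                 median_class_accuracy = sc$median_class_accuracy)
    }))
  })
  readr::write_csv(do.call(rbind, tiers),
                   file.path(work, "tiered_accuracy.csv"))
}
cat("evaluation tables written under", work, "\n")
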