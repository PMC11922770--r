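#!/usr/bin/env Rscript
suppressPackageStartupMessages(library(methylnb))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(f, d = NULL) {
  i <- match(f, args); if (is.na(i)) d else args[i + 1]
}
work <- arg("--work", "work")
model_dir <- arg("--model", file.path(work, "model"))
run_train(file.path(work, "training.tsv"),
          file.path(work, "annotation.tsv"),
          model_dir, k = 5)
cat("model written to", model_dir, "\n")
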