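#!/usr/bin/env Rscript
# Merge the downloaded beta matrices into one training matrix.
# Expects per-cohort matrix + annotation TSVs and the four probe exclusion
# lists (one probe ID per line) under --data-dir.

suppressPackageStartupMessages(library(methylnb))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(f, d = NULL) {
  i <- match(f, args); if (is.na(i)) d else args[i + 1]
}
data_dir <- arg("--data-dir", "data")
out <- arg("--out", "work")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

excl <- read_probe_exclusions(
  sex_chromosome = file.path(data_dir, "probes_xy.txt"),
  snp_proximal = file.path(data_dir, "probes_snp.txt"),
  multimapping = file.path(data_dir, "probes_multimap.txt"),
  non_shared_platform = file.path(data_dir, "probes_not_on_epic.txt"))

cohorts <- c("cns", "metastasis", "sarcoma")
mats <- lapply(cohorts, function(ch) {
  mfile <- file.path(data_dir, paste0(ch, "_beta.tsv"))
  if (!file.exists(mfile)) return(NULL)
  m <- read_meth_matrix(mfile, file.path(data_dir, paste0(ch, "_ann.tsv")))
  correct_batch(filter_probes(m, excl))
})
mats <- Filter(Negate(is.null), mats)
merged <- assemble_training(mats)
cat("merged:", nrow(merged$values), "samples x", ncol(merged$values),
    "probes,", length(unique(merged$samples$class_label)), "classes\n")
write_meth_matrix(merged, file.path(out, "training.tsv"),
                  file.path(out, "annotation.tsv"))
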