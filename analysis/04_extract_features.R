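#!/usr/bin/env Rscript
# Stage 4: the 500-feature representation for the positives and the
# cross-dataset selection of negatives. Datasets larger than the positive
# set are undersampled to it before extraction (the split protocol would
# discard the surplus anyway), and the leakage filter removes negatives
# whose feature vector exactly duplicates a positive's.
source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

dir.create(res_path("features"), showWarnings = FALSE)
write_schema(res_path("features", "schema.json"))

positives <- load_dataset("positives")
n_pos <- nrow(positives$records)
pos_X <- extract_features_dataset(positives)
write.table(pos_X, res_path("features", "positives.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("positives:", n_pos, "x", ncol(pos_X), "\n")

set.seed(ANALYSIS_SEED + 200)
for (name in CROSS_DATASETS) {
  d <- load_dataset(name)
  if (nrow(d$records) > n_pos)
    d$records <- d$records[sort(sample.int(nrow(d$records), n_pos)), ]
  X <- extract_features_dataset(d)
  X <- leakage_filter(X, pos_X)
  write.table(X, res_path("features", paste0(name, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("%-24s %6d rows (%d leaked removed)\n", name, nrow(X),
              attr(X, "n_removed")))
}
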