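#!/usr/bin/env Rscript
# Stage 7: can one-class models replace negative data? One-class SVM and
# isolation forest (trained on positives only) against their binary
# counterparts (SVM, random forest) on identical test sets.
source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

pos_X <- load_features("positives")
ds <- "tarbase_microarray"
neg_X <- load_features(ds)
plan <- make_split_plan(nrow(pos_X), setNames(nrow(neg_X), ds),
                        repeats = 20, base_seed = ANALYSIS_SEED)

res <- one_class_comparison(pos_X, neg_X, plan, ds)
cat("one-class vs binary on", ds, "(mean over 20 repeats):\n")
print(res$summary, digits = 3)
write.table(res$summary, res_path("one_class.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$per_repeat, res_path("one_class_per_repeat.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
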