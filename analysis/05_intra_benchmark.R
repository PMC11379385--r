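#!/usr/bin/env Rscript
# Stage 5: intra-dataset classification -- one gradient-boosted classifier
# per negative dataset, trained and tested within that dataset over the
# 20-repeat shared-positive split plan.
source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

pos_X <- load_features("positives")
feats <- lapply(setNames(nm = CROSS_DATASETS), load_features)
plan <- make_split_plan(nrow(pos_X), vapply(feats, nrow, integer(1)),
                        repeats = 20, base_seed = ANALYSIS_SEED)

rows <- lapply(CROSS_DATASETS, function(ds) {
  r <- evaluate_pair(ds, ds, pos_X, feats, plan)
  cat(sprintf("%-24s ACC %.3f+-%.3f TPR %.3f TNR %.3f F1 %.3f\n", ds,
              r$mean["acc"], r$sd["acc"], r$mean["tpr"], r$mean["tnr"],
              r$mean["f1"]))
  data.frame(dataset = ds, t(r$mean), t(setNames(r$sd,
                                                 paste0(names(r$sd), "_sd"))))
})
intra <- do.call(rbind, rows)
write.table(intra, res_path("intra_dataset.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
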