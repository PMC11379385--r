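#!/usr/bin/env Rscript
# Stage 8: model-comparison statistics -- SHAP profile divergence between
# per-dataset classifiers, the two-negative-class separability probe, and
# the balanced-mixture difficulty check.
source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

pos_X <- load_features("positives")
feats <- lapply(setNames(nm = CROSS_DATASETS), load_features)
plan <- make_split_plan(nrow(pos_X), vapply(feats, nrow, integer(1)),
                        repeats = 20, base_seed = ANALYSIS_SEED)

# one classifier per dataset (first repeat's training split)
models <- lapply(setNames(nm = CROSS_DATASETS), function(ds) {
  tr <- mtinegbench:::split_xy(pos_X, feats[[ds]], plan$repeats[[1]],
                               ds, "train")
  mtinegbench:::fit_xgb(tr$X, tr$y, list(max_depth = 6, eta = 0.1,
                                         nrounds = 150))
})

pairs <- t(combn(CROSS_DATASETS, 2))
n_cmp <- nrow(pairs)
shap <- matrix(0, length(CROSS_DATASETS), length(CROSS_DATASETS),
               dimnames = list(CROSS_DATASETS, CROSS_DATASETS))
for (i in seq_len(n_cmp)) {
  a <- pairs[i, 1]; b <- pairs[i, 2]
  s <- shap_compare(models[[a]], rbind(pos_X, feats[[a]]),
                    models[[b]], rbind(pos_X, feats[[b]]),
                    k = 100, n_comparisons = n_cmp)
  shap[a, b] <- shap[b, a] <- s$neg_log10
}
cat("-log10 Bonferroni-corrected Wilcoxon p over top-100 SHAP unions\n")
cat("(0 = not significant at 0.05):\n")
print(round(shap, 1))
write.table(shap, res_path("shap_divergence.tsv"), sep = "\t", quote = FALSE)

# two-negative-class classification over all pairs
tn <- data.frame()
for (i in seq_len(n_cmp)) {
  a <- pairs[i, 1]; b <- pairs[i, 2]
  m <- two_negative_eval(feats[[a]], feats[[b]], seed = ANALYSIS_SEED + i)
  tn <- rbind(tn, data.frame(A = a, B = b, t(m)))
}
cat("\ntwo-negative-class ACC range:", round(min(tn$acc), 2), "-",
    round(max(tn$acc), 2), "\n")
write.table(tn, res_path("two_negative.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

# balanced-mixture difficulty: intra ACC of the mixture cannot beat the best
# of its constituents
mix <- load_dataset("mixture")
keep <- mix$records$method %in% CROSS_DATASETS
mix$records <- mix$records[keep, ]
mix_X <- leakage_filter(extract_features_dataset(mix), pos_X)
plan_mix <- make_split_plan(nrow(pos_X), c(mixture = nrow(mix_X)),
                            repeats = 20, base_seed = ANALYSIS_SEED)
r <- evaluate_pair("mixture", "mixture", pos_X, list(mixture = mix_X),
                   plan_mix)
intra <- read.delim(res_path("intra_dataset.tsv"))
cat(sprintf("\nmixture intra ACC %.3f vs best constituent %.3f\n",
            r$mean["acc"], max(intra$acc)))
jsonlite::write_json(list(mixture_acc = unname(r$mean["acc"]),
                          best_constituent_acc = max(intra$acc)),
                     res_path("mixture.json"), auto_unbox = TRUE, digits = NA)
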