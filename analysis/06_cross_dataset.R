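#!/usr/bin/env Rscript
# Stage 6: cross-dataset classification -- classifiers trained per dataset
# are evaluated on every dataset's test split -- plus the dataset
# characteristics that explain the matrix: six-class duplex distributions,
# miRNA concentration (CDF-90) and pairwise KL divergences of miRNA usage.
source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

pos_X <- load_features("positives")
feats <- lapply(setNames(nm = CROSS_DATASETS), load_features)
plan <- make_split_plan(nrow(pos_X), vapply(feats, nrow, integer(1)),
                        repeats = 20, base_seed = ANALYSIS_SEED)

cm <- cross_matrix(pos_X, feats, plan)
write.table(cm$mean, res_path("cross_matrix_mean.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cm$sd, res_path("cross_matrix_sd.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
acc <- matrix(NA, length(CROSS_DATASETS), length(CROSS_DATASETS),
              dimnames = list(train = CROSS_DATASETS, test = CROSS_DATASETS))
for (i in seq_len(nrow(cm$mean)))
  acc[cm$mean$train[i], cm$mean$test[i]] <- cm$mean$acc[i]
cat("cross-dataset mean ACC (rows train, columns test):\n")
print(round(acc, 3))

# dataset characteristics
chars <- lapply(setNames(nm = c("positives", CROSS_DATASETS)), function(nm) {
  d <- load_dataset(nm)
  cdf <- mirna_cdf90(d$records$mirna_seq)
  list(classes = duplex_class_distribution(d),
       cdf90_fraction = cdf$fraction, n_distinct = cdf$n_distinct,
       seqs = d$records$mirna_seq)
})
cat("\nCDF-90 fraction of distinct miRNAs carrying >90% of interactions:\n")
for (nm in names(chars))
  cat(sprintf("  %-24s %.2f (%d distinct)\n", nm, chars[[nm]]$cdf90_fraction,
              chars[[nm]]$n_distinct))

kl <- matrix(NA, length(chars), length(chars),
             dimnames = list(target = names(chars), source = names(chars)))
for (p in names(chars)) for (q in names(chars)) {
  d <- mirna_distributions(chars[[p]]$seqs, chars[[q]]$seqs)
  kl[p, q] <- kl_divergence(d$p, d$q)
}
cat("\nKL divergence of miRNA distributions, D(target || source):\n")
print(round(kl, 2))
write.table(kl, res_path("kl_divergence.tsv"), sep = "\t", quote = FALSE)

classes <- do.call(rbind, lapply(names(chars), function(nm)
  data.frame(dataset = nm, t(as.vector(chars[[nm]]$classes)))))
names(classes)[2:7] <- paste(rep(c("canonical", "non_canonical"), 3),
                             rep(c("low", "medium", "high"), each = 2),
                             sep = "_")
write.table(classes, res_path("duplex_classes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
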