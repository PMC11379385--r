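#!/usr/bin/env Rscript
# Stage 2: compute duplexes for the planted positives, keep valid
# (canonical / non-canonical) interactions, and summarize the six duplex
# classes -- the positive dataset every later stage shares.
source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

world <- analysis_world()
positives <- process_positives(world$positives)
write_interactions(positives, res_path("positives.tsv"))

cat("raw records:", positives$summary$n_input,
    " invalid dropped:", positives$summary$n_invalid,
    " kept:", nrow(positives$records), "\n")

truth <- world$truth[positives$records$record_id]
agree <- mean(truth == positives$records$seed_type)
cat("seed-type agreement with planted truth:", round(agree, 3), "\n")

d <- duplex_class_distribution(positives)
cat("duplex class distribution (rows sum to 1 overall):\n")
print(round(d, 3))
write.table(as.data.frame.matrix(d), res_path("positives_duplex_classes.tsv"),
            sep = "\t", quote = FALSE)
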