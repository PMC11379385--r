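#!/usr/bin/env Rscript
# Stage 1: generate the synthetic world (miRNA catalog, 3'UTRs with planted
# sites, CLIP lists, TarBase-style table) and export its artifacts.
source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

world <- analysis_world()
write_world(world, res_path("world"))

cat("world seed:", world$seed, "\n")
cat("miRNAs:", nrow(world$mirnas), " UTRs:", nrow(world$utrs), "\n")
cat("planted positives:", nrow(world$positives),
    "(skipped:", length(world$skipped), ")\n")
cat("truth mix:", paste(names(table(world$truth)), table(world$truth),
                        collapse = ", "), "\n")
cat("CLIP lists:", nrow(world$clip_mirnas), "miRNAs x",
    nrow(world$clip_mrnas), "mRNA fragments\n")
cat("TarBase rows:", nrow(world$tarbase_rows), "\n")
cat("artifacts written to", res_path("world"), "\n")
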