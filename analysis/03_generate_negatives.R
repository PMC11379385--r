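#!/usr/bin/env Rscript
# Stage 3: run all six negative-generation methods (with their sub-cases)
# against the shared positives, plus the balanced mixture, and export every
# dataset with its generation summary.
source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

world <- analysis_world()
positives <- process_positives(world$positives)
fpd <- build_fpd(positives)
seed <- ANALYSIS_SEED

datasets <- list()
add <- function(d) { datasets[[d$name]] <<- d }

# Method 1: mock miRNA
add(gen_mock_mirna(positives, world$mirnas, seed = seed + 101))

# Method 2: mock mRNA (three region modes x mono/di shuffling)
for (mode in c("full_mrna", "fragment", "fragment_and_mirna"))
  for (k in 1:2)
    add(gen_mock_mrna(positives, mode, k = k, catalog = world$mirnas,
                      seed = seed + 110 + 10 * k + match(mode, c(
                        "full_mrna", "fragment", "fragment_and_mirna"))))

# Method 3: non-positive sites on CLASH, two selection rules (plus the two
# bias-countering rules examined in the selection-rule comparison)
for (rule in c("min_mfe", "random", "median_mfe", "p20_random"))
  add(gen_nps_clash(positives, rule, seed = seed + 150))

# Method 4: TarBase-style negatives, three variants
add(gen_tarbase_negatives(world$tarbase_rows, fpd, "all",
                          world$mirnas, world$utrs))
add(gen_tarbase_negatives(world$tarbase_rows, fpd, "tissue:liver",
                          world$mirnas, world$utrs))
add(gen_tarbase_negatives(world$tarbase_rows, fpd, "microarray",
                          world$mirnas, world$utrs))

# Method 5: CLIP non CLASH
add(gen_clip_non_clash(world$clip_mirnas, world$clip_mrnas, fpd))

# Method 6: non-positive sites on CLIP, two selection rules
add(gen_nps_clip(world$clip_mirnas, world$clip_mrnas, fpd, "min_mfe",
                 seed = seed + 160))
add(gen_nps_clip(world$clip_mirnas, world$clip_mrnas, fpd, "random",
                 seed = seed + 161))

# balanced mixture over every generated dataset
add(combine_negatives(datasets, 6 * (nrow(positives$records) %/% 6),
                      seed = seed + 170))

summaries <- list()
for (d in datasets) {
  write_interactions(d, res_path(paste0(d$name, ".tsv")))
  summaries[[d$name]] <- c(list(n_records = nrow(d$records)), d$summary)
  cat(sprintf("%-28s %6d records\n", d$name, nrow(d$records)))
}
jsonlite::write_json(summaries, res_path("negatives_summary.json"),
                     auto_unbox = TRUE, pretty = TRUE)
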