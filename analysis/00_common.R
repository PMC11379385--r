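# shared setup for the analysis drivers: seed, world parameters, result
# paths. Every driver regenerates deterministic inputs from the seed rather
# than deserializing binary state, so each script can be re-run on its own.
suppressMessages(library(mtinegbench))

ANALYSIS_SEED <- {
  a <- commandArgs(trailingOnly = TRUE)
  if (length(a) >= 1) as.integer(a[1]) else 1L
}
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

res_path <- function(...) file.path(RESULTS_DIR, ...)

# the negative datasets carried into the cross-dataset stage (the site-level
# and full-mRNA-level representatives of each method family)
CROSS_DATASETS <- c("mock_mirna", "mock_di_mrna", "mock_di_fragment",
                    "nps_clash_random", "tarbase_microarray",
                    "clip_non_clash", "nps_clip_random")

analysis_world <- function(seed = ANALYSIS_SEED) gen_world(seed = seed)

load_dataset <- function(name) {
  read_interactions(res_path(paste0(name, ".tsv")), name = name)
}

load_features <- function(name) {
  df <- read.delim(res_path("features", paste0(name, ".tsv")),
                   check.names = FALSE)
  as.matrix(df)
}
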