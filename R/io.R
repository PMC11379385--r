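# Readers and writers: interaction tables as TSV (fixed header), catalogs
# as FASTA, run manifests as JSON. Coordinates are 0-based half-open
# throughout.

REQUIRED_TSV_COLUMNS <- c("mirna_name", "mirna_seq", "gene_id",
                          "fragment_seq", "fragment_start", "fragment_end",
                          "full_len", "duplex_pairs", "mfe_kcal_mol",
                          "seed_type", "density_class", "label", "method")

#' Write an interaction dataset as TSV
#'
#' @param dataset An `mti_dataset`.
#' @param path Output file.
#' @export
write_interactions <- function(dataset, path) {
  write.table(dataset$records, path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an interaction dataset from TSV
#'
#' @param path TSV file with the fixed header (extra columns are kept).
#' @param name Dataset name (default: file name without extension).
#' @return An `mti_dataset`.
#' @export
read_interactions <- function(path, name = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, quote = "",
                   fileEncoding = "UTF-8")
  missing_cols <- setdiff(REQUIRED_TSV_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("fragment_start", "fragment_end", "full_len")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0)
      stop("malformed coordinate in ", path, " column ", col,
           " at data line ", bad[1], call. = FALSE)
    df[[col]] <- v
  }
  make_dataset(name %||% sub("\\.[^.]*$", "", basename(path)), df)
}

#' Write a sequence catalog as FASTA
#'
#' @param catalog Data frame with a `sequence` column and a `name` or
#'   `gene_id` id column.
#' @param path Output file.
#' @export
write_fasta_catalog <- function(catalog, path) {
  ids <- catalog$name %||% catalog$gene_id
  set <- Biostrings::RNAStringSet(setNames(catalog$sequence, ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a run manifest as JSON
#'
#' @param path Output file.
#' @param params Parameter list.
#' @param seed Integer seed.
#' @param extra Optional extra entries.
#' @export
write_manifest <- function(path, params, seed, extra = list()) {
  jsonlite::write_json(c(list(package = "mtinegbench",
                              version = as.character(
                                utils::packageVersion("mtinegbench")),
                              seed = seed, params = params), extra),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write the artifacts of a synthetic world
#'
#' Catalogs as FASTA, interaction/CLIP/TarBase tables as TSV, and a JSON
#' manifest with the generating parameters and seed.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_catalog(world$mirnas, file.path(dir, "mirnas.fa"))
  write_fasta_catalog(world$utrs, file.path(dir, "utrs.fa"))
  wt <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE,
                                    fileEncoding = "UTF-8")
  wt(world$positives, "positives_raw.tsv")
  wt(world$clip_mirnas, "clip_mirnas.tsv")
  wt(world$clip_mrnas, "clip_mrnas.tsv")
  wt(world$tarbase_rows, "tarbase.tsv")
  wt(data.frame(record_id = names(world$truth), truth = world$truth),
     "truth.tsv")
  write_manifest(file.path(dir, "manifest.json"), world$params, world$seed)
  invisible(dir)
}
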