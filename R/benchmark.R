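# End-to-end drivers: the desk-scale benchmark (world -> positives -> mock
# negatives -> features -> splits -> intra/cross ML -> one-class), the
# shuffle-conservation audit and the mask/FPD safety audit. These are the
# entry points the analysis scripts, the test suite and the acceptance
# script share.

#' Exact k-mer conservation audit of the shuffles
#'
#' Draws random sequences and verifies that the k = 1 shuffle preserves
#' mononucleotide counts exactly and the k = 2 shuffle preserves
#' dinucleotide counts exactly.
#'
#' @param n Number of random sequences.
#' @param len_range Length range.
#' @param seed RNG seed.
#' @return List with `n` and the violation counts `k1_violations`,
#'   `k2_violations`.
#' @export
shuffle_conservation_check <- function(n = 1000L, len_range = c(20L, 200L),
                                       seed = 1L) {
  with_seed(seed, {
    k1 <- k2 <- 0L
    for (i in seq_len(n)) {
      s <- random_rna(sample(seq(len_range[1], len_range[2]), 1))
      s1 <- shuffle_kmer(s, 1L)
      if (!identical(sort(chars(s)), sort(chars(s1)))) k1 <- k1 + 1L
      s2 <- shuffle_kmer(s, 2L)
      di <- function(x) {
        v <- chars(x)
        sort(paste0(v[-length(v)], v[-1]))
      }
      if (!identical(di(s), di(s2))) k2 <- k2 + 1L
    }
    list(n = n, k1_violations = k1, k2_violations = k2)
  })
}

# overlap count between emitted site spans and masked spans
count_span_overlaps <- function(sites, masks, extend = 10L) {
  # sites: data frame with gene/key, start, end; masks: list key -> matrix
  n <- 0L
  for (i in seq_len(nrow(sites))) {
    m <- masks[[sites$key[i]]]
    if (is.null(m)) next
    a <- pmax(0L, m[, 1] - extend); b <- m[, 2] + extend
    if (any(sites$start[i] < b & sites$end[i] > a)) n <- n + 1L
  }
  n
}

#' Mask and FPD safety audit on a synthetic world
#'
#' Generates the site-scanning datasets (non-positive-site CLASH and CLIP)
#' and the FPD-filtered datasets (TarBase, CLIP-non-CLASH) and exhaustively
#' counts (i) emitted sites overlapping a masked span and (ii) emitted
#' records whose (gene, miRNA) or (gene, seed family) pair is in the FPD.
#'
#' @param world A `synthetic_world`.
#' @param engine A `duplex_engine`.
#' @param seed RNG seed for the stochastic stages.
#' @return List of violation counts and dataset sizes.
#' @export
safety_check <- function(world, engine = duplex_engine_dp(), seed = 1L) {
  positives <- process_positives(world$positives, engine)
  fpd <- build_fpd(positives)
  pos <- positives$records

  nps_clash <- gen_nps_clash(positives, "min_mfe", engine, seed = seed + 1L)
  tarbase <- gen_tarbase_negatives(world$tarbase_rows, fpd, "all",
                                   world$mirnas, world$utrs, engine)
  cnc <- gen_clip_non_clash(world$clip_mirnas, world$clip_mrnas, fpd, engine)
  nps_clip <- gen_nps_clip(world$clip_mirnas, world$clip_mrnas, fpd,
                           "random", engine, seed = seed + 2L)

  # NPS CLASH masks are per (miRNA, gene) pair
  pair_masks <- lapply(split(pos[, c("site_start", "site_end")],
                             paste(pos$mirna_name, pos$gene_id, sep = "\r")),
                       as.matrix)
  r <- nps_clash$records
  clash_overlaps <- count_span_overlaps(
    data.frame(key = paste(r$mirna_name, r$gene_id, sep = "\r"),
               start = r$site_start, end = r$site_end,
               stringsAsFactors = FALSE), pair_masks)

  # NPS CLIP masks are per gene: CLIP fragments plus FPD sites
  gene_masks <- lapply(split(world$clip_mrnas[, c("fragment_start",
                                                  "fragment_end")],
                             world$clip_mrnas$gene_id), as.matrix)
  for (g in names(fpd$site_spans))
    gene_masks[[g]] <- rbind(gene_masks[[g]], fpd$site_spans[[g]])
  r <- nps_clip$records
  clip_overlaps <- count_span_overlaps(
    data.frame(key = r$gene_id, start = r$site_start, end = r$site_end,
               stringsAsFactors = FALSE), gene_masks)

  fpd_hits <- function(recs, family = TRUE, pair = TRUE) {
    h <- 0L
    if (pair) h <- h + sum(paste(recs$gene_id, recs$mirna_name, sep = "\r")
                           %in% fpd$pair_index)
    if (family) h <- h + sum(paste(recs$gene_id, seed_family(recs$mirna_seq),
                                   sep = "\r") %in% fpd$seed_family_index)
    h
  }

  list(
    n_positives = nrow(pos),
    sizes = c(nps_clash = nrow(nps_clash$records),
              tarbase = nrow(tarbase$records),
              clip_non_clash = nrow(cnc$records),
              nps_clip = nrow(nps_clip$records)),
    mask_overlaps = clash_overlaps + clip_overlaps,
    fpd_violations = fpd_hits(tarbase$records, family = FALSE) +
      fpd_hits(cnc$records, pair = FALSE) + fpd_hits(nps_clip$records),
    tail_violations = sum(with(cnc$records,
      vapply(seq_along(duplex_pairs), function(i)
        nchar(mirna_seq[i]) - max(parse_pairs_string(duplex_pairs[i])$mirna_pos),
        numeric(1)) > 5))
  )
}

#' Run the desk-scale intra/cross benchmark
#'
#' Generates a synthetic world, processes the positives, builds the two
#' site-level mock-mRNA datasets (mono- and dinucleotide shuffling),
#' extracts the 500-feature representation, applies the leakage filter,
#' builds the 20-repeat shared-positive split plan, runs the intra/cross
#' gradient-boosting evaluation and the one-class comparison, and returns
#' the headline quantities.
#'
#' @param seed Integer seed for the whole run.
#' @param world_params Overrides of [default_world_params()].
#' @param repeats Number of split repeats.
#' @param xgb_params Gradient-boosting hyperparameters used for all
#'   datasets (fixed mid-grid values by default; see [tune_xgboost()] for
#'   the search).
#' @param engine,acc_engine Engines.
#' @return List with the cross matrix, one-class summary, derived headline
#'   numbers and the intermediate objects.
#' @export
run_benchmark <- function(seed = 1L, world_params = list(), repeats = 20L,
                          xgb_params = list(max_depth = 6L, eta = 0.1,
                                            nrounds = 150L),
                          engine = duplex_engine_dp(),
                          acc_engine = accessibility_engine_pf()) {
  world <- gen_world(world_params, seed = seed)
  positives <- process_positives(world$positives, engine)

  mono <- gen_mock_mrna(positives, "fragment", k = 1L, engine = engine,
                        seed = seed + 11L)
  di <- gen_mock_mrna(positives, "fragment", k = 2L, engine = engine,
                      seed = seed + 12L)

  pos_X <- extract_features_dataset(positives, acc_engine, engine)
  neg_X <- list(mock_mono_fragment = extract_features_dataset(mono, acc_engine,
                                                              engine),
                mock_di_fragment = extract_features_dataset(di, acc_engine,
                                                            engine))
  neg_X <- lapply(neg_X, leakage_filter, positives = pos_X)

  plan <- make_split_plan(nrow(pos_X),
                          vapply(neg_X, nrow, integer(1)),
                          repeats = repeats, base_seed = seed)
  cm <- cross_matrix(pos_X, neg_X, plan, xgb_params)
  occ <- one_class_comparison(pos_X, neg_X$mock_di_fragment, plan,
                              "mock_di_fragment")

  # headline numbers
  diag_mean <- function(ds) {
    m <- cm$mean
    m$acc[m$train == ds & m$test == ds]
  }
  pr <- cm$per_repeat
  tpr_spread <- max(vapply(split(pr, paste(pr$train, pr$rep)), function(d)
    diff(range(d$tpr)), numeric(1)))

  truth <- world$truth
  can_ids <- names(truth)[truth == "canonical"]
  rec <- positives$records
  canonical_recovery <-
    sum(rec$record_id %in% can_ids & rec$seed_type == "canonical") /
    length(can_ids)

  osum <- occ$summary
  list(world = world, positives = positives,
       datasets = list(mock_mono_fragment = mono, mock_di_fragment = di),
       features = c(list(positives = pos_X), neg_X),
       plan = plan, cross = cm, one_class = occ,
       headline = list(
         n_positives = nrow(rec),
         canonical_recovery = canonical_recovery,
         acc_intra_mono = diag_mean("mock_mono_fragment"),
         acc_intra_di = diag_mean("mock_di_fragment"),
         tpr_spread_across_test_sets = tpr_spread,
         tnr_one_class_svm = osum$tnr[osum$model == "one_class_svm"],
         tnr_svm = osum$tnr[osum$model == "svm"],
         tnr_isolation_forest = osum$tnr[osum$model == "isolation_forest"],
         tnr_random_forest = osum$tnr[osum$model == "random_forest"]))
}
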