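# The six negative-interaction generation methods, positive-set processing,
# full-positive-dataset (FPD) filtering and the balanced mixture.
#
# Every emitted dataset is restricted to *valid* records (canonical or
# non-canonical seed), duplicate (miRNA, gene, duplex) triples are dropped,
# and records carry the duplex serialization (pair map with target positions
# relative to the fragment), its MFE, seed type and density class.

DATASET_COLUMNS <- c("record_id", "mirna_name", "mirna_seq", "gene_id",
                     "fragment_seq", "fragment_start", "fragment_end",
                     "full_len", "site_start", "site_end", "duplex_pairs",
                     "mfe_kcal_mol", "n_pairs", "seed_type", "density_class",
                     "label", "method", "full_mrna_seq")

# assemble a Dataset from a record data frame: enforce the duplicate filter
# on (miRNA name, gene, duplex pairing) and attach metadata
make_dataset <- function(name, records, summary = list()) {
  if (is.null(records) || nrow(records) == 0) {
    records <- as.data.frame(setNames(rep(list(character(0)),
                                          length(DATASET_COLUMNS)),
                                      DATASET_COLUMNS))
  } else {
    key <- paste(records$mirna_name, records$gene_id, records$duplex_pairs,
                 sep = "\r")
    dup <- duplicated(key)
    summary$duplicates_removed <- sum(dup)
    records <- records[!dup, , drop = FALSE]
    rownames(records) <- NULL
  }
  structure(list(name = name, records = records, summary = summary),
            class = "mti_dataset")
}

# extend a site span to `width` nt, clipped to [0, len)
extend_span <- function(s0, s1, len, width = 75L) {
  slen <- s1 - s0
  pad <- pmax(0L, width - slen)
  f0 <- pmax(0L, s0 - pad %/% 2L)
  f1 <- f0 + pmax(width, slen)
  over <- f1 > len
  f1[over] <- len[over]
  f0[over] <- pmax(0L, len[over] - pmax(width, slen[over]))
  cbind(f0, f1)
}

# shift the target coordinates of a serialized pair map by -offset
remap_pairs <- function(pairs_str, offset) {
  vapply(seq_along(pairs_str), function(i) {
    p <- parse_pairs_string(pairs_str[i])
    paste(p$mirna_pos, p$target_pos - offset[i], sep = ":", collapse = ";")
  }, character(1))
}

seed_family <- function(mirna_seq) substr(mirna_seq, 2, 8)

#' Build the full-positive-dataset (FPD) index
#'
#' The FPD is the union of all supplied positive datasets. It indexes
#' (gene, miRNA) pairs, (gene, miRNA seed family) pairs -- the seed family
#' being the 7-mer at miRNA positions 2-8 -- and the positive site spans per
#' gene, and is used to exclude genuine interactions from candidate
#' negatives.
#'
#' @param positive_datasets A list of `mti_dataset` objects (or one).
#' @return An `fpd` object: `pair_index`, `seed_family_index`, `site_spans`.
#' @export
build_fpd <- function(positive_datasets) {
  if (inherits(positive_datasets, "mti_dataset"))
    positive_datasets <- list(positive_datasets)
  recs <- do.call(rbind, lapply(positive_datasets, function(d)
    d$records[, c("mirna_name", "mirna_seq", "gene_id",
                  "site_start", "site_end")]))
  spans <- lapply(split(recs[, c("site_start", "site_end")], recs$gene_id),
                  function(df) as.matrix(df))
  structure(list(
    pair_index = unique(paste(recs$gene_id, recs$mirna_name, sep = "\r")),
    seed_family_index = unique(paste(recs$gene_id,
                                     seed_family(recs$mirna_seq), sep = "\r")),
    site_spans = spans), class = "fpd")
}

# build dataset records from raw fields + scan rows (already filtered valid);
# scan site coordinates are relative to the scanned target, whose offset on
# the full mRNA is `target_offset`
records_from_scan <- function(tag, mirna_name, mirna_seq, gene_id, full_seq,
                              scan, target_offset, frag_span = NULL,
                              remap = TRUE, label = "negative") {
  n <- length(mirna_name)
  if (n == 0) return(NULL)
  site0 <- target_offset + scan$site_start
  site1 <- target_offset + scan$site_end
  len <- nchar(full_seq)
  if (is.null(frag_span)) frag_span <- extend_span(site0, site1, len)
  pairs <- scan$pairs
  if (remap) pairs <- remap_pairs(pairs, frag_span[, 1] - target_offset)
  data.frame(
    record_id = sprintf("%s-%05d", tag, seq_len(n)),
    mirna_name = mirna_name, mirna_seq = mirna_seq, gene_id = gene_id,
    fragment_seq = substr(full_seq, frag_span[, 1] + 1L, frag_span[, 2]),
    fragment_start = frag_span[, 1], fragment_end = frag_span[, 2],
    full_len = len, site_start = site0, site_end = site1,
    duplex_pairs = pairs, mfe_kcal_mol = scan$mfe, n_pairs = scan$n_pairs,
    seed_type = seed_type_from_code(scan$seed_code),
    density_class = density_class_from_count(scan$n_pairs),
    label = label, method = tag, full_mrna_seq = full_seq,
    stringsAsFactors = FALSE)
}

#' Process raw positive interactions into a valid positive dataset
#'
#' Computes the duplex of each (miRNA, fragment) pair, keeps only valid
#' (canonical / non-canonical) interactions, and drops duplicate
#' (miRNA, gene, duplex) records.
#'
#' @param raw_records Data frame with `mirna_name`, `mirna_seq`, `gene_id`,
#'   `fragment_seq`, `fragment_start`, `fragment_end`, `full_mrna_seq`.
#' @param engine A `duplex_engine`.
#' @return An `mti_dataset` named `"positives"`, with a processing summary.
#' @export
process_positives <- function(raw_records, engine = duplex_engine_dp()) {
  sc <- engine$scan(raw_records$mirna_seq, raw_records$fragment_seq, -1L)
  keep <- sc$valid
  r <- raw_records[keep, , drop = FALSE]
  sck <- sc[keep, , drop = FALSE]
  recs <- records_from_scan(
    "positive", r$mirna_name, r$mirna_seq, r$gene_id, r$full_mrna_seq,
    sck, target_offset = r$fragment_start,
    frag_span = cbind(r$fragment_start, r$fragment_end),
    label = "positive")
  if (!is.null(recs) && "record_id" %in% names(r)) {
    recs$record_id <- r$record_id  # keep world record ids for truth lookups
  }
  make_dataset("positives", recs,
               summary = list(n_input = nrow(raw_records),
                              n_invalid = sum(!keep)))
}

#' Method 1: mock-miRNA negatives
#'
#' For each positive, the miRNA is mononucleotide-shuffled until its seed
#' windows (2-7 and 3-8) match no catalog miRNA, then the duplex against the
#' full mRNA is computed; the process repeats until a valid duplex is found
#' or `max_attempts` is reached.
#'
#' @param positives Processed positive `mti_dataset`.
#' @param catalog miRNA catalog used for the seed-collision screen.
#' @param engine A `duplex_engine`.
#' @param max_attempts Attempt cap per positive (default 100).
#' @param seed Optional RNG seed.
#' @return An `mti_dataset` with method tag `mock_mirna`.
#' @export
gen_mock_mirna <- function(positives, catalog, engine = duplex_engine_dp(),
                           max_attempts = 100L, seed = NULL) {
  idx <- seed_window_index(catalog)
  pos <- positives$records
  with_seed(seed, {
    n <- nrow(pos)
    done <- logical(n)
    cand_seq <- character(n)
    scans <- vector("list", n)
    for (attempt in seq_len(max_attempts)) {
      act <- which(!done)
      if (length(act) == 0) break
      cand <- vapply(pos$mirna_seq[act], shuffle_kmer, character(1), k = 1L)
      ok_seed <- !vapply(cand, seed_collides, logical(1), index = idx)
      trial <- act[ok_seed]
      if (length(trial) == 0) next
      sc <- engine$scan(cand[ok_seed], pos$full_mrna_seq[trial], -1L)
      hit <- which(sc$valid)
      for (h in hit) {
        i <- trial[h]
        done[i] <- TRUE
        cand_seq[i] <- cand[ok_seed][h]
        scans[[i]] <- sc[h, , drop = FALSE]
      }
    }
    won <- which(done)
    sc <- do.call(rbind, scans[won])
    recs <- records_from_scan(
      "mock_mirna", paste0(pos$mirna_name[won], "|mock"), cand_seq[won],
      pos$gene_id[won], pos$full_mrna_seq[won], sc, target_offset = 0L)
    make_dataset("mock_mirna", recs,
                 summary = list(n_source = n, n_exhausted = sum(!done)))
  })
}

# one mock-target attempt for a batch of positives; returns list(target,
# full, frag_span, offset) on the mock coordinate system
mock_target_once <- function(pos, region_mode, k) {
  n <- nrow(pos)
  if (region_mode == "full_mrna") {
    full <- vapply(pos$full_mrna_seq, shuffle_kmer, character(1), k = k)
    list(target = full, full = full, offset = rep(0L, n), frag_span = NULL)
  } else {
    len <- nchar(pos$full_mrna_seq)
    e0 <- pmax(0L, pos$site_start - 100L)
    e1 <- pmin(len, pos$site_end + 100L)
    ext <- substr(pos$full_mrna_seq, e0 + 1L, e1)
    ext <- vapply(ext, shuffle_kmer, character(1), k = k)
    tl <- pmin(50L, pos$site_start - e0)
    tr <- pmin(50L, e1 - pos$site_end)
    elen <- e1 - e0
    frag <- substr(ext, tl + 1L, elen - tr)
    list(target = frag, full = ext, offset = tl,
         frag_span = cbind(tl, elen - tr))
  }
}

#' Method 2: mock-mRNA negatives
#'
#' The target side of each positive is replaced by a shuffled version:
#' `full_mrna` shuffles the whole 3'UTR; `fragment` extends the site by
#' 100 nt per side (clipped at the mRNA bounds), shuffles the extended
#' region and trims 50 nt per side, keeping the trimmed-off flanks as
#' context; `fragment_and_mirna` additionally replaces the miRNA by a
#' Method-1 mock. Shuffling preserves exact k-mer counts (`k` = 1 or 2).
#' Each attempt reshuffles; retries continue to validity or `max_attempts`.
#'
#' @param positives Processed positive `mti_dataset`.
#' @param region_mode `"full_mrna"`, `"fragment"` or `"fragment_and_mirna"`.
#' @param k Shuffle order: 1 (mono) or 2 (di).
#' @param catalog miRNA catalog (needed for `fragment_and_mirna`).
#' @param engine A `duplex_engine`.
#' @param max_attempts Attempt cap per positive.
#' @param seed Optional RNG seed.
#' @return An `mti_dataset` tagged `mock_<mono|di>_<mrna|fragment|fragment_mirna>`.
#' @export
gen_mock_mrna <- function(positives, region_mode = c("full_mrna", "fragment",
                                                     "fragment_and_mirna"),
                          k = 1L, catalog = NULL,
                          engine = duplex_engine_dp(), max_attempts = 100L,
                          seed = NULL) {
  region_mode <- match.arg(region_mode)
  tag <- paste0("mock_", c("mono", "di")[k], "_",
                switch(region_mode, full_mrna = "mrna", fragment = "fragment",
                       fragment_and_mirna = "fragment_mirna"))
  mock_mir <- region_mode == "fragment_and_mirna"
  if (mock_mir && is.null(catalog))
    stop("fragment_and_mirna mode requires the miRNA catalog", call. = FALSE)
  idx <- if (mock_mir) seed_window_index(catalog)
  pos <- positives$records
  with_seed(seed, {
    n <- nrow(pos)
    done <- logical(n)
    out <- vector("list", n)
    for (attempt in seq_len(max_attempts)) {
      act <- which(!done)
      if (length(act) == 0) break
      sub <- pos[act, , drop = FALSE]
      mt <- mock_target_once(sub, region_mode, k)
      mir <- sub$mirna_seq
      mname <- sub$mirna_name
      if (mock_mir) {
        mir <- vapply(mir, shuffle_kmer, character(1), k = 1L)
        keep <- !vapply(mir, seed_collides, logical(1), index = idx)
        mname <- paste0(mname, "|mock")
      } else keep <- rep(TRUE, length(act))
      if (!any(keep)) next
      sc <- engine$scan(mir[keep], mt$target[keep], -1L)
      hit <- which(sc$valid)
      kact <- act[keep]
      for (h in hit) {
        i <- kact[h]
        done[i] <- TRUE
        out[[i]] <- list(scan = sc[h, , drop = FALSE],
                         mirna_seq = mir[keep][h], mirna_name = mname[keep][h],
                         full = mt$full[keep][h], offset = mt$offset[keep][h],
                         frag = if (is.null(mt$frag_span)) NULL
                                else mt$frag_span[keep, , drop = FALSE][h, ])
      }
    }
    won <- which(done)
    if (length(won) == 0) return(make_dataset(tag, NULL))
    sc <- do.call(rbind, lapply(out[won], `[[`, "scan"))
    full <- vapply(out[won], `[[`, character(1), "full")
    offset <- vapply(out[won], `[[`, integer(1), "offset")
    frag_span <- if (region_mode == "full_mrna") NULL else
      do.call(rbind, lapply(out[won], `[[`, "frag"))
    recs <- records_from_scan(
      tag, vapply(out[won], `[[`, character(1), "mirna_name"),
      vapply(out[won], `[[`, character(1), "mirna_seq"),
      pos$gene_id[won], full, sc, target_offset = offset,
      frag_span = frag_span)
    make_dataset(tag, recs,
                 summary = list(n_source = n, n_exhausted = sum(!done)))
  })
}

# selection among valid candidates by MFE; returns one index
select_candidate <- function(mfe, rule) {
  n <- length(mfe)
  if (n == 1) return(1L)
  ord <- order(mfe)  # most negative first
  switch(rule,
    min_mfe = ord[1L],
    random = sample.int(n, 1L),
    median_mfe = ord[if (n %% 2L == 1L) (n + 1L) %/% 2L else n %/% 2L],
    p20_random = {
      top <- ord[seq_len(ceiling(0.2 * n))]
      if (length(top) == 1L) top else sample(top, 1L)
    },
    stop("unknown selection rule: ", rule, call. = FALSE))
}

# mask spans (0-based half-open, extended by `extend` per side) with N
mask_sequence <- function(seq, spans, extend = 10L) {
  if (is.null(spans) || nrow(spans) == 0) return(seq)
  len <- nchar(seq)
  for (i in seq_len(nrow(spans))) {
    a <- max(0L, spans[i, 1] - extend)
    b <- min(len, spans[i, 2] + extend)
    if (b > a) substr(seq, a + 1L, b) <- strrep("N", b - a)
  }
  seq
}

# full sliding windows of `width` every `step` nt; 0-based starts
window_starts <- function(len, width = 75L, step = 40L) {
  if (len < width) return(integer(0))
  seq(0L, len - width, by = step)
}

#' Method 3: non-positive-site CLASH negatives
#'
#' For each positive (miRNA, gene) pair, all its positive sites (extended by
#' 10 nt per side) are masked with N on the full mRNA; the masked sequence
#' is scanned with 75-nt windows every 40 nt; valid window duplexes become
#' candidates and one is chosen per pair by the selection rule.
#'
#' @param positives Processed positive `mti_dataset`.
#' @param selection `"min_mfe"`, `"random"`, `"median_mfe"` or
#'   `"p20_random"` (random among the best 20% by MFE).
#' @param engine A `duplex_engine`.
#' @param seed Optional RNG seed (used by the stochastic selection rules).
#' @return An `mti_dataset` tagged `nps_clash_<rule>`.
#' @export
gen_nps_clash <- function(positives, selection = "min_mfe",
                          engine = duplex_engine_dp(), seed = NULL) {
  pos <- positives$records
  tag <- paste0("nps_clash_", selection)
  grp <- split(seq_len(nrow(pos)), paste(pos$mirna_name, pos$gene_id,
                                         sep = "\r"))
  # build all windows of all groups, then scan once
  wtab <- lapply(grp, function(ix) {
    r1 <- pos[ix[1], ]
    masked <- mask_sequence(r1$full_mrna_seq,
                            cbind(pos$site_start[ix], pos$site_end[ix]))
    st <- window_starts(nchar(masked))
    if (length(st) == 0) return(NULL)
    data.frame(gi = ix[1], wstart = st,
               wseq = substr(rep(masked, length(st)), st + 1L, st + 75L),
               stringsAsFactors = FALSE)
  })
  wtab <- do.call(rbind, wtab[!vapply(wtab, is.null, logical(1))])
  sc <- engine$scan(pos$mirna_seq[wtab$gi], wtab$wseq, -1L)
  ok <- which(sc$valid)
  with_seed(seed, {
    picks <- vapply(split(ok, wtab$gi[ok]), function(ix) {
      ix[select_candidate(sc$mfe[ix], selection)]
    }, integer(1))
    gi <- wtab$gi[picks]
    scp <- sc[picks, , drop = FALSE]
    recs <- records_from_scan(
      tag, pos$mirna_name[gi], pos$mirna_seq[gi], pos$gene_id[gi],
      pos$full_mrna_seq[gi], scp, target_offset = wtab$wstart[picks],
      frag_span = cbind(wtab$wstart[picks], wtab$wstart[picks] + 75L))
    make_dataset(tag, recs,
                 summary = list(n_groups = length(grp),
                                n_no_candidate = length(grp) - length(picks)))
  })
}

#' Method 4: TarBase-style database negatives
#'
#' Duplicate (gene, miRNA) rows are collapsed, pairs present in the FPD are
#' removed, the variant filter is applied, sequences are looked up in the
#' catalogs, and the duplex against the full mRNA is computed; valid
#' interactions are kept.
#'
#' @param tarbase_rows Data frame with `gene_id`, `mirna_name`, `tissue`,
#'   `method`.
#' @param fpd An `fpd` index.
#' @param variant `"all"`, `"tissue:<name>"` or `"microarray"`.
#' @param mirnas,utrs Catalogs for sequence lookup.
#' @param engine A `duplex_engine`.
#' @return An `mti_dataset` tagged `tarbase`, `tarbase_<tissue>` or
#'   `tarbase_microarray`.
#' @export
gen_tarbase_negatives <- function(tarbase_rows, fpd, variant = "all",
                                  mirnas, utrs,
                                  engine = duplex_engine_dp()) {
  rows <- tarbase_rows[!duplicated(paste(tarbase_rows$gene_id,
                                         tarbase_rows$mirna_name, sep = "\r")), ]
  rows <- rows[!(paste(rows$gene_id, rows$mirna_name, sep = "\r") %in%
                   fpd$pair_index), ]
  tag <- "tarbase"
  if (startsWith(variant, "tissue:")) {
    tis <- sub("^tissue:", "", variant)
    rows <- rows[rows$tissue == tis, ]
    tag <- paste0("tarbase_", tis)
  } else if (variant == "microarray") {
    rows <- rows[rows$method == "microarray", ]
    tag <- "tarbase_microarray"
  } else if (variant != "all") {
    stop("unknown variant: ", variant, call. = FALSE)
  }
  mseq <- setNames(mirnas$sequence, mirnas$name)
  gseq <- setNames(utrs$sequence, utrs$gene_id)
  known <- rows$mirna_name %in% names(mseq) & rows$gene_id %in% names(gseq)
  rows <- rows[known, , drop = FALSE]
  if (nrow(rows) == 0) return(make_dataset(tag, NULL))
  sc <- engine$scan(mseq[rows$mirna_name], gseq[rows$gene_id], -1L)
  keep <- sc$valid
  rows <- rows[keep, , drop = FALSE]
  sck <- sc[keep, , drop = FALSE]
  recs <- records_from_scan(
    tag, rows$mirna_name, unname(mseq[rows$mirna_name]), rows$gene_id,
    unname(gseq[rows$gene_id]), sck, target_offset = 0L)
  make_dataset(tag, recs,
               summary = list(n_rows = nrow(tarbase_rows),
                              n_unknown = sum(!known), n_invalid = sum(!keep)))
}

#' Method 5: CLIP-non-CLASH negatives
#'
#' All miRNA x mRNA-fragment pairs from the CLIP lists are formed; pairs
#' whose (gene, miRNA seed family) appears in the FPD are removed; the
#' duplex on the fragment is computed; valid interactions with an unpaired
#' miRNA 3' tail of at most `max_tail` nt are kept.
#'
#' @param clip_mirnas Data frame `name`, `sequence`.
#' @param clip_mrnas Data frame `gene_id`, `fragment_seq`, `full_seq`,
#'   `fragment_start`, `fragment_end`.
#' @param fpd An `fpd` index.
#' @param engine A `duplex_engine`.
#' @param max_tail Maximum unpaired 3' tail (default 5 nt).
#' @return An `mti_dataset` tagged `clip_non_clash`.
#' @export
gen_clip_non_clash <- function(clip_mirnas, clip_mrnas, fpd,
                               engine = duplex_engine_dp(), max_tail = 5L) {
  if (nrow(clip_mirnas) == 0 || nrow(clip_mrnas) == 0)
    stop("CLIP lists must be non-empty", call. = FALSE)
  gr <- expand.grid(mi = seq_len(nrow(clip_mirnas)),
                    mj = seq_len(nrow(clip_mrnas)))
  fam <- paste(clip_mrnas$gene_id[gr$mj],
               seed_family(clip_mirnas$sequence[gr$mi]), sep = "\r")
  pair <- paste(clip_mrnas$gene_id[gr$mj], clip_mirnas$name[gr$mi],
                sep = "\r")
  keep <- !(fam %in% fpd$seed_family_index) & !(pair %in% fpd$pair_index)
  gr <- gr[keep, , drop = FALSE]
  n_family_filtered <- sum(!keep)
  sc <- engine$scan(clip_mirnas$sequence[gr$mi],
                    clip_mrnas$fragment_seq[gr$mj], as.integer(max_tail))
  ok <- sc$valid
  gr <- gr[ok, , drop = FALSE]
  sck <- sc[ok, , drop = FALSE]
  mr <- clip_mrnas[gr$mj, , drop = FALSE]
  recs <- records_from_scan(
    "clip_non_clash", clip_mirnas$name[gr$mi], clip_mirnas$sequence[gr$mi],
    mr$gene_id, mr$full_seq, sck, target_offset = mr$fragment_start,
    frag_span = cbind(mr$fragment_start, mr$fragment_end))
  make_dataset("clip_non_clash", recs,
               summary = list(n_pairs = length(keep),
                              n_family_filtered = n_family_filtered,
                              n_invalid_or_tail = sum(!ok)))
}

#' Method 6: non-positive-site CLIP negatives
#'
#' For each full mRNA in the CLIP list, the CLIP fragments and the FPD
#' positive sites (extended by 10 nt per side) are masked; the masked
#' sequence is scanned with 75-nt windows every 40 nt; each window draws a
#' random miRNA from the CLIP list, retrying to a valid, FPD-clean duplex or
#' `max_attempts`; one candidate per mRNA is chosen by the selection rule.
#'
#' @inheritParams gen_clip_non_clash
#' @param selection Candidate selection rule (see [gen_nps_clash()]).
#' @param max_attempts Attempt cap per window.
#' @param seed Optional RNG seed.
#' @return An `mti_dataset` tagged `nps_clip_<rule>`.
#' @export
gen_nps_clip <- function(clip_mirnas, clip_mrnas, fpd, selection = "random",
                         engine = duplex_engine_dp(), max_attempts = 100L,
                         seed = NULL) {
  if (nrow(clip_mirnas) == 0) stop("empty miRNA list", call. = FALSE)
  tag <- paste0("nps_clip_", selection)
  genes <- unique(clip_mrnas$gene_id)
  full <- setNames(clip_mrnas$full_seq[!duplicated(clip_mrnas$gene_id)],
                   clip_mrnas$gene_id[!duplicated(clip_mrnas$gene_id)])
  wtab <- lapply(genes, function(g) {
    spans <- as.matrix(clip_mrnas[clip_mrnas$gene_id == g,
                                  c("fragment_start", "fragment_end")])
    if (!is.null(fpd$site_spans[[g]]))
      spans <- rbind(spans, fpd$site_spans[[g]])
    masked <- mask_sequence(full[[g]], spans)
    st <- window_starts(nchar(masked))
    if (length(st) == 0) return(NULL)
    data.frame(gene = g, wstart = st,
               wseq = substr(rep(masked, length(st)), st + 1L, st + 75L),
               stringsAsFactors = FALSE)
  })
  wtab <- do.call(rbind, wtab[!vapply(wtab, is.null, logical(1))])
  if (is.null(wtab)) return(make_dataset(tag, NULL))
  nw <- nrow(wtab)
  with_seed(seed, {
    done <- logical(nw)
    mir_ix <- integer(nw)
    scans <- vector("list", nw)
    for (attempt in seq_len(max_attempts)) {
      act <- which(!done)
      if (length(act) == 0) break
      draw <- sample.int(nrow(clip_mirnas), length(act), replace = TRUE)
      # FPD exclusion for the drawn pair
      fam <- paste(wtab$gene[act], seed_family(clip_mirnas$sequence[draw]),
                   sep = "\r")
      pair <- paste(wtab$gene[act], clip_mirnas$name[draw], sep = "\r")
      okf <- !(fam %in% fpd$seed_family_index) & !(pair %in% fpd$pair_index)
      trial <- act[okf]
      if (length(trial) == 0) next
      sc <- engine$scan(clip_mirnas$sequence[draw[okf]], wtab$wseq[trial], -1L)
      hit <- which(sc$valid)
      for (h in hit) {
        i <- trial[h]
        done[i] <- TRUE
        mir_ix[i] <- draw[okf][h]
        scans[[i]] <- sc[h, , drop = FALSE]
      }
    }
    won <- which(done)
    if (length(won) == 0) return(make_dataset(tag, NULL))
    sc <- do.call(rbind, scans[won])
    picks <- vapply(split(seq_along(won), wtab$gene[won]), function(ix) {
      ix[select_candidate(sc$mfe[ix], selection)]
    }, integer(1))
    w <- won[picks]
    scp <- sc[picks, , drop = FALSE]
    recs <- records_from_scan(
      tag, clip_mirnas$name[mir_ix[w]], clip_mirnas$sequence[mir_ix[w]],
      wtab$gene[w], unname(full[wtab$gene[w]]), scp,
      target_offset = wtab$wstart[w],
      frag_span = cbind(wtab$wstart[w], wtab$wstart[w] + 75L))
    make_dataset(tag, recs,
                 summary = list(n_mrnas = length(genes), n_windows = nw,
                                n_window_exhausted = sum(!done)))
  })
}

#' Balanced mixture of negative datasets
#'
#' Draws equal counts without replacement from each dataset
#' (`floor(n_total / k)` each); if a dataset is smaller than its quota its
#' records are all taken and the shortfall is reallocated proportionally
#' with a warning. Per-record method tags are preserved.
#'
#' @param datasets List of >= 2 `mti_dataset` objects.
#' @param n_total Total mixture size.
#' @param seed Optional RNG seed.
#' @return An `mti_dataset` named `mixture`.
#' @export
combine_negatives <- function(datasets, n_total, seed = NULL) {
  if (length(datasets) < 2) stop("need at least 2 datasets", call. = FALSE)
  sizes <- vapply(datasets, function(d) nrow(d$records), integer(1))
  k <- length(datasets)
  quota <- rep(n_total %/% k, k)
  if (any(sizes < quota)) {
    short <- sizes < quota
    deficit <- sum(quota[short] - sizes[short])
    quota[short] <- sizes[short]
    room <- sizes - quota
    while (deficit > 0 && any(room > 0)) {
      i <- which.max(room)
      add <- min(deficit, room[i])
      quota[i] <- quota[i] + add
      room[i] <- room[i] - add
      deficit <- deficit - add
    }
    warning("some datasets were smaller than their quota; ",
            "reallocated proportionally", call. = FALSE)
  }
  with_seed(seed, {
    recs <- do.call(rbind, lapply(seq_len(k), function(i) {
      d <- datasets[[i]]$records
      d[sample.int(nrow(d), quota[i]), , drop = FALSE]
    }))
    recs$record_id <- sprintf("mixture-%05d", seq_len(nrow(recs)))
    make_dataset("mixture", recs, summary = list(quotas = quota))
  })
}
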