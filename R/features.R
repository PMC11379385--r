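# The 500-feature representation of an interaction, in five categories:
# seed (13), free energy (7), mRNA composition (62), miRNA pairing (48) and
# site accessibility (370). Feature identities are fixed by the schema
# (machine-readable via build_schema()/write_schema()); all extraction is
# deterministic given the record and the engines.

ACC_OFFSETS <- -10:26   # site-relative positions (0-based offsets from start)
ACC_WIDTHS <- 1:10      # unpaired-stretch widths

#' Build the 500-feature schema
#'
#' @return Data frame with `name`, `category`, `index` (1..500). Category
#'   totals are seed 13, free_energy 7, mrna_composition 62,
#'   mirna_pairing 48, accessibility 370.
#' @export
build_schema <- function() {
  seed <- c("seed_canonical", "seed_non_canonical",
            "seed_wc_2_7", "seed_gu_2_7", "seed_unpaired_2_7",
            "seed_tbulge_2_7", "seed_wc_3_8", "seed_gu_3_8",
            "seed_unpaired_3_8", "seed_tbulge_3_8",
            "seed_paired_frac_2_8", "seed_gc_2_8", "seed_contiguous_helix")
  fe <- c("mfe_duplex", "mfe_seed_region", "mfe_3p_region", "mfe_per_nt",
          "fold_proxy_site", "fold_proxy_flank5", "fold_proxy_flank3")
  comp <- c(unlist(lapply(c("site", "flank5", "flank3"), function(r)
    c(paste0("freq_", r, "_", RNA_BASES), paste0("freq_", r, "_", DINUCS)))),
    "gc_site", "gc_flanks")
  pairing <- c(sprintf("mirna_wc_pos%02d", 1:22),
               sprintf("mirna_gu_pos%02d", 1:22),
               "total_pairs", "total_wc", "total_gu", "tail_3p")
  acc <- as.vector(t(outer(ACC_OFFSETS, ACC_WIDTHS, function(o, w)
    sprintf("acc_p%+03d_w%02d", o, w))))
  nm <- c(seed, fe, comp, pairing, acc)
  data.frame(name = nm,
             category = rep(c("seed", "free_energy", "mrna_composition",
                              "mirna_pairing", "accessibility"),
                            c(length(seed), length(fe), length(comp),
                              length(pairing), length(acc))),
             index = seq_along(nm), stringsAsFactors = FALSE)
}

#' Write the feature schema as JSON
#'
#' @param path Output file.
#' @export
write_schema <- function(path) {
  jsonlite::write_json(build_schema(), path, dataframe = "rows")
  invisible(path)
}

#' Partition-function accessibility engine
#'
#' Computes exact region-unpaired probabilities from a McCaskill-style
#' inside/outside partition function over a base-pair-counting energy model,
#' evaluated on a local window (default 120 nt) centered on the site. The
#' probability reported for (position, width) is that the stretch of `width`
#' bases ending at the position is entirely unpaired; stretches clipped at
#' the window bounds are evaluated on their overlap, and positions entirely
#' outside get the neutral value 1. Sequences with no legal pair give 1
#' everywhere.
#'
#' @param window Local fold window in nt.
#' @return An `accessibility_engine` with a
#'   `profile(full_seq, site_start, site_end)` function returning a
#'   37 x 10 matrix (offsets -10..26 from the site start x widths 1..10).
#' @export
accessibility_engine_pf <- function(window = 120L) {
  structure(list(
    name = "mccaskill-counting",
    window = window,
    profile = function(full_seq, site_start, site_end) {
      len <- nchar(full_seq)
      mid <- (site_start + site_end) %/% 2L
      w0 <- max(0L, mid - window %/% 2L)
      w1 <- min(len, w0 + window)
      w0 <- max(0L, w1 - window)
      sub <- substr(full_seq, w0 + 1L, w1)
      # 1-based positions within the local window
      pos_local <- site_start + ACC_OFFSETS + 1L - w0
      m <- region_unpaired_probs_cpp(sub, as.integer(pos_local),
                                     max(ACC_WIDTHS))
      dimnames(m) <- list(sprintf("p%+03d", ACC_OFFSETS),
                          sprintf("w%02d", ACC_WIDTHS))
      m
    }), class = "accessibility_engine")
}

#' Accessibility profile of a target site
#'
#' @param full_mrna Full mRNA sequence.
#' @param site_span Numeric length-2, 0-based half-open site span.
#' @param acc_engine An `accessibility_engine`.
#' @return 37 x 10 matrix of unpaired probabilities (positions x widths),
#'   flattened row-major into the feature vector.
#' @export
accessibility_profile <- function(full_mrna, site_span,
                                  acc_engine = accessibility_engine_pf()) {
  if (site_span[1] < 0 || site_span[2] > nchar(full_mrna))
    stop("site_span outside the sequence", call. = FALSE)
  acc_engine$profile(full_mrna, site_span[1], site_span[2])
}

base_freqs <- function(seq) {
  if (is.na(seq) || !nzchar(seq)) return(setNames(numeric(4), RNA_BASES))
  tab <- table(factor(chars(seq), levels = RNA_BASES))
  n <- sum(tab)
  if (n == 0) return(setNames(numeric(4), RNA_BASES))
  setNames(as.vector(tab) / n, RNA_BASES)
}

dinuc_freqs <- function(seq) {
  if (is.na(seq) || nchar(seq) < 2) return(setNames(numeric(16), DINUCS))
  v <- chars(seq)
  d <- paste0(v[-length(v)], v[-1])
  tab <- table(factor(d, levels = DINUCS))
  n <- sum(tab)
  if (n == 0) setNames(numeric(16), DINUCS) else
    setNames(as.vector(tab) / n, DINUCS)
}

gc_frac <- function(seq) {
  if (is.na(seq) || !nzchar(seq)) return(0)
  v <- chars(seq)
  mean(v %in% c("G", "C"))
}

# energy of the duplex restricted to a subset of pairs: pair energies plus
# stacking bonuses between retained pairs contiguous on both strands
pair_subset_energy <- function(mirna_seq, target_seq, mi, tj, keep) {
  if (!any(keep)) return(0)
  par <- duplex_energy_params()
  mb <- chars(mirna_seq)[mi[keep]]
  tb <- chars(target_seq)[tj[keep]]
  key <- paste0(pmin(mb, tb), pmax(mb, tb))
  pe <- c(CG = par$pair_gc, AU = par$pair_au, GU = par$pair_gu)[key]
  pe[is.na(pe)] <- 0
  stacks <- sum(diff(mi[keep]) == 1 & diff(tj[keep]) == -1)
  sum(pe) + stacks * par$stack
}

self_fold_proxy <- function(seq, engine) {
  if (is.na(seq) || nchar(seq) < 2) return(0)
  d <- engine$align(seq, seq)
  if (is.null(d) || length(d) == 0) 0 else d$mfe
}

#' Extract the 500-feature vector of one interaction record
#'
#' @param record One-row data frame (or list) with the dataset record
#'   fields, including `full_mrna_seq`, `site_start`/`site_end`,
#'   `fragment_seq`, `fragment_start`, `duplex_pairs`, `mfe_kcal_mol`,
#'   `seed_type`.
#' @param acc_engine An `accessibility_engine`.
#' @param duplex_engine A `duplex_engine` (used for the local fold proxies).
#' @return Named numeric vector of length 500 in schema order.
#' @export
extract_features <- function(record, acc_engine = accessibility_engine_pf(),
                             duplex_engine = duplex_engine_dp()) {
  r <- as.list(record)
  if (is.null(r$full_mrna_seq) || is.na(r$full_mrna_seq))
    stop("record lacks full_mrna_seq", call. = FALSE)
  mir <- r$mirna_seq
  frag <- r$fragment_seq
  full <- r$full_mrna_seq
  len <- nchar(full)
  p <- parse_pairs_string(r$duplex_pairs)
  mi <- p$mirna_pos; tj <- p$target_pos

  st <- seed_window_stats_cpp(mir, frag, mi, tj)
  w27 <- st$w2_7; w38 <- st$w3_8
  seed_f <- c(
    as.numeric(r$seed_type == "canonical"),
    as.numeric(r$seed_type == "non_canonical"),
    w27$wc, w27$gu, w27$unpaired, w27$tbulge,
    w38$wc, w38$gu, w38$unpaired, w38$tbulge,
    mean(2:8 %in% mi), gc_frac(substr(mir, 2, 8)),
    as.numeric(w27$canonical_window || w38$canonical_window))

  s0 <- r$site_start; s1 <- r$site_end
  site_seq <- substr(full, s0 + 1L, s1)
  f5_seq <- if (s0 > 0) substr(full, max(0L, s0 - 50L) + 1L, s0) else ""
  f3_seq <- if (s1 < len) substr(full, s1 + 1L, min(len, s1 + 50L)) else ""

  fe <- c(r$mfe_kcal_mol,
          pair_subset_energy(mir, frag, mi, tj, mi <= 8),
          pair_subset_energy(mir, frag, mi, tj, mi >= 9),
          r$mfe_kcal_mol / nchar(mir),
          self_fold_proxy(site_seq, duplex_engine),
          self_fold_proxy(f5_seq, duplex_engine),
          self_fold_proxy(f3_seq, duplex_engine))

  comp <- c(base_freqs(site_seq), dinuc_freqs(site_seq),
            base_freqs(f5_seq), dinuc_freqs(f5_seq),
            base_freqs(f3_seq), dinuc_freqs(f3_seq),
            gc_frac(site_seq), gc_frac(paste0(f5_seq, f3_seq)))

  mb <- chars(mir)[mi]; tb <- chars(frag)[tj]
  key <- paste0(pmin(mb, tb), pmax(mb, tb))
  wc_pos <- mi[key %in% c("AU", "CG")]
  gu_pos <- mi[key == "GU"]
  pairing <- c(as.numeric(1:22 %in% wc_pos), as.numeric(1:22 %in% gu_pos),
               length(mi), length(wc_pos), length(gu_pos),
               nchar(mir) - if (length(mi)) max(mi) else 0L)

  acc <- as.vector(t(acc_engine$profile(full, s0, s1)))

  v <- c(seed_f, fe, comp, pairing, acc)
  names(v) <- schema_names()
  v
}

# memoized schema name vector (extraction is called per record)
schema_names <- local({
  nm <- NULL
  function() {
    if (is.null(nm)) nm <<- build_schema()$name
    nm
  }
})

#' Extract the feature matrix of a dataset
#'
#' @param dataset An `mti_dataset`.
#' @param acc_engine,duplex_engine Engines as in [extract_features()].
#' @return Numeric matrix, one row per record (rownames = record ids),
#'   columns in schema order.
#' @export
extract_features_dataset <- function(dataset,
                                     acc_engine = accessibility_engine_pf(),
                                     duplex_engine = duplex_engine_dp()) {
  recs <- dataset$records
  nm <- build_schema()$name
  out <- matrix(NA_real_, nrow(recs), length(nm),
                dimnames = list(recs$record_id, nm))
  for (i in seq_len(nrow(recs)))
    out[i, ] <- extract_features(recs[i, ], acc_engine, duplex_engine)
  out
}

#' Remove negatives whose feature vector duplicates a positive
#'
#' Classification operates on features, not sequences, so a negative whose
#' full feature vector exactly equals some positive's is label noise; such
#' rows are removed.
#'
#' @param negatives,positives Feature matrices over the same schema.
#' @return The filtered negative matrix, with attribute `n_removed`.
#' @export
leakage_filter <- function(negatives, positives) {
  if (!identical(colnames(negatives), colnames(positives)))
    stop("feature schemas differ", call. = FALSE)
  ns <- round(rowSums(negatives), 9)
  ps <- round(rowSums(positives), 9)
  cand <- which(ns %in% ps)
  drop <- logical(nrow(negatives))
  if (length(cand) > 0) {
    key <- function(m) do.call(paste, c(as.data.frame(m), sep = "\r"))
    pk <- key(positives[round(rowSums(positives), 9) %in% ns[cand], ,
                        drop = FALSE])
    drop[cand] <- key(negatives[cand, , drop = FALSE]) %in% pk
  }
  out <- negatives[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}
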