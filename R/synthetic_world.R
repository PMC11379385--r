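# Seeded synthetic worlds emulating the inputs of a CLASH/CLIP/TarBase-style
# study: a mature-miRNA catalog, a 3'UTR catalog, planted positive
# (chimeric) interactions with known canonical/non-canonical truth, CLIP-like
# separate miRNA/mRNA lists, and a TarBase-like labeled table. Planted sites
# are written into the 3'UTR sequences, so the catalog carried by the world
# is the post-planting one and every record's site is literally present in
# its full mRNA at the recorded coordinates.

#' Generate a synthetic mature-miRNA catalog
#'
#' @param n Number of miRNAs (>= 1).
#' @param length_range Integer range of lengths, within 19-24 nt.
#' @param seed Optional RNG seed (the caller's RNG state is restored).
#' @return Data frame with `name` and `sequence` (i.i.d. uniform A/C/G/U).
#' @export
gen_mirna_catalog <- function(n, length_range = c(19L, 24L), seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be >= 1", call. = FALSE)
  if (length(length_range) != 2 || length_range[1] > length_range[2] ||
      length_range[1] < 19 || length_range[2] > 24)
    stop("length_range must lie within [19, 24]", call. = FALSE)
  with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    data.frame(name = sprintf("mir-%04d", seq_len(n)),
               sequence = vapply(lens, random_rna, character(1)),
               stringsAsFactors = FALSE)
  })
}

# dinucleotide bias of the UTR Markov model: CpG depletion and A/U-run
# enrichment, the dominant dinucleotide asymmetries of mammalian 3'UTRs
UTR_DINUC_BIAS <- local({
  b <- matrix(1, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  b["C", "G"] <- 0.2
  b["A", "A"] <- b["U", "U"] <- 1.5
  b["A", "U"] <- b["U", "A"] <- 1.2
  b
})

# first-order transition matrix whose stationary distribution matches the
# requested base composition under the dinucleotide bias
utr_transition <- function(base_probs, bias = UTR_DINUC_BIAS) {
  target <- base_probs
  q <- target
  for (it in 1:50) {
    trans <- sweep(bias, 2, q, "*")
    trans <- trans / rowSums(trans)
    ev <- eigen(t(trans))
    stat <- abs(Re(ev$vectors[, which.max(Re(ev$values))]))
    stat <- stat / sum(stat)
    if (max(abs(stat - target)) < 1e-10) break
    q <- q * target / stat
    q <- q / sum(q)
  }
  list(trans = trans, stationary = stat)
}

#' Generate a synthetic 3'UTR catalog
#'
#' Sequences are drawn from a first-order Markov chain whose stationary base
#' composition matches `gc_frac` and whose dinucleotide bias emulates
#' mammalian 3'UTRs (depleted CpG, enriched A/U runs) -- the structure that
#' distinguishes mono- from dinucleotide shuffling downstream.
#'
#' @param n Number of UTRs (>= 1).
#' @param length_range Integer range of lengths in nt.
#' @param gc_frac Target GC fraction, strictly between 0 and 1.
#' @param seed Optional RNG seed.
#' @return Data frame with `gene_id` and `sequence`.
#' @export
gen_utr_catalog <- function(n, length_range = c(200L, 3000L), gc_frac = 0.45,
                            seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be >= 1", call. = FALSE)
  if (!is.numeric(gc_frac) || gc_frac <= 0 || gc_frac >= 1)
    stop("gc_frac must be strictly between 0 and 1", call. = FALSE)
  if (length(length_range) != 2 || length_range[1] > length_range[2] ||
      length_range[1] < 1)
    stop("invalid length_range", call. = FALSE)
  probs <- c(A = (1 - gc_frac) / 2, C = gc_frac / 2,
             G = gc_frac / 2, U = (1 - gc_frac) / 2)
  model <- utr_transition(probs)
  with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    data.frame(gene_id = sprintf("gene-%04d", seq_len(n)),
               sequence = vapply(lens, function(L)
                 markov_rna_cpp(L, model$stationary, model$trans),
                 character(1)),
               stringsAsFactors = FALSE)
  })
}

# non-pairing target base for a given miRNA base (neither WC nor G:U)
mismatch_base <- function(mirna_base) {
  opts <- switch(mirna_base,
                 A = c("A", "C", "G"), C = c("A", "C", "U"),
                 G = c("A", "G"), U = c("C", "U"))
  sample(opts, 1)
}

# build the target-side site for one planted interaction; returns the site
# string (5'->3' on the target) whose 3' end pairs miRNA position 1
plant_site <- function(mirna_seq, canonical, end_pair_prob) {
  core <- rna_revcomp(substr(mirna_seq, 1, 9))
  if (!canonical) {
    # one G:U or one mismatch at a position hitting both windows (3..7)
    p <- sample(3:7, 1)
    idx <- 9 - p + 1  # site index pairing miRNA position p
    mb <- substr(mirna_seq, p, p)
    gu_possible <- mb %in% c("G", "U")
    if (gu_possible && runif(1) < 0.5) {
      sub <- if (mb == "G") "U" else "G"
    } else {
      sub <- mismatch_base(mb)
    }
    substr(core, idx, idx) <- sub
  }
  if (runif(1) < end_pair_prob && nchar(mirna_seq) >= 17) {
    len3 <- sample(4:8, 1)
    len3 <- min(len3, nchar(mirna_seq) - 12)
    helix <- rna_revcomp(substr(mirna_seq, 13, 12 + len3))
    spacer <- random_rna(sample(3:6, 1))
    paste0(helix, spacer, core)
  } else {
    core
  }
}

#' Plant positive interactions into a synthetic world
#'
#' For each interaction a miRNA is drawn with probability proportional to
#' rank^(-abundance_alpha) (a Zipf law over the catalog order), a target-side
#' site complementary to its 5' region (fully Watson-Crick for canonical
#' truth; with one G:U or one mismatch inside the seed windows for
#' non-canonical truth, plus optional partial 3'-end pairing) is written into
#' a randomly chosen 3'UTR, and the CLASH-style fragment around the site is
#' recorded. Coordinates are 0-based half-open on the full mRNA.
#'
#' @param world_params List with `n_interactions`, `canonical_frac`,
#'   `abundance_alpha`, `fragment_len` (default 75), `end_pair_prob`
#'   (default 0.5: chance of appending a 4-8 nt 3'-end helix).
#' @param mirnas,utrs Catalogs from [gen_mirna_catalog()]/[gen_utr_catalog()].
#' @param seed Optional RNG seed.
#' @return List: `records` (data frame of raw interaction records including
#'   the post-planting full mRNA), `utrs` (catalog with sites written in),
#'   `truth` (named vector record id -> "canonical"/"non_canonical"),
#'   `skipped` (character log of skipped plants).
#' @export
gen_positive_interactions <- function(world_params, mirnas, utrs, seed = NULL) {
  p <- world_params
  n_int <- p$n_interactions
  cf <- p$canonical_frac %||% 0.5
  alpha <- p$abundance_alpha %||% 1.0
  flen <- p$fragment_len %||% 75L
  epp <- p$end_pair_prob %||% 0.5
  if (nrow(mirnas) < 1 || nrow(utrs) < 1)
    stop("catalogs must be non-empty", call. = FALSE)
  if (cf < 0 || cf > 1) stop("canonical_frac must be in [0, 1]", call. = FALSE)

  with_seed(seed, {
    seqs <- setNames(utrs$sequence, utrs$gene_id)
    occupied <- setNames(vector("list", nrow(utrs)), utrs$gene_id)
    mir_prob <- seq_len(nrow(mirnas))^(-alpha)
    recs <- vector("list", n_int)
    truth <- character(0)
    skipped <- character(0)
    hosts <- utrs$gene_id[nchar(utrs$sequence) >= flen]

    for (i in seq_len(n_int)) {
      mi <- sample.int(nrow(mirnas), 1, prob = mir_prob)
      canonical <- runif(1) < cf
      site <- plant_site(mirnas$sequence[mi], canonical, epp)
      slen <- nchar(site)
      placed <- FALSE
      for (try in 1:10) {
        gene <- sample(hosts, 1)
        glen <- nchar(seqs[[gene]])
        if (glen < flen || glen < slen) next
        s0 <- sample.int(glen - slen + 1L, 1) - 1L  # site start, 0-based
        pad <- flen - slen
        f0 <- max(0L, s0 - pad %/% 2L)
        f1 <- f0 + flen
        if (f1 > glen) { f1 <- glen; f0 <- glen - flen }
        occ <- occupied[[gene]]
        clash <- !is.null(occ) && any(f0 < occ[, 2] & f1 > occ[, 1])
        if (clash) next
        substr(seqs[[gene]], s0 + 1L, s0 + slen) <- site
        occupied[[gene]] <- rbind(occ, c(f0, f1))
        rid <- sprintf("pos-%05d", i)
        recs[[i]] <- data.frame(
          record_id = rid, mirna_name = mirnas$name[mi],
          mirna_seq = mirnas$sequence[mi], gene_id = gene,
          site_start = s0, site_end = s0 + slen,
          fragment_start = f0, fragment_end = f1,
          stringsAsFactors = FALSE)
        truth[rid] <- if (canonical) "canonical" else "non_canonical"
        placed <- TRUE
        break
      }
      if (!placed)
        skipped <- c(skipped, sprintf("interaction %d: no placement found", i))
    }
    records <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
    if (is.null(records)) stop("no interactions could be planted", call. = FALSE)
    records$full_mrna_seq <- unname(seqs[records$gene_id])
    records$fragment_seq <- substr(records$full_mrna_seq,
                                   records$fragment_start + 1L,
                                   records$fragment_end)
    utrs$sequence <- unname(seqs[utrs$gene_id])
    list(records = records, utrs = utrs, truth = truth, skipped = skipped)
  })
}

#' Derive CLIP-style miRNA and mRNA lists from a world
#'
#' The miRNA list contains every miRNA used in the positives; the mRNA list
#' contains the planted fragments plus `extra_mrna_count` fragments sampled
#' from genes with no planted site. Fragments are 75 nt where the host
#' allows and never shorter than 40 nt.
#'
#' @param world A `synthetic_world`.
#' @param extra_mrna_count Number of extra non-interacting fragments.
#' @param seed Optional RNG seed.
#' @return List with `clip_mirnas` (name, sequence) and `clip_mrnas`
#'   (gene_id, fragment_seq, full_seq, fragment_start, fragment_end).
#' @export
gen_clip_lists <- function(world, extra_mrna_count = 0L, seed = NULL) {
  pos <- world$positives
  clip_mirnas <- unique(pos[, c("mirna_name", "mirna_seq")])
  names(clip_mirnas) <- c("name", "sequence")
  frag <- unique(pos[, c("gene_id", "fragment_start", "fragment_end")])
  utr_seq <- setNames(world$utrs$sequence, world$utrs$gene_id)
  clip_mrnas <- data.frame(
    gene_id = frag$gene_id,
    fragment_seq = substr(utr_seq[frag$gene_id], frag$fragment_start + 1L,
                          frag$fragment_end),
    full_seq = unname(utr_seq[frag$gene_id]),
    fragment_start = frag$fragment_start, fragment_end = frag$fragment_end,
    stringsAsFactors = FALSE)
  if (extra_mrna_count > 0) {
    free <- setdiff(world$utrs$gene_id, pos$gene_id)
    free <- free[nchar(utr_seq[free]) >= 40]
    with_seed(seed, {
      picks <- sample(free, min(extra_mrna_count, length(free)))
      extra <- lapply(picks, function(g) {
        glen <- nchar(utr_seq[[g]])
        w <- min(75L, glen)
        f0 <- sample.int(glen - w + 1L, 1) - 1L
        data.frame(gene_id = g,
                   fragment_seq = substr(utr_seq[[g]], f0 + 1L, f0 + w),
                   full_seq = utr_seq[[g]],
                   fragment_start = f0, fragment_end = f0 + w,
                   stringsAsFactors = FALSE)
      })
      clip_mrnas <- rbind(clip_mrnas, do.call(rbind, extra))
    })
  }
  rownames(clip_mirnas) <- rownames(clip_mrnas) <- NULL
  list(clip_mirnas = clip_mirnas, clip_mrnas = clip_mrnas)
}

#' Generate a TarBase-style labeled negative table
#'
#' Rows are unique (gene, miRNA) pairs annotated with a tissue and an
#' experimental method; a configurable fraction deliberately collides with
#' the planted positives so that downstream full-positive-dataset filtering
#' is exercised.
#'
#' @param world A `synthetic_world`.
#' @param n_rows Number of rows (>= 1).
#' @param tissues,methods Non-empty annotation vocabularies.
#' @param collision_frac Fraction of rows drawn from planted positive pairs.
#' @param seed Optional RNG seed.
#' @return Data frame: `gene_id`, `mirna_name`, `tissue`, `method`.
#' @export
gen_tarbase_table <- function(world, n_rows, tissues, methods,
                              collision_frac = 0, seed = NULL) {
  if (n_rows < 1) stop("n_rows must be >= 1", call. = FALSE)
  if (length(tissues) == 0 || length(methods) == 0)
    stop("tissues and methods must be non-empty", call. = FALSE)
  pos_pairs <- unique(paste(world$positives$gene_id,
                            world$positives$mirna_name, sep = "\r"))
  with_seed(seed, {
    n_coll <- round(collision_frac * n_rows)
    n_coll <- min(n_coll, length(pos_pairs))
    coll <- if (n_coll > 0) sample(pos_pairs, n_coll) else character(0)
    keys <- coll
    genes <- world$utrs$gene_id
    mirs <- world$mirnas$name
    guard <- 0
    while (length(keys) < n_rows) {
      need <- n_rows - length(keys)
      cand <- paste(sample(genes, need, replace = TRUE),
                    sample(mirs, need, replace = TRUE), sep = "\r")
      keys <- unique(c(keys, setdiff(cand, pos_pairs)))
      guard <- guard + 1
      if (guard > 1000) stop("could not assemble enough unique pairs",
                             call. = FALSE)
    }
    keys <- keys[seq_len(n_rows)]
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    data.frame(gene_id = parts[, 1], mirna_name = parts[, 2],
               tissue = sample(tissues, n_rows, replace = TRUE),
               method = sample(methods, n_rows, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

#' Default synthetic-world parameters
#'
#' The study conditions the package's benchmark runs under: 2,000 planted
#' positives over 300 miRNAs and 1,000 3'UTRs, an even canonical /
#' non-canonical mixture, Zipf exponent 1 for miRNA abundance, 75-nt
#' fragments, and TarBase/CLIP side-tables sized to exercise every
#' generation method.
#'
#' @return Named list of parameters accepted by [gen_world()].
#' @export
default_world_params <- function() {
  list(n_mirnas = 300L, n_utrs = 1000L, n_interactions = 2000L,
       canonical_frac = 0.5, abundance_alpha = 1.0, fragment_len = 75L,
       end_pair_prob = 0.5, gc_frac = 0.45,
       mirna_len_range = c(19L, 24L), utr_len_range = c(200L, 3000L),
       clip_extra_mrnas = 200L, tarbase_rows = 3000L,
       tarbase_collision_frac = 0.1,
       tissues = c("liver", "brain", "kidney", "heart"),
       tarbase_methods = c("microarray", "qPCR", "proteomics", "sequencing"))
}

#' Generate a complete synthetic world
#'
#' @param params Parameter list as in [default_world_params()]; missing
#'   entries take the defaults.
#' @param seed Integer seed driving every stage (sub-stage seeds are derived
#'   from it).
#' @return A `synthetic_world`: catalogs (post-planting), positive records,
#'   truth labels, CLIP lists, TarBase table, parameters and seed.
#' @export
gen_world <- function(params = list(), seed = 1L) {
  p <- utils::modifyList(default_world_params(), params)
  mirnas <- gen_mirna_catalog(p$n_mirnas, p$mirna_len_range, seed = seed + 1L)
  utrs <- gen_utr_catalog(p$n_utrs, p$utr_len_range, p$gc_frac,
                          seed = seed + 2L)
  pos <- gen_positive_interactions(
    list(n_interactions = p$n_interactions, canonical_frac = p$canonical_frac,
         abundance_alpha = p$abundance_alpha, fragment_len = p$fragment_len,
         end_pair_prob = p$end_pair_prob),
    mirnas, utrs, seed = seed + 3L)
  world <- structure(list(
    mirnas = mirnas, utrs = pos$utrs, positives = pos$records,
    truth = pos$truth, skipped = pos$skipped, params = p, seed = seed),
    class = "synthetic_world")
  clip <- gen_clip_lists(world, p$clip_extra_mrnas, seed = seed + 4L)
  world$clip_mirnas <- clip$clip_mirnas
  world$clip_mrnas <- clip$clip_mrnas
  world$tarbase_rows <- gen_tarbase_table(
    world, p$tarbase_rows, p$tissues, p$tarbase_methods,
    p$tarbase_collision_frac, seed = seed + 5L)
  world
}
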