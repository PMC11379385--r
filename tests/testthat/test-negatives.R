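# the six negative-generation methods, FPD filtering and the mixture

test_that("positive processing keeps only valid, deduplicated records", {
  pos <- small_positives()
  r <- pos$records
  expect_true(all(r$seed_type %in% c("canonical", "non_canonical")))
  key <- paste(r$mirna_name, r$gene_id, r$duplex_pairs)
  expect_false(any(duplicated(key)))
  # a duplicated raw record collapses to one output record
  raw <- small_world()$positives
  doubled <- rbind(raw, raw[1, ])
  ds <- process_positives(doubled)
  expect_equal(nrow(ds$records), nrow(pos$records))
})

test_that("mock miRNAs dodge real seeds and form valid duplexes", {
  w <- small_world()
  pos <- small_positives()
  m1 <- gen_mock_mirna(pos, w$mirnas, max_attempts = 50, seed = 5)
  r <- m1$records
  expect_lte(nrow(r), nrow(pos$records))
  expect_gt(nrow(r), 0)
  idx <- seed_window_index(w$mirnas)
  expect_false(any(vapply(r$mirna_seq, seed_collides, logical(1),
                          index = idx)))
  expect_true(all(r$seed_type %in% c("canonical", "non_canonical")))
  expect_equal(unique(r$method), "mock_mirna")
  # mock miRNA preserves the letter multiset of some source miRNA
  src <- setNames(w$mirnas$sequence, paste0(w$mirnas$name, "|mock"))
  counts <- function(s) paste(sort(strsplit(s, "")[[1]]), collapse = "")
  expect_identical(vapply(r$mirna_seq, counts, character(1), USE.NAMES = FALSE),
                   vapply(unname(src[r$mirna_name]), counts, character(1),
                          USE.NAMES = FALSE))
})

test_that("mock mRNA fragment mode shuffles site+-100 and trims 50 a side", {
  pos <- small_positives()
  sub <- pos
  # unique (gene, miRNA) sources so each mock maps back unambiguously
  keep <- !duplicated(paste(pos$records$gene_id, pos$records$mirna_name))
  sub$records <- pos$records[keep, ][1:40, ]
  m <- gen_mock_mrna(sub, "fragment", k = 2, max_attempts = 50, seed = 6)
  r <- m$records
  expect_gt(nrow(r), 0)
  expect_equal(unique(r$method), "mock_di_fragment")
  expect_true(all(r$seed_type %in% c("canonical", "non_canonical")))
  # the mock full sequence is a dinucleotide-preserving shuffle of the
  # original site region extended 100 nt per side
  counts2 <- function(s) {
    v <- strsplit(s, "")[[1]]
    sort(table(paste0(v[-length(v)], v[-1])))
  }
  orig <- sub$records
  for (i in seq_len(min(10, nrow(r)))) {
    cand <- orig[orig$gene_id == r$gene_id[i] &
                   orig$mirna_name == r$mirna_name[i], ][1, ]
    e0 <- max(0, cand$site_start - 100)
    e1 <- min(nchar(cand$full_mrna_seq), cand$site_end + 100)
    ext <- substr(cand$full_mrna_seq, e0 + 1, e1)
    expect_identical(counts2(r$full_mrna_seq[i]), counts2(ext))
    # trimmed 50 nt per side (clipped at the source bounds)
    tl <- min(50, cand$site_start - e0)
    tr <- min(50, e1 - cand$site_end)
    expect_equal(r$fragment_start[i], tl)
    expect_equal(r$fragment_end[i], nchar(ext) - tr)
  }
})

test_that("the six mock-mRNA datasets carry distinct method tags", {
  pos <- small_positives()
  sub <- pos
  sub$records <- sub$records[1:15, ]
  w <- small_world()
  tags <- character(0)
  for (mode in c("full_mrna", "fragment", "fragment_and_mirna"))
    for (k in 1:2) {
      d <- gen_mock_mrna(sub, mode, k = k, catalog = w$mirnas,
                         max_attempts = 30, seed = k * 10)
      tags <- c(tags, d$name)
      expect_true(all(d$records$method == d$name))
    }
  expect_equal(sort(tags),
               sort(c("mock_mono_mrna", "mock_di_mrna",
                      "mock_mono_fragment", "mock_di_fragment",
                      "mock_mono_fragment_mirna", "mock_di_fragment_mirna")))
})

test_that("sliding-window starts and selection rules match enumeration", {
  expect_equal(mtinegbench:::window_starts(200), c(0, 40, 80, 120))
  expect_equal(mtinegbench:::window_starts(75), 0)
  expect_equal(mtinegbench:::window_starts(74), integer(0))
  mfe <- c(-8, -12, -10)
  expect_equal(mfe[mtinegbench:::select_candidate(mfe, "min_mfe")], -12)
  expect_equal(mfe[mtinegbench:::select_candidate(mfe, "median_mfe")], -10)
  # 20th-percentile set of 3 candidates = best ceil(0.6) = 1 candidate
  set.seed(1)
  expect_equal(mfe[mtinegbench:::select_candidate(mfe, "p20_random")], -12)
  # even count: lower MFE of the two middle candidates
  expect_equal(c(-8, -12, -10, -6)[mtinegbench:::select_candidate(
    c(-8, -12, -10, -6), "median_mfe")], -10)
})

test_that("NPS CLASH negatives avoid masked positive sites", {
  pos <- small_positives()
  nps <- gen_nps_clash(pos, "min_mfe", seed = 7)
  r <- nps$records
  expect_gt(nrow(r), 0)
  p <- pos$records
  for (i in seq_len(nrow(r))) {
    own <- p[p$mirna_name == r$mirna_name[i] & p$gene_id == r$gene_id[i], ]
    a <- pmax(0, own$site_start - 10); b <- own$site_end + 10
    expect_false(any(r$site_start[i] < b & r$site_end[i] > a))
  }
  # one negative per (miRNA, gene) group at most
  expect_false(any(duplicated(paste(r$mirna_name, r$gene_id))))
})

test_that("TarBase negatives respect FPD, variants and counting", {
  w <- small_world()
  pos <- small_positives()
  fpd <- build_fpd(pos)
  tb <- gen_tarbase_negatives(w$tarbase_rows, fpd, "all", w$mirnas, w$utrs)
  key <- paste(tb$records$gene_id, tb$records$mirna_name, sep = "\r")
  expect_equal(sum(key %in% fpd$pair_index), 0)
  liver <- gen_tarbase_negatives(w$tarbase_rows, fpd, "tissue:liver",
                                 w$mirnas, w$utrs)
  lrows <- w$tarbase_rows[w$tarbase_rows$tissue == "liver", ]
  expect_true(all(paste(liver$records$gene_id, liver$records$mirna_name) %in%
                    paste(lrows$gene_id, lrows$mirna_name)))
  micro <- gen_tarbase_negatives(w$tarbase_rows, fpd, "microarray",
                                 w$mirnas, w$utrs)
  mrows <- w$tarbase_rows[w$tarbase_rows$method == "microarray", ]
  expect_true(all(paste(micro$records$gene_id, micro$records$mirna_name) %in%
                    paste(mrows$gene_id, mrows$mirna_name)))

  # 3 rows, 1 in FPD, all forming valid duplexes -> 2 outputs
  p1 <- pos$records[1, ]
  rows3 <- data.frame(
    gene_id = rep(p1$gene_id, 3),
    mirna_name = c(p1$mirna_name, w$mirnas$name[1:2]),
    tissue = "liver", method = "microarray", stringsAsFactors = FALSE)
  # force validity by using miRNAs whose duplex on this gene is valid
  out <- gen_tarbase_negatives(rows3, fpd, "all", w$mirnas, w$utrs)
  expect_false(p1$mirna_name %in% out$records$mirna_name)
  expect_lte(nrow(out$records), 2)
})

test_that("CLIP-non-CLASH forms the full product and enforces the tail cap", {
  w <- small_world()
  pos <- small_positives()
  fpd <- build_fpd(pos)
  cm <- w$clip_mrnas[1:2, ]
  ci <- w$clip_mirnas[1:2, ]
  d <- gen_clip_non_clash(ci, cm, fpd)
  expect_equal(d$summary$n_pairs, 4)  # Cartesian product before filtering
  full <- gen_clip_non_clash(w$clip_mirnas, w$clip_mrnas, fpd)
  r <- full$records
  fam <- paste(r$gene_id, substr(r$mirna_seq, 2, 8), sep = "\r")
  expect_equal(sum(fam %in% fpd$seed_family_index), 0)
  tails <- vapply(seq_len(nrow(r)), function(i)
    nchar(r$mirna_seq[i]) -
      max(mtinegbench:::parse_pairs_string(r$duplex_pairs[i])$mirna_pos),
    numeric(1))
  expect_true(all(tails <= 5))
  expect_error(gen_clip_non_clash(ci[0, ], cm, fpd), "non-empty")
})

test_that("NPS CLIP negatives stay off masked spans and out of the FPD", {
  w <- small_world()
  pos <- small_positives()
  fpd <- build_fpd(pos)
  d <- gen_nps_clip(w$clip_mirnas, w$clip_mrnas, fpd, "min_mfe",
                    max_attempts = 20, seed = 9)
  r <- d$records
  expect_gt(nrow(r), 0)
  for (i in seq_len(nrow(r))) {
    g <- r$gene_id[i]
    spans <- as.matrix(w$clip_mrnas[w$clip_mrnas$gene_id == g,
                                    c("fragment_start", "fragment_end")])
    if (!is.null(fpd$site_spans[[g]]))
      spans <- rbind(spans, fpd$site_spans[[g]])
    a <- pmax(0, spans[, 1] - 10); b <- spans[, 2] + 10
    expect_false(any(r$site_start[i] < b & r$site_end[i] > a))
  }
  fam <- paste(r$gene_id, substr(r$mirna_seq, 2, 8), sep = "\r")
  expect_equal(sum(fam %in% fpd$seed_family_index), 0)
  expect_false(any(duplicated(r$gene_id)))  # one candidate per mRNA
})

test_that("the balanced mixture draws equal quotas and keeps tags", {
  pos <- small_positives()
  w <- small_world()
  a <- gen_mock_mirna(pos, w$mirnas, max_attempts = 30, seed = 1)
  b <- gen_nps_clash(pos, "random", seed = 2)
  fpd <- build_fpd(pos)
  cc <- gen_clip_non_clash(w$clip_mirnas, w$clip_mrnas, fpd)
  mix <- combine_negatives(list(a, b, cc), 90, seed = 3)
  expect_equal(nrow(mix$records), 90)
  expect_equal(unname(table(mix$records$method)[c(a$name, b$name, cc$name)]),
               rep(30L, 3), ignore_attr = TRUE)
  mix2 <- combine_negatives(list(a, b, cc), 90, seed = 3)
  expect_equal(mix$records$duplex_pairs, mix2$records$duplex_pairs)
  expect_error(combine_negatives(list(a), 10), "at least 2")
  # quota reallocation when one dataset is too small
  tiny <- a; tiny$records <- tiny$records[1:5, ]
  expect_warning(mix3 <- combine_negatives(list(tiny, b, cc), 90, seed = 4),
                 "smaller")
  expect_equal(nrow(mix3$records), 90)
})
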