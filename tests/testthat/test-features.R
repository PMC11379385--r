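# 500-feature schema, extraction, accessibility and leakage filtering

test_that("schema has the fixed category structure", {
  s <- build_schema()
  expect_equal(nrow(s), 500)
  expect_equal(as.vector(table(s$category)[c("seed", "free_energy",
                                             "mrna_composition",
                                             "mirna_pairing",
                                             "accessibility")]),
               c(13, 7, 62, 48, 370))
  expect_false(any(duplicated(s$name)))
  expect_identical(build_schema(), s)  # idempotent
  tmp <- tempfile(fileext = ".json")
  write_schema(tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$name, s$name)
})

test_that("feature vectors are complete, finite and deterministic", {
  pos <- small_positives()
  r <- pos$records[3, ]
  v <- extract_features(r)
  expect_length(v, 500)
  expect_true(all(is.finite(v)))
  expect_identical(names(v), build_schema()$name)
  expect_identical(v, extract_features(r))
  # accessibility block within [0, 1]
  acc <- v[build_schema()$category == "accessibility"]
  expect_length(acc, 370)
  expect_true(all(acc >= 0 & acc <= 1))
  # zero G:U duplex -> all paired-GU indicators zero
  p <- mtinegbench:::parse_pairs_string(r$duplex_pairs)
  keys <- paste0(substring(r$mirna_seq, p$mirna_pos, p$mirna_pos),
                 substring(r$fragment_seq, p$target_pos, p$target_pos))
  if (!any(keys %in% c("GU", "UG")))
    expect_true(all(v[sprintf("mirna_gu_pos%02d", 1:22)] == 0))
})

test_that("composition frequencies close to one per region", {
  pos <- small_positives()
  # pick records with full 50-nt flanks on both sides
  r <- pos$records
  ok <- which(r$site_start >= 50 & r$site_end + 50 <= nchar(r$full_mrna_seq))
  for (i in head(ok, 5)) {
    v <- extract_features(r[i, ])
    for (reg in c("site", "flank5", "flank3")) {
      expect_equal(sum(v[paste0("freq_", reg, "_", c("A", "C", "G", "U"))]),
                   1, tolerance = 1e-9)
      din <- mtinegbench:::DINUCS
      expect_equal(sum(v[paste0("freq_", reg, "_", din)]), 1,
                   tolerance = 1e-9)
    }
  }
})

test_that("a poly-A site has unit accessibility everywhere", {
  m <- accessibility_profile(strrep("A", 200), c(80, 100))
  expect_equal(dim(m), c(37, 10))
  expect_true(all(m == 1))
})

test_that("accessibility matches brute-force structure enumeration", {
  eng <- accessibility_engine_pf()
  seqs <- c("GGGAAAACCCAA", "GCAUGGAAUCCAUG", "AAGGGAAAACCCUU")
  for (s in seqs) {
    m <- region_unpaired <- mtinegbench:::region_unpaired_probs_cpp(
      s, seq_len(nchar(s)), 3)
    for (pos in seq_len(nchar(s))) {
      for (w in 1:3) {
        a <- max(1, pos - w + 1)
        expect_equal(m[pos, w], oracle_unpaired_prob(s, a, pos),
                     tolerance = 1e-9,
                     label = sprintf("%s pos %d w %d", s, pos, w))
      }
    }
  }
})

test_that("accessibility profile is deterministic and clipped correctly", {
  s <- paste(rep(c("G", "C", "A", "U"), 60), collapse = "")
  m1 <- accessibility_profile(s, c(5, 25))   # site close to the 5' end
  m2 <- accessibility_profile(s, c(5, 25))
  expect_identical(m1, m2)
  expect_true(all(m1 >= 0 & m1 <= 1))
  expect_error(accessibility_profile(s, c(-2, 10)), "outside")
})

test_that("leakage filter removes exact cross-class duplicates only", {
  set.seed(1)
  pos <- matrix(rnorm(50), 5, 10, dimnames = list(NULL, letters[1:10]))
  neg <- matrix(rnorm(30), 3, 10, dimnames = list(NULL, letters[1:10]))
  out <- leakage_filter(neg, pos)
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "n_removed"), 0)
  neg2 <- rbind(neg, pos[2, , drop = FALSE])
  out2 <- leakage_filter(neg2, pos)
  expect_equal(nrow(out2), 3)
  expect_equal(attr(out2, "n_removed"), 1)
  colnames(neg2) <- rev(colnames(neg2))
  expect_error(leakage_filter(neg2, pos), "schemas differ")
})

test_that("mono shuffling perturbs dinucleotide composition more than di", {
  pos <- small_positives()
  r <- head(pos$records, 200)
  set.seed(33)
  d1 <- d2 <- numeric(nrow(r))
  for (i in seq_len(nrow(r))) {
    f <- r$fragment_seq[i]
    orig <- mtinegbench:::dinuc_freqs(f)
    d1[i] <- mean(abs(mtinegbench:::dinuc_freqs(shuffle_kmer(f, 1)) - orig))
    d2[i] <- mean(abs(mtinegbench:::dinuc_freqs(shuffle_kmer(f, 2)) - orig))
  }
  expect_gt(mean(d1), mean(d2))
})
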