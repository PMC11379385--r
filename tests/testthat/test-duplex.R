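# duplex engine and the seed/density validity scheme

test_that("engine handles perfect complements, impossible pairs and N", {
  d <- compute_duplex("UUUUUU", "AAAAAA")
  expect_equal(nrow(d$pairs), 6)
  expect_equal(d$pairs$mirna_pos, 1:6)
  expect_equal(d$pairs$target_pos, 6:1)  # antiparallel
  expect_lt(d$mfe, 0)

  expect_null(compute_duplex("AAAA", "AAAA"))    # no legal A:A pair
  expect_null(compute_duplex("UUUUUU", "NNNNNN"))  # N unpairable
  expect_error(compute_duplex("UUXU", "AAAA"), "characters")
})

test_that("duplexes satisfy the antiparallel pair-map invariants", {
  set.seed(7)
  legal <- c(AU = TRUE, UA = TRUE, GC = TRUE, CG = TRUE, GU = TRUE, UG = TRUE)
  for (i in 1:100) {
    mir <- paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = "")
    tgt <- paste(sample(c("A", "C", "G", "U"), 75, TRUE), collapse = "")
    d <- compute_duplex(mir, tgt)
    if (is.null(d)) next
    expect_true(all(diff(d$pairs$mirna_pos) >= 1))
    expect_true(all(diff(d$pairs$target_pos) <= -1))
    expect_lte(d$mfe, 0)
    keys <- paste0(substring(mir, d$pairs$mirna_pos, d$pairs$mirna_pos),
                   substring(tgt, d$pairs$target_pos, d$pairs$target_pos))
    expect_true(all(keys %in% names(legal)))
    expect_equal(d$site_span,
                 c(min(d$pairs$target_pos) - 1L, max(d$pairs$target_pos)))
  }
})

test_that("engine MFE is at least as low as any contiguous helix", {
  set.seed(11)
  for (i in 1:60) {
    mir <- paste(sample(c("A", "C", "G", "U"), sample(10:20, 1), TRUE),
                 collapse = "")
    tgt <- paste(sample(c("A", "C", "G", "U"), sample(10:30, 1), TRUE),
                 collapse = "")
    d <- compute_duplex(mir, tgt)
    hx <- oracle_best_helix(mir, tgt)
    if (hx < 0) {
      expect_false(is.null(d))
      expect_lte(d$mfe, hx + 1e-9)
    }
  }
})

test_that("engine output is deterministic", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  tgt <- "ACCAUACAACCUACUACCUCAGGGAAUGUAAGGAUCCGAUA"
  expect_identical(compute_duplex(mir, tgt), compute_duplex(mir, tgt))
})

# target whose letters Watson-Crick-complement the miRNA at each given pair
build_target <- function(mir, mi, tj, len = 40) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  v <- rep("A", len)
  mirv <- strsplit(mir, "")[[1]]
  v[tj] <- comp[mirv[mi]]
  paste(v, collapse = "")
}

test_that("seed classification follows the window rules", {
  mir <- "AGCAUGCAUAGCAUGCAUAGCA"
  # contiguous WC helix over miRNA 1..9 at target 30..22 -> canonical
  can <- fake_duplex(1:9, 30:22)
  tgt <- build_target(mir, 1:9, 30:22)
  expect_equal(classify_seed(can, mir, tgt), "canonical")

  # one G:U in each window, no bulge -> non-canonical
  tgt_gu <- tgt
  substr(tgt_gu, 29, 29) <- "U"  # partner of miRNA pos 2 (G) -> G:U
  substr(tgt_gu, 26, 26) <- "G"  # partner of miRNA pos 5 (U) -> U:G
  expect_equal(classify_seed(can, mir, tgt_gu), "non_canonical")

  # two unpaired positions in both windows -> other
  two_gaps <- fake_duplex(c(1, 2, 3, 8, 9), c(30, 29, 28, 23, 22))
  expect_equal(classify_seed(two_gaps, mir,
                             build_target(mir, c(1, 2, 3, 8, 9),
                                          c(30, 29, 28, 23, 22))), "other")

  expect_error(classify_seed(can, "ACGUACGU", tgt), "shorter than 9")
})

test_that("mismatch or single bulge keeps a window non-canonical", {
  mir <- "AGCAUGCAUAGCAUGCAUAGCA"

  # miRNA position 5 unpaired and one target position skipped: 1x1 loop
  mm_mi <- c(1:4, 6:9); mm_tj <- c(30:27, 25:22)
  mm <- fake_duplex(mm_mi, mm_tj)
  expect_equal(classify_seed(mm, mir, build_target(mir, mm_mi, mm_tj)),
               "non_canonical")

  # one extra (bulged) target nucleotide between partners of pos 4 and 5
  bg_mi <- 1:9; bg_tj <- c(31:28, 26:22)
  bg <- fake_duplex(bg_mi, bg_tj)
  expect_equal(classify_seed(bg, mir, build_target(mir, bg_mi, bg_tj)),
               "non_canonical")

  # two bulged target nucleotides -> other
  b2_mi <- 1:9; b2_tj <- c(32:29, 26:22)
  b2 <- fake_duplex(b2_mi, b2_tj)
  expect_equal(classify_seed(b2, mir, build_target(mir, b2_mi, b2_tj)),
               "other")
})

test_that("density classes split at 11 and 16 pairs", {
  mk <- function(n) fake_duplex(1:n, (n + 10):11)
  expect_equal(classify_density(mk(10)), "low")
  expect_equal(classify_density(mk(11)), "medium")
  expect_equal(classify_density(mk(16)), "medium")
  expect_equal(classify_density(mk(17)), "high")
})

test_that("validity and tail length follow their definitions", {
  d <- compute_duplex("UUUUUU", "AAAAAA")
  d$seed_type <- "canonical"
  expect_true(is_valid_interaction(d))
  d$seed_type <- "other"
  expect_false(is_valid_interaction(d))
  expect_false(is_valid_interaction(NULL))

  dd <- fake_duplex(c(2, 3, 16), c(40, 39, 20))
  expect_equal(unpaired_tail_length(dd, 22), 6)
  dd2 <- fake_duplex(c(2, 22), c(40, 20))
  expect_equal(unpaired_tail_length(dd2, 22), 0)
  empty <- fake_duplex(integer(0), integer(0))
  empty$pairs <- empty$pairs[0, ]
  expect_equal(unpaired_tail_length(empty, 22), 22)
})

test_that("every duplex gets exactly one seed type and one density class", {
  set.seed(3)
  n_seen <- 0
  for (i in 1:200) {
    mir <- paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = "")
    tgt <- paste(sample(c("A", "C", "G", "U"), 75, TRUE), collapse = "")
    d <- compute_duplex(mir, tgt)
    if (is.null(d)) next
    n_seen <- n_seen + 1
    expect_true(d$seed_type %in% c("canonical", "non_canonical", "other"))
    expect_true(d$density_class %in% c("low", "medium", "high"))
  }
  expect_gt(n_seen, 100)
})

test_that("the RNAduplex adapter parses structures into legal pair maps", {
  skip_if(Sys.which("RNAduplex") == "", "RNAduplex not on PATH")
  eng <- duplex_engine_rnaduplex()
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  tgt <- "CUAUACAACCUACUACCUCAAUGGAUUUUUGGGACGG"
  d <- compute_duplex(mir, tgt, engine = eng)
  expect_false(is.null(d))
  expect_true(all(diff(d$pairs$mirna_pos) >= 1))
  expect_true(all(diff(d$pairs$target_pos) <= -1))
  keys <- paste0(substring(mir, d$pairs$mirna_pos, d$pairs$mirna_pos),
                 substring(tgt, d$pairs$target_pos, d$pairs$target_pos))
  expect_true(all(keys %in% c("AU", "UA", "GC", "CG", "GU", "UG")))
  expect_lt(d$mfe, 0)
})
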