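# synthetic world generation: catalogs, planted positives, CLIP/TarBase

test_that("miRNA catalog obeys alphabet, length and determinism contracts", {
  expect_error(gen_mirna_catalog(0), "n must be")
  expect_error(gen_mirna_catalog(5, c(10, 30)), "length_range")
  a <- gen_mirna_catalog(50, seed = 7)
  b <- gen_mirna_catalog(50, seed = 7)
  expect_identical(a, b)
  expect_true(all(grepl("^[ACGU]{19,24}$", a$sequence)))
  expect_false(any(duplicated(a$name)))
})

test_that("UTR catalog matches the requested GC content", {
  expect_error(gen_utr_catalog(10, gc_frac = 0), "gc_frac")
  u <- gen_utr_catalog(100, gc_frac = 0.4, seed = 1)
  expect_equal(nrow(u), 100)
  expect_false(any(duplicated(u$gene_id)))
  pooled <- paste(u$sequence, collapse = "")
  gc <- mean(strsplit(pooled, "")[[1]] %in% c("G", "C"))
  expect_gt(gc, 0.35)
  expect_lt(gc, 0.45)
})

test_that("planted positives satisfy coordinate closure and truth labels", {
  w <- small_world()
  r <- w$positives
  # fragment is literally the recorded substring of the full mRNA
  expect_identical(r$fragment_seq,
                   substr(r$full_mrna_seq, r$fragment_start + 1,
                          r$fragment_end))
  # site inside fragment inside mRNA
  expect_true(all(r$site_start >= r$fragment_start))
  expect_true(all(r$site_end <= r$fragment_end))
  expect_true(all(r$fragment_end <= nchar(r$full_mrna_seq)))
  expect_true(all(w$truth %in% c("canonical", "non_canonical")))
  # the world's UTR catalog is the post-planting one
  utr <- setNames(w$utrs$sequence, w$utrs$gene_id)
  expect_identical(r$full_mrna_seq, unname(utr[r$gene_id]))
})

test_that("world generation is deterministic under a fixed seed", {
  p <- list(n_mirnas = 30, n_utrs = 60, n_interactions = 60,
            clip_extra_mrnas = 10, tarbase_rows = 100)
  expect_identical(gen_world(p, seed = 9), gen_world(p, seed = 9))
})

test_that("canonical_frac = 1 forces canonical truth and high recovery", {
  p <- gen_positive_interactions(
    list(n_interactions = 200, canonical_frac = 1, abundance_alpha = 1),
    gen_mirna_catalog(40, seed = 2), gen_utr_catalog(80, seed = 3), seed = 4)
  expect_true(all(p$truth == "canonical"))
  ds <- process_positives(p$records)
  expect_gte(nrow(ds$records) / nrow(p$records), 0.95)
  expect_gte(mean(ds$records$seed_type == "canonical"), 0.95)
})

test_that("uniform miRNA abundance gives a CDF-90 fraction near 0.9", {
  mir <- gen_mirna_catalog(50, seed = 5)
  utr <- gen_utr_catalog(100, seed = 6)
  p <- gen_positive_interactions(
    list(n_interactions = 1000, canonical_frac = 0.5, abundance_alpha = 0),
    mir, utr, seed = 7)
  obs <- mirna_cdf90(p$records$mirna_seq)$fraction
  # oracle: multinomial sampling with equal probabilities
  oracle <- replicate(200, {
    draws <- sample(mir$sequence, 1000, replace = TRUE)
    mirna_cdf90(draws)$fraction
  })
  expect_gt(obs, quantile(oracle, 0.005))
  expect_lte(obs, max(1, quantile(oracle, 0.995)))
})

test_that("CLIP lists cover the positives and respect fragment bounds", {
  w <- small_world()
  cl0 <- gen_clip_lists(w, extra_mrna_count = 0)
  expect_true(all(cl0$clip_mrnas$gene_id %in% w$positives$gene_id))
  expect_true(all(w$positives$mirna_seq %in% cl0$clip_mirnas$sequence))
  cl <- gen_clip_lists(w, extra_mrna_count = 30, seed = 8)
  expect_true(all(nchar(cl$clip_mrnas$fragment_seq) >= 40))
  expect_true(all(nchar(cl$clip_mrnas$fragment_seq) <= 75))
  expect_identical(cl, gen_clip_lists(w, extra_mrna_count = 30, seed = 8))
})

test_that("TarBase table plants the exact collision count, no duplicates", {
  w <- small_world()
  tb <- gen_tarbase_table(w, 500, tissues = c("liver", "brain"),
                          methods = c("microarray", "qPCR"),
                          collision_frac = 0.1, seed = 3)
  expect_equal(nrow(tb), 500)
  key <- paste(tb$gene_id, tb$mirna_name)
  expect_false(any(duplicated(key)))
  pos_key <- unique(paste(w$positives$gene_id, w$positives$mirna_name))
  expect_equal(sum(key %in% pos_key), round(0.1 * 500))
  tb0 <- gen_tarbase_table(w, 200, "liver", "qPCR",
                           collision_frac = 0, seed = 4)
  expect_equal(sum(paste(tb0$gene_id, tb0$mirna_name) %in% pos_key), 0)
  expect_error(gen_tarbase_table(w, 10, character(0), "x"), "non-empty")
})
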