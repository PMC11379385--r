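# split protocol, metrics, classifiers, distribution statistics

test_that("split plan: 20 repeats, 80/20, shared positives, disjoint sets", {
  plan <- make_split_plan(100, c(a = 150, b = 100), repeats = 20,
                          base_seed = 5)
  expect_length(plan$repeats, 20)
  r1 <- plan$repeats[[1]]
  expect_length(r1$pos_test, 20)
  expect_length(r1$pos_train, 80)
  expect_length(intersect(r1$pos_train, r1$pos_test), 0)
  for (rp in plan$repeats) {
    for (ds in c("a", "b")) {
      nn <- rp$neg[[ds]]
      expect_length(intersect(nn$train, nn$test), 0)
      expect_lte(length(nn$train) + length(nn$test), 100)  # undersampled
    }
  }
  # the positive partition is the plan-level contract shared by datasets
  plan2 <- make_split_plan(100, c(a = 150), repeats = 20, base_seed = 5)
  expect_identical(lapply(plan$repeats, `[[`, "pos_test"),
                   lapply(plan2$repeats, `[[`, "pos_test"))
  expect_error(make_split_plan(100, c(a = 1)), "smaller")
  expect_warning(make_split_plan(100, c(a = 50)), "kept in full")
})

test_that("metric formulas match hand-computed confusion examples", {
  m <- compute_metrics(tp = 8, fn = 2, tn = 6, fp = 4)
  expect_equal(unname(m["tpr"]), 0.8)
  expect_equal(unname(m["tnr"]), 0.6)
  expect_equal(unname(m["acc"]), 0.7)
  expect_equal(unname(m["f1"]), 0.7273, tolerance = 1e-4)
  perfect <- compute_metrics(10, 0, 10, 0)
  expect_true(all(perfect[c("acc", "tpr", "tnr", "f1")] == 1))
  expect_true(all(perfect[c("fpr", "fnr")] == 0))
  none <- compute_metrics(0, 0, 5, 0)
  expect_true(is.na(none["tpr"]))
})

test_that("a classifier on permuted labels scores near chance", {
  set.seed(9)
  n <- 400
  X <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(NULL, paste0("f", 1:20)))
  y <- sample(rep(0:1, n / 2))
  te <- sample.int(n, 80)
  model <- mtinegbench:::fit_xgb(X[-te, ], y[-te],
                                 list(max_depth = 3, eta = 0.3, nrounds = 30))
  acc <- mean(as.numeric(mtinegbench:::predict_xgb(model, X[te, ]) > 0.5) ==
                y[te])
  sigma <- sqrt(0.25 / 80)
  expect_lt(abs(acc - 0.5), 3.5 * sigma)
})

test_that("cross-matrix TPR is identical across test datasets per repeat", {
  set.seed(10)
  n <- 120
  mk <- function(shift) matrix(rnorm(n * 10, shift), n, 10,
                               dimnames = list(NULL, paste0("f", 1:10)))
  pos <- mk(1)
  feats <- list(a = mk(-1), b = mk(0))
  plan <- make_split_plan(n, c(a = n, b = n), repeats = 3, base_seed = 1)
  cm <- cross_matrix(pos, feats, plan,
                     list(max_depth = 3, eta = 0.3, nrounds = 30))
  pr <- cm$per_repeat
  for (tr in c("a", "b")) for (r in 1:3) {
    tprs <- pr$tpr[pr$train == tr & pr$rep == r]
    expect_equal(diff(range(tprs)), 0)
  }
  expect_equal(nrow(cm$mean), 4)  # 2x2 cells
  # diagonal equals the dedicated intra evaluation
  ep <- evaluate_pair("a", "a", pos, feats, plan,
                      list(max_depth = 3, eta = 0.3, nrounds = 30))
  expect_equal(unname(ep$mean["acc"]),
               cm$mean$acc[cm$mean$train == "a" & cm$mean$test == "a"])
})

test_that("KL divergence matches closed forms and is asymmetric", {
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  # P concentrated on x, Q uniform on {x, y}
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(kl_divergence(c(0.5, 0.5), c(0.9, 0.1)),
                                kl_divergence(c(0.9, 0.1), c(0.5, 0.5)))))
  expect_error(kl_divergence(c(0.5, 0.5), c(1)), "supports")
  expect_error(kl_divergence(c(2, 1), c(0.5, 0.5)), "probability")
  # smoothed distributions are well-formed and give non-negative divergence
  set.seed(2)
  for (i in 1:20) {
    sa <- sample(letters[1:6], 30, TRUE)
    sb <- sample(letters[4:9], 30, TRUE)
    d <- mirna_distributions(sa, sb, pseudocount = 0.5)
    expect_equal(sum(d$p), 1, tolerance = 1e-9)
    expect_gte(kl_divergence(d$p, d$q), 0)
  }
  expect_error(mirna_distributions(c("a"), c("b"), pseudocount = 0),
               "pseudocount")
})

test_that("CDF-90 uses a strict threshold", {
  x <- c(rep("m1", 91), paste0("m", 2:10))
  expect_equal(mirna_cdf90(x)$n_mirnas, 1)
  expect_equal(mirna_cdf90(x)$fraction, 0.1)
  y <- c(rep("m1", 9), "m2")  # 9/10 is not strictly > 0.9
  expect_equal(mirna_cdf90(y)$n_mirnas, 2)
  expect_equal(mirna_cdf90(y)$fraction, 1.0)
  expect_equal(mirna_cdf90("m1")$n_mirnas, 1)
  expect_equal(mirna_cdf90("m1")$fraction, 1.0)
})

test_that("SHAP comparison: self-comparison is null, threshold rule holds", {
  set.seed(4)
  n <- 200
  X <- matrix(rnorm(n * 15), n, 15, dimnames = list(NULL, paste0("f", 1:15)))
  y <- as.numeric(X[, 1] + rnorm(n, 0, 0.5) > 0)
  model <- mtinegbench:::fit_xgb(X, y, list(max_depth = 3, eta = 0.3,
                                            nrounds = 30))
  self <- shap_compare(model, X, model, X, k = 10)
  expect_equal(self$p_value, 1)
  expect_equal(self$neg_log10, 0)  # p > 0.05 reported as 0
  imp <- shap_importance(model, X)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_equal(names(which.max(imp)), "f1")
})

test_that("two-negative probe: indistinguishable halves score near chance, a
          composition signal is detected", {
  set.seed(6)
  n <- 300
  base <- matrix(rnorm(2 * n * 12), 2 * n, 12,
                 dimnames = list(NULL, paste0("f", 1:12)))
  same <- two_negative_eval(base[1:n, ], base[(n + 1):(2 * n), ], seed = 1)
  sigma <- sqrt(0.25 / (2 * round(0.2 * n)))
  expect_lt(abs(same["acc"] - 0.5), 4 * sigma)
  shifted <- base[(n + 1):(2 * n), ]
  shifted[, 1] <- shifted[, 1] + 2
  diffr <- two_negative_eval(base[1:n, ], shifted, seed = 1)
  expect_gt(diffr["acc"], 0.5 + 3 * sigma)
  expect_true(all(c("fpr", "fnr") %in% names(diffr)))
})

test_that("isolation forest separates an obvious outlier cluster", {
  set.seed(8)
  X <- matrix(rnorm(200 * 5), 200, 5)
  model <- iforest_fit(X, n_trees = 50, sample_size = 64, seed = 1)
  inl <- iforest_score(model, X)
  out <- iforest_score(model, matrix(8, 10, 5))
  expect_gt(min(out), max(0.5, mean(inl)))
})

test_that("one-class models train on positives only and report 4x5 results", {
  set.seed(12)
  n <- 150
  pos <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  neg <- matrix(rnorm(n * 8, 2.5), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  plan <- make_split_plan(n, c(d = n), repeats = 2, base_seed = 3)
  res <- one_class_comparison(pos, neg, plan, "d")
  expect_equal(sort(unique(res$summary$model)),
               sort(c("one_class_svm", "svm", "isolation_forest",
                      "random_forest")))
  expect_true(all(c("acc", "auc", "tpr", "tnr", "fpr") %in%
                    names(res$summary)))
  # well-separated classes: the binary models see the negatives, so their
  # TNR must be high
  expect_gt(res$summary$tnr[res$summary$model == "svm"], 0.9)
  expect_gt(res$summary$tnr[res$summary$model == "random_forest"], 0.9)
})

test_that("duplex class distribution has six cells summing to one", {
  pos <- small_positives()
  d <- duplex_class_distribution(pos)
  expect_equal(dim(d), c(2, 3))
  expect_equal(sum(d), 1, tolerance = 1e-9)
  sub <- pos
  sub$records <- sub$records[sub$records$seed_type == "canonical", ]
  d2 <- duplex_class_distribution(sub)
  expect_true(all(d2["non_canonical", ] == 0))
})
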