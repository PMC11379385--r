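# The benchmark harness: shared-positive repeated splits, binary gradient
# boosting (intra- and cross-dataset), one-class comparisons, SHAP-based
# model comparison, miRNA-distribution statistics and duplex-class summaries.
#
# The split protocol: every negative dataset is undersampled to the positive
# count and split 80/20, 20 times; for a given repeat the positive partition
# is identical across all negative datasets, so a fixed classifier evaluated
# on different test datasets sees exactly the same positive test rows (TPR
# depends only on those).

#' Build the repeated shared-positive split plan
#'
#' @param n_pos Number of positive records.
#' @param neg_sizes Named integer vector of negative-dataset sizes.
#' @param repeats Number of split repeats (default 20).
#' @param test_frac Test fraction (default 0.2).
#' @param base_seed Base RNG seed; repeat r uses `base_seed + r`.
#' @return A `split_plan`: list of repeats, each with `pos_train`,
#'   `pos_test` and per-dataset `neg` index lists (indices into the original
#'   negative matrices, after undersampling to `n_pos`).
#' @export
make_split_plan <- function(n_pos, neg_sizes, repeats = 20L, test_frac = 0.2,
                            base_seed = 0L) {
  if (n_pos < 2) stop("need at least 2 positives", call. = FALSE)
  n_test <- round(test_frac * n_pos)
  if (n_test < 1 || n_test >= n_pos)
    stop("test fraction leaves an empty train or test set", call. = FALSE)
  small <- neg_sizes < n_pos
  if (any(neg_sizes < 2))
    stop("negative dataset smaller than required test size", call. = FALSE)
  if (any(small))
    warning("datasets smaller than the positive set are kept in full: ",
            paste(names(neg_sizes)[small], collapse = ", "), call. = FALSE)
  reps <- lapply(seq_len(repeats), function(r) {
    with_seed(base_seed + r, {
      pos_test <- sort(sample.int(n_pos, n_test))
      neg <- lapply(neg_sizes, function(nn) {
        sub <- if (nn > n_pos) sort(sample.int(nn, n_pos)) else seq_len(nn)
        nt <- round(test_frac * length(sub))
        te <- sort(sample(sub, nt))
        list(train = setdiff(sub, te), test = te)
      })
      list(pos_train = setdiff(seq_len(n_pos), pos_test),
           pos_test = pos_test, neg = neg)
    })
  })
  structure(list(repeats = reps, n_pos = n_pos, neg_sizes = neg_sizes,
                 test_frac = test_frac, base_seed = base_seed),
            class = "split_plan")
}

#' Classification metrics from confusion counts
#'
#' @param tp,fn,tn,fp Non-negative confusion counts.
#' @return Named numeric vector `acc`, `tpr`, `tnr`, `fpr`, `fnr`, `f1`
#'   (undefined ratios are `NA`).
#' @export
compute_metrics <- function(tp, fn, tn, fp) {
  total <- tp + fn + tn + fp
  if (total == 0) stop("empty confusion table", call. = FALSE)
  sdiv <- function(a, b) if (b > 0) a / b else NA_real_
  tpr <- sdiv(tp, tp + fn)
  tnr <- sdiv(tn, tn + fp)
  prec <- sdiv(tp, tp + fp)
  f1 <- if (!is.na(prec) && !is.na(tpr) && (prec + tpr) > 0)
    2 * prec * tpr / (prec + tpr) else NA_real_
  c(acc = (tp + tn) / total, tpr = tpr, tnr = tnr,
    fpr = if (is.na(tnr)) NA_real_ else 1 - tnr,
    fnr = if (is.na(tpr)) NA_real_ else 1 - tpr, f1 = f1)
}

metrics_from_pred <- function(pred, truth) {
  compute_metrics(tp = sum(pred == 1 & truth == 1),
                  fn = sum(pred == 0 & truth == 1),
                  tn = sum(pred == 0 & truth == 0),
                  fp = sum(pred == 1 & truth == 0))
}

# rank-based AUC (Mann-Whitney); scores larger for the positive class
auc_score <- function(scores, truth) {
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Default gradient-boosting hyperparameters
#'
#' @return List with `max_depth`, `eta`, `nrounds` (library defaults used
#'   for the two-negative-class probe).
#' @export
default_xgb_params <- function() list(max_depth = 6L, eta = 0.3, nrounds = 100L)

fit_xgb <- function(X, y, params = default_xgb_params()) {
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = params$max_depth,
                  eta = params$eta, nthread = 1),
    data = xgboost::xgb.DMatrix(X, label = y), nrounds = params$nrounds,
    verbose = 0)
}

predict_xgb <- function(model, X) {
  predict(model, xgboost::xgb.DMatrix(X))
}

#' Grid-search hyperparameters for the gradient-boosting classifier
#'
#' 5-fold cross-validated grid search minimizing classification error.
#'
#' @param X,y Training matrix and 0/1 labels.
#' @param grid Data frame of candidate `max_depth`, `eta`, `nrounds`.
#' @param nfolds Number of folds.
#' @param seed RNG seed for the fold assignment.
#' @return The best row of `grid` as a list.
#' @export
tune_xgboost <- function(X, y,
                         grid = expand.grid(max_depth = c(3L, 6L),
                                            eta = c(0.05, 0.1),
                                            nrounds = c(100L, 300L)),
                         nfolds = 5L, seed = 0L) {
  errs <- vapply(seq_len(nrow(grid)), function(g) {
    cv <- with_seed(seed, xgboost::xgb.cv(
      params = list(objective = "binary:logistic",
                    max_depth = grid$max_depth[g], eta = grid$eta[g],
                    nthread = 1, eval_metric = "error"),
      data = xgboost::xgb.DMatrix(X, label = y), nrounds = grid$nrounds[g],
      nfold = nfolds, verbose = 0))
    ev <- cv$evaluation_log
    ev$test_error_mean[nrow(ev)]
  }, numeric(1))
  as.list(grid[which.min(errs), ])
}

# assemble train/test matrices for one repeat
split_xy <- function(pos_X, neg_X, rep_plan, ds, part) {
  ni <- rep_plan$neg[[ds]][[part]]
  pi <- rep_plan[[paste0("pos_", part)]]
  list(X = rbind(pos_X[pi, , drop = FALSE], neg_X[ni, , drop = FALSE]),
       y = rep(c(1, 0), c(length(pi), length(ni))))
}

#' Train/test one (train-dataset, test-dataset) pair over all repeats
#'
#' A gradient-boosted classifier is trained per repeat on the training split
#' of `train_ds` and evaluated on the test split of `test_ds`; positives are
#' shared.
#'
#' @param train_ds,test_ds Negative dataset names (keys of `features`).
#' @param pos_X Positive feature matrix.
#' @param features Named list of negative feature matrices.
#' @param plan A `split_plan` over these datasets.
#' @param xgb_params Hyperparameters (see [default_xgb_params()]).
#' @return List with `per_repeat` (metric rows) and `mean`/`sd` vectors.
#' @export
evaluate_pair <- function(train_ds, test_ds, pos_X, features, plan,
                          xgb_params = default_xgb_params()) {
  rows <- lapply(seq_along(plan$repeats), function(r) {
    rp <- plan$repeats[[r]]
    tr <- split_xy(pos_X, features[[train_ds]], rp, train_ds, "train")
    te <- split_xy(pos_X, features[[test_ds]], rp, test_ds, "test")
    model <- fit_xgb(tr$X, tr$y, xgb_params)
    metrics_from_pred(as.numeric(predict_xgb(model, te$X) > 0.5), te$y)
  })
  per_repeat <- do.call(rbind, rows)
  list(train = train_ds, test = test_ds, per_repeat = per_repeat,
       mean = colMeans(per_repeat), sd = apply(per_repeat, 2, sd))
}

#' Full cross-dataset evaluation matrix
#'
#' For every training dataset, one classifier is fitted per repeat and then
#' evaluated on the test splits of every dataset (so the positive test rows
#' -- and hence the TPR -- are identical across test datasets for a fixed
#' classifier and repeat).
#'
#' @inheritParams evaluate_pair
#' @param xgb_params Either one parameter list for all datasets or a named
#'   list of per-training-dataset parameter lists.
#' @return List: `per_repeat` (long data frame train/test/repeat/metrics)
#'   and `summary` (mean and sd per train/test/metric).
#' @export
cross_matrix <- function(pos_X, features, plan,
                         xgb_params = default_xgb_params()) {
  ds <- names(features)
  per_ds_params <- !is.null(names(xgb_params)) &&
    all(ds %in% names(xgb_params))
  rows <- list()
  for (tr_ds in ds) {
    pars <- if (per_ds_params) xgb_params[[tr_ds]] else xgb_params
    for (r in seq_along(plan$repeats)) {
      rp <- plan$repeats[[r]]
      tr <- split_xy(pos_X, features[[tr_ds]], rp, tr_ds, "train")
      model <- fit_xgb(tr$X, tr$y, pars)
      for (te_ds in ds) {
        te <- split_xy(pos_X, features[[te_ds]], rp, te_ds, "test")
        m <- metrics_from_pred(as.numeric(predict_xgb(model, te$X) > 0.5),
                               te$y)
        rows[[length(rows) + 1]] <- data.frame(
          train = tr_ds, test = te_ds, rep = r, t(m),
          stringsAsFactors = FALSE)
      }
    }
  }
  per_repeat <- do.call(rbind, rows)
  agg <- function(f) stats::aggregate(
    per_repeat[, c("acc", "tpr", "tnr", "fpr", "fnr", "f1")],
    by = list(train = per_repeat$train, test = per_repeat$test), FUN = f)
  list(per_repeat = per_repeat, mean = agg(mean),
       sd = agg(stats::sd))
}

#' Mean-|SHAP| feature attribution of a fitted model
#'
#' TreeSHAP contributions averaged over a data matrix, as absolute values
#' normalized to sum to one.
#'
#' @param model A fitted xgboost booster.
#' @param X Feature matrix.
#' @return Named numeric vector over the schema features.
#' @export
shap_importance <- function(model, X) {
  contrib <- predict(model, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
  v <- colMeans(abs(contrib[, -ncol(contrib), drop = FALSE]))
  if (sum(v) > 0) v / sum(v) else v
}

#' Compare two models' top-feature SHAP profiles
#'
#' The union of each model's top-k features (by normalized mean-|SHAP|) is
#' taken and a paired Wilcoxon signed-rank test compares the two normalized
#' attribution vectors over that union; a Bonferroni factor (the number of
#' model pairs compared in the enclosing analysis) corrects the p-value.
#'
#' @param model_a,model_b Fitted boosters on the shared schema.
#' @param X_a,X_b Matrices to average attributions over.
#' @param k Top-feature count per model (default 100).
#' @param n_comparisons Bonferroni factor.
#' @return List `p_value`, `p_adjusted`, `neg_log10` (0 when the corrected
#'   p exceeds 0.05), `union_size`.
#' @export
shap_compare <- function(model_a, X_a, model_b, X_b, k = 100L,
                         n_comparisons = 1L) {
  sa <- shap_importance(model_a, X_a)
  sb <- shap_importance(model_b, X_b)
  un <- union(names(sort(sa, decreasing = TRUE))[seq_len(min(k, length(sa)))],
              names(sort(sb, decreasing = TRUE))[seq_len(min(k, length(sb)))])
  if (length(un) < 2)
    return(list(p_value = NA_real_, p_adjusted = NA_real_,
                neg_log10 = NA_real_, union_size = length(un)))
  d <- sa[un] - sb[un]
  p <- if (all(d == 0)) 1 else
    suppressWarnings(wilcox.test(sa[un], sb[un], paired = TRUE)$p.value)
  padj <- min(1, p * n_comparisons)
  list(p_value = p, p_adjusted = padj,
       neg_log10 = if (padj > 0.05) 0 else -log10(padj),
       union_size = length(un))
}

#' miRNA concentration: how few miRNAs carry 90% of the interactions
#'
#' miRNA sequences are counted and sorted by descending count; the smallest
#' prefix whose cumulative share strictly exceeds 0.9 is reported, as a
#' count and as a fraction of distinct miRNAs.
#'
#' @param mirna_seqs Character vector of the dataset's miRNA sequences (one
#'   entry per interaction).
#' @return List `n_mirnas`, `fraction`, `n_distinct`.
#' @export
mirna_cdf90 <- function(mirna_seqs) {
  if (length(mirna_seqs) == 0) stop("empty dataset", call. = FALSE)
  cnt <- sort(table(mirna_seqs), decreasing = TRUE)
  cum <- cumsum(cnt) / sum(cnt)
  n <- unname(which(cum > 0.9)[1])
  list(n_mirnas = as.integer(n), fraction = n / length(cnt),
       n_distinct = length(cnt))
}

#' Smoothed miRNA-sequence distributions of two datasets
#'
#' Distributions over the union support of both datasets' miRNA sequences,
#' with an additive pseudocount applied to the counts before normalizing.
#'
#' @param seqs_p,seqs_q miRNA sequence vectors of the target (P) and source
#'   (Q) datasets.
#' @param pseudocount Additive smoothing (default 0.5); must be positive
#'   when either dataset misses part of the union support.
#' @return List of aligned probability vectors `p` and `q`.
#' @export
mirna_distributions <- function(seqs_p, seqs_q, pseudocount = 0.5) {
  support <- union(seqs_p, seqs_q)
  cp <- table(factor(seqs_p, levels = support))
  cq <- table(factor(seqs_q, levels = support))
  if (pseudocount <= 0 && (any(cp == 0) || any(cq == 0)))
    stop("non-positive pseudocount with incomplete supports", call. = FALSE)
  p <- (as.numeric(cp) + pseudocount); p <- p / sum(p)
  q <- (as.numeric(cq) + pseudocount); q <- q / sum(q)
  list(p = setNames(p, support), q = setNames(q, support))
}

#' Kullback-Leibler divergence D(P||Q)
#'
#' Natural-log KL divergence over aligned probability vectors; terms with
#' P(x) = 0 contribute 0.
#'
#' @param p,q Aligned probability vectors (non-negative, each summing to 1).
#' @return Non-negative scalar (infinite if Q lacks mass where P has some).
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("supports differ", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("inputs must be probability distributions", call. = FALSE)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Can a classifier tell two negative datasets apart?
#'
#' Trains a default-hyperparameter gradient-boosted classifier to separate
#' records of dataset A (label 1) from dataset B (label 0) after
#' undersampling to equal size, with one 80/20 split.
#'
#' @param X_a,X_b Feature matrices of the two negative datasets.
#' @param seed RNG seed for undersampling and the split.
#' @return Named metric vector (includes `fpr` and `fnr`).
#' @export
two_negative_eval <- function(X_a, X_b, seed = 0L) {
  n <- min(nrow(X_a), nrow(X_b))
  if (n < 10) stop("datasets too small", call. = FALSE)
  with_seed(seed, {
    a <- X_a[sample.int(nrow(X_a), n), , drop = FALSE]
    b <- X_b[sample.int(nrow(X_b), n), , drop = FALSE]
    X <- rbind(a, b)
    y <- rep(c(1, 0), each = n)
    te <- sample.int(2 * n, round(0.4 * n))  # 20% of the combined set
    model <- fit_xgb(X[-te, , drop = FALSE], y[-te], default_xgb_params())
    metrics_from_pred(as.numeric(predict_xgb(model, X[te, , drop = FALSE])
                                 > 0.5), y[te])
  })
}

standardize_cols <- function(X, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(X, 2, center, "-"), 2, scale, "/")
}

#' One-class versus binary classification comparison
#'
#' Per repeat, four models are evaluated on identical test sets: a one-class
#' support-vector novelty detector versus its binary SVM counterpart (shared
#' RBF gamma), and an isolation forest versus a random-forest counterpart.
#' The one-class models are trained on the positive training rows only.
#' Features are standardized with the positive-training statistics.
#'
#' @param pos_X Positive feature matrix.
#' @param neg_X Negative feature matrix of the chosen dataset.
#' @param plan A `split_plan` whose `neg` entry `dataset` refers to `neg_X`.
#' @param dataset Name of the negative dataset in the plan.
#' @param params Hyperparameters: `gamma`, `nu`, `cost`, `n_trees`,
#'   `sample_size`, `rf_trees`.
#' @return List `per_repeat` (long data frame) and `summary` (mean/sd per
#'   model and metric: acc, auc, tpr, tnr, fpr).
#' @export
one_class_comparison <- function(pos_X, neg_X, plan, dataset,
                                 params = list()) {
  p <- utils::modifyList(
    list(gamma = 1 / ncol(pos_X), nu = 0.1, cost = 1, n_trees = 100L,
         sample_size = 256L, rf_trees = 100L), params)
  rows <- list()
  for (r in seq_along(plan$repeats)) {
    rp <- plan$repeats[[r]]
    ptr <- pos_X[rp$pos_train, , drop = FALSE]
    ntr <- neg_X[rp$neg[[dataset]]$train, , drop = FALSE]
    pte <- pos_X[rp$pos_test, , drop = FALSE]
    nte <- neg_X[rp$neg[[dataset]]$test, , drop = FALSE]
    ce <- colMeans(ptr); sc <- apply(ptr, 2, sd)
    ptr_s <- standardize_cols(ptr, ce, sc)
    ntr_s <- standardize_cols(ntr, ce, sc)
    te_X <- standardize_cols(rbind(pte, nte), ce, sc)
    te_y <- rep(c(1, 0), c(nrow(pte), nrow(nte)))

    preds <- list()
    # one-class SVM: trained on positives only
    oc <- e1071::svm(ptr_s, y = NULL, type = "one-classification",
                     kernel = "radial", gamma = p$gamma, nu = p$nu,
                     scale = FALSE)
    dv <- attr(predict(oc, te_X, decision.values = TRUE), "decision.values")
    preds$one_class_svm <- list(pred = as.numeric(dv[, 1] > 0),
                                score = dv[, 1])
    # binary SVM counterpart (same gamma)
    bs <- e1071::svm(rbind(ptr_s, ntr_s),
                     factor(rep(c(1, 0), c(nrow(ptr_s), nrow(ntr_s))),
                            levels = c(1, 0)),
                     kernel = "radial", gamma = p$gamma, cost = p$cost,
                     scale = FALSE)
    pv <- predict(bs, te_X, decision.values = TRUE)
    preds$svm <- list(pred = as.numeric(as.character(pv)),
                      score = attr(pv, "decision.values")[, 1])
    # isolation forest: trained on positives only; high score = anomaly
    iforest <- iforest_fit(ptr_s, p$n_trees, p$sample_size,
                           seed = plan$base_seed + r)
    isc <- iforest_score(iforest, te_X)
    preds$isolation_forest <- list(pred = as.numeric(isc <= 0.5),
                                   score = -isc)
    # random-forest counterpart
    rf <- ranger::ranger(
      x = rbind(ptr_s, ntr_s),
      y = factor(rep(c(1, 0), c(nrow(ptr_s), nrow(ntr_s))),
                 levels = c(0, 1)),
      num.trees = p$rf_trees, probability = TRUE, num.threads = 1,
      seed = plan$base_seed + r)
    rp1 <- predict(rf, te_X)$predictions[, "1"]
    preds$random_forest <- list(pred = as.numeric(rp1 > 0.5), score = rp1)

    for (m in names(preds)) {
      met <- metrics_from_pred(preds[[m]]$pred, te_y)
      rows[[length(rows) + 1]] <- data.frame(
        model = m, rep = r, acc = met["acc"],
        auc = auc_score(preds[[m]]$score, te_y),
        tpr = met["tpr"], tnr = met["tnr"], fpr = met["fpr"],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  per_repeat <- do.call(rbind, rows)
  mets <- c("acc", "auc", "tpr", "tnr", "fpr")
  summary <- do.call(rbind, lapply(split(per_repeat, per_repeat$model),
    function(d) data.frame(model = d$model[1],
                           t(setNames(colMeans(d[, mets]), mets)),
                           t(setNames(apply(d[, mets], 2, sd),
                                      paste0(mets, "_sd"))),
                           row.names = NULL)))
  list(per_repeat = per_repeat, summary = summary)
}

#' Six-class duplex distribution of a dataset
#'
#' Proportions over seed type (canonical / non-canonical) x base-pairing
#' density (low / medium / high), summing to one.
#'
#' @param dataset An `mti_dataset` of valid records.
#' @return 2 x 3 proportion matrix.
#' @export
duplex_class_distribution <- function(dataset) {
  r <- dataset$records
  tab <- table(factor(r$seed_type, levels = c("canonical", "non_canonical")),
               factor(r$density_class, levels = c("low", "medium", "high")))
  tab / sum(tab)
}
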