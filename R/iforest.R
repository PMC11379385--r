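# Isolation forest (Liu, Ting & Zhou): trees isolate points by recursive
# random axis-aligned splits on subsamples; anomaly score derives from the
# average path length. Used as the tree-based one-class counterpart of the
# random forest in the one-class comparison.

iforest_cn <- function(n) {
  # average unsuccessful-search path length of a BST with n nodes
  if (n <= 1) return(0)
  2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n
}

itree_build <- function(X, idx, depth, max_depth) {
  n <- length(idx)
  if (n <= 1 || depth >= max_depth)
    return(list(leaf = TRUE, size = n))
  # random feature with spread; give up after a few draws (constant node)
  for (try in 1:10) {
    f <- sample.int(ncol(X), 1)
    lo <- min(X[idx, f]); hi <- max(X[idx, f])
    if (hi > lo) {
      sp <- runif(1, lo, hi)
      l <- idx[X[idx, f] < sp]
      r <- idx[X[idx, f] >= sp]
      if (length(l) > 0 && length(r) > 0)
        return(list(leaf = FALSE, feature = f, split = sp,
                    left = itree_build(X, l, depth + 1, max_depth),
                    right = itree_build(X, r, depth + 1, max_depth)))
    }
  }
  list(leaf = TRUE, size = n)
}

#' Fit an isolation forest
#'
#' @param X Numeric matrix (rows = observations).
#' @param n_trees Number of isolation trees.
#' @param sample_size Subsample size per tree (capped at `nrow(X)`).
#' @param seed Optional RNG seed.
#' @return An `iforest` model object.
#' @export
iforest_fit <- function(X, n_trees = 100L, sample_size = 256L, seed = NULL) {
  sample_size <- min(sample_size, nrow(X))
  max_depth <- ceiling(log2(max(2, sample_size)))
  with_seed(seed, {
    trees <- lapply(seq_len(n_trees), function(t) {
      idx <- sample.int(nrow(X), sample_size)
      itree_build(X, idx, 0L, max_depth)
    })
    structure(list(trees = trees, sample_size = sample_size,
                   ncol = ncol(X)), class = "iforest")
  })
}

# vectorized path length of all rows through one tree
itree_paths <- function(node, X, idx, depth, out) {
  if (node$leaf || length(idx) == 0) {
    out[idx] <- depth + iforest_cn(node$size %||% 1)
    return(out)
  }
  go_l <- X[idx, node$feature] < node$split
  out <- itree_paths(node$left, X, idx[go_l], depth + 1, out)
  itree_paths(node$right, X, idx[!go_l], depth + 1, out)
}

#' Isolation-forest anomaly scores
#'
#' @param model An `iforest`.
#' @param X Matrix with the training schema.
#' @return Scores in (0, 1); larger = more anomalous. The conventional
#'   decision threshold is 0.5.
#' @export
iforest_score <- function(model, X) {
  paths <- rowSums(vapply(model$trees, function(tr)
    itree_paths(tr, X, seq_len(nrow(X)), 0, numeric(nrow(X))),
    numeric(nrow(X)))) / length(model$trees)
  2^(-paths / iforest_cn(model$sample_size))
}
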