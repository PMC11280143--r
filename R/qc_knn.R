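## Injection-site separability QC -----------------------------------------
##
## KNN classification of 3-D coordinates with stratified k-fold
## cross-validation; the best-k CV accuracy is compared with a
## label-shuffled null in which the same procedure (including best-k
## selection) is repeated per shuffle, so the selection bias cancels.

.stratified_folds <- function(labels, folds) {
  f <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- which(labels == g)
    f[idx] <- rep_len(seq_len(folds), length(idx))[sample.int(length(idx))]
  }
  f
}

.knn_cv_accuracy <- function(ord, labels, k_grid, fold) {
  ## ord[i, ] = indices of all other points sorted by distance from i;
  ## labels as integer codes for speed (called ~1000x inside the null)
  n <- length(labels)
  lab <- as.integer(factor(labels))
  ncls <- max(lab)
  hits <- integer(length(k_grid))
  kmax <- max(k_grid)
  for (i in seq_len(n)) {
    oi <- ord[i, ]
    nb <- oi[fold[oi] != fold[i]][seq_len(kmax)]
    vl <- lab[nb]
    for (kk in seq_along(k_grid)) {
      votes <- vl[seq_len(k_grid[kk])]
      cnt <- tabulate(votes, ncls)
      winners <- which(cnt == max(cnt))
      ## distance tie-break: nearest neighbor among the tied classes
      pred <- if (length(winners) == 1L) winners
              else votes[votes %in% winners][1]
      hits[kk] <- hits[kk] + (pred == lab[i])
    }
  }
  setNames(hits / n, k_grid)
}

#' KNN separability of labeled 3-D coordinates
#'
#' @param coords numeric matrix n x 3 (um).
#' @param labels group label per point (>= 2 classes, >= `folds` points per
#'   class).
#' @param k_grid neighbor counts to try (default odd 1..15, capped below the
#'   smallest class size).
#' @param folds cross-validation folds (default 5).
#' @param n_shuffles label permutations for the null (default 1000).
#' @param seed integer seed.
#' @return list of class `separability_result`: `k_grid`, `accuracy_by_k`,
#'   `best_k`, `cv_accuracy`, `null_accuracies`, `p` (fraction of null >=
#'   observed), `significant` (p < 0.05).
#' @export
knn_separability <- function(coords, labels, k_grid = seq(1, 15, by = 2),
                             folds = 5, n_shuffles = 1000, seed) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stopf("need >= 2 classes")
  if (min(table(labels)) < folds)
    stopf("need >= %d points per class for %d-fold CV", folds, folds)
  k_grid <- k_grid[k_grid < min(table(labels))]
  if (!length(k_grid)) stopf("no usable k in k_grid")
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  ord <- t(apply(d, 1, order))            # smallest-index tie-break via order()
  with_seed(seed, {
    fold <- .stratified_folds(labels, folds)
    acc <- .knn_cv_accuracy(ord, labels, k_grid, fold)
    best <- which.max(acc)                 # ties -> smallest k (grid sorted)
    obs <- acc[best]
    null_acc <- vapply(seq_len(n_shuffles), function(s) {
      lab_s <- labels[sample.int(n)]
      fold_s <- .stratified_folds(lab_s, folds)
      max(.knn_cv_accuracy(ord, lab_s, k_grid, fold_s))
    }, numeric(1))
    structure(list(k_grid = k_grid, accuracy_by_k = acc,
                   best_k = k_grid[best], cv_accuracy = as.numeric(obs),
                   null_accuracies = null_acc,
                   p = mean(null_acc >= obs),
                   significant = mean(null_acc >= obs) < 0.05),
              class = "separability_result")
  })
}

#' @export
print.separability_result <- function(x, ...) {
  cat(sprintf("KNN separability: best k = %d, CV accuracy = %.3f, p = %.4g%s\n",
              x$best_k, x$cv_accuracy, x$p,
              if (x$significant) " (significant)" else ""))
  invisible(x)
}
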