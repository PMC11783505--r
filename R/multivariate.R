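#' Vectorise coactivation matrices into a subject x feature table
#'
#' Flattens each subject's symmetric ROI x ROI coactivation matrix into its
#' lower triangle (diagonal excluded), in column-major order: feature
#' `roiJ~roiI` for column `J` < row `I`. All subjects must share the same
#' ROI ordering. `unvectorize_coactivation()` inverts the operation.
#'
#' @param matrices list of symmetric matrices with identical dimnames, e.g.
#'   from [coactivation_matrix()].
#' @return subjects x `R(R-1)/2` matrix; row names from the list names.
#' @export
vectorize_coactivation <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0L) {
    stop("`matrices` must be a non-empty list", call. = FALSE)
  }
  labs <- rownames(matrices[[1]])
  R <- nrow(matrices[[1]])
  if (is.null(labs)) labs <- sprintf("roi_%02d", seq_len(R))
  lower <- which(lower.tri(matrix(0, R, R)))
  ij <- arrayInd(lower, c(R, R))
  feat_names <- sprintf("%s~%s", labs[ij[, 2]], labs[ij[, 1]])
  out <- t(vapply(matrices, function(m) {
    if (!identical(dim(m), c(R, R)) ||
        (!is.null(rownames(m)) && !identical(rownames(m), labs))) {
      stop("all matrices must share dimensions and ROI labels", call. = FALSE)
    }
    unclass(m)[lower]
  }, numeric(length(lower))))
  colnames(out) <- feat_names
  out
}

#' @rdname vectorize_coactivation
#' @param features one row of a [vectorize_coactivation()] table.
#' @param labels ROI labels of the original matrix.
#' @return `unvectorize_coactivation()`: the symmetric matrix with NA
#'   diagonal.
#' @export
unvectorize_coactivation <- function(features, labels) {
  R <- length(labels)
  M <- matrix(NA_real_, R, R, dimnames = list(labels, labels))
  M[lower.tri(M)] <- as.numeric(features)
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  M
}

#' Balanced accuracy from labels and predictions
#'
#' The mean of per-class recalls; chance level is 0.5 for two classes
#' regardless of class imbalance.
#'
#' @param truth,pred vectors of true and predicted class labels.
#' @return balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  classes <- sort(unique(truth))
  mean(vapply(classes, function(cl) {
    mean(pred[truth == cl] == cl)
  }, numeric(1)))
}

# Stratified fold assignment: within each class, subjects are shuffled and
# dealt round-robin, so every fold's class ratio is within one subject of
# the global ratio.
stratified_folds <- function(labels, k, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Cross-validated balanced accuracy of a linear-SVM genotype classifier
#'
#' Trains a linear-kernel support vector machine (cost `C`) in a stratified
#' k-fold cross-validation and returns the balanced accuracy pooled over
#' folds. Features are standardised using training-fold statistics only, so
#' no information leaks from held-out subjects.
#'
#' @param features subjects x features numeric matrix, e.g.
#'   [vectorize_coactivation()].
#' @param labels two-class label vector; each class needs at least `k`
#'   members.
#' @param k number of stratified folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param cost SVM regularisation constant (default 1).
#' @return balanced accuracy in `[0, 1]`.
#' @export
crossval_balanced_accuracy <- function(features, labels, k = 5, seed = NULL,
                                       cost = 1) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("`labels` must have two classes", call. = FALSE)
  if (min(table(labels)) < k) {
    stop("each class needs at least `k` members for stratified folds",
         call. = FALSE)
  }
  fold <- stratified_folds(as.character(labels), k, seed)
  pred <- character(length(labels))
  for (f in seq_len(k)) {
    tr <- fold != f
    mu <- colMeans(features[tr, , drop = FALSE])
    sd <- apply(features[tr, , drop = FALSE], 2, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    xtr <- sweep(sweep(features[tr, , drop = FALSE], 2, mu), 2, sd, "/")
    xte <- sweep(sweep(features[!tr, , drop = FALSE], 2, mu), 2, sd, "/")
    fit <- e1071::svm(xtr, labels[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    pred[!tr] <- as.character(stats::predict(fit, xte))
  }
  balanced_accuracy(as.character(labels), pred)
}

#' Permutation test of classifier performance
#'
#' Compares the observed cross-validated balanced accuracy with its null
#' distribution obtained by re-running the full cross-validation loop on
#' randomly permuted labels (`n_perm` times, default 5000). The p-value is
#' `(1 + #{null >= observed}) / (1 + n_perm)`, never exactly zero.
#'
#' @inheritParams crossval_balanced_accuracy
#' @param n_perm number of label permutations.
#' @param seed RNG seed controlling folds and permutations.
#' @return object of class `permutation_result`: `observed_bacc`,
#'   `null_baccs`, `p`, `n_perm`, `k_folds`, `seed`.
#' @export
permutation_test <- function(features, labels, n_perm = 5000, k = 5,
                             seed = 1L, cost = 1) {
  stopifnot_scalar(n_perm, "n_perm", lower = 1)
  n_perm <- as.integer(n_perm)
  observed <- crossval_balanced_accuracy(features, labels, k = k,
                                         seed = seed, cost = cost)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample(labels)
      crossval_balanced_accuracy(features, perm, k = k, seed = NULL,
                                 cost = cost)
    }, numeric(1))
  })
  p <- (1 + sum(nulls >= observed)) / (1 + n_perm)
  structure(list(observed_bacc = observed, null_baccs = nulls, p = p,
                 n_perm = n_perm, k_folds = k,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: balanced accuracy %.3f, p = %.4g (%d permutations, %d folds)\n",
    x$observed_bacc, x$p, x$n_perm, x$k_folds))
  invisible(x)
}
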