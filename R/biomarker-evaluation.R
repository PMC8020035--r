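# ROC curves with pair-counting AUC, stratified percentile bootstrap
# confidence intervals, and nested-panel predictive accuracy.

#' ROC curve and AUC
#'
#' The step curve starts at (0, 0) and ends at (1, 1) with both
#' coordinates non-decreasing; tied scores are grouped into single
#' steps. The AUC equals the Mann-Whitney U statistic normalized by
#' n1*n2, ties counted one half, and is invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores real-valued classifier scores, higher indicating the
#'   second factor level.
#' @param labels two-class factor; both classes must be present.
#' @return List of class `roc_result`: `curve` (data frame: threshold,
#'   fpr, tpr), `auc`.
#' @export
roc_curve <- function(scores, labels) {
  f <- .as_two_level_factor(labels)
  pos <- f == levels(f)[2L]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / n0, 0)
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  structure(list(curve = curve, auc = .auc_rank(scores, f)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d thresholds)\n", x$auc,
              nrow(x$curve) - 1L))
  invisible(x)
}

#' Stratified percentile bootstrap CI for the AUC
#'
#' Samples are resampled with replacement within each class (so no
#' resample can lose a class), the rank AUC recomputed, and the
#' percentile interval at the stated level returned.
#'
#' @param scores,labels as in [roc_curve()].
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param level confidence level in (0, 1).
#' @param seed RNG seed; same seed, identical interval.
#' @return Numeric `c(lower, upper)`; attribute `"boot_auc"` holds the
#'   resampled AUCs.
#' @export
bootstrap_ci <- function(scores, labels, n_boot = 2000L, level = 0.95,
                         seed = NULL) {
  if (n_boot < 100L) stop("n_boot must be >= 100")
  .check_prob(level, "level")
  f <- .as_two_level_factor(labels)
  i1 <- which(f == levels(f)[2L])
  i0 <- which(f == levels(f)[1L])
  if (!length(i1) || !length(i0)) stop("both classes must be present")
  .with_seed(seed, {
    boot <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(i0, length(i0), replace = TRUE),
               sample(i1, length(i1), replace = TRUE))
      .auc_rank(scores[idx], f[idx])
    }, 0)
    alpha <- 1 - level
    ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2)))
    attr(ci, "boot_auc") <- boot
    ci
  })
}

# Youden-optimal threshold on training predictions: candidates are
# midpoints between consecutive sorted unique scores plus the extremes;
# ties resolved toward the smallest threshold.
.youden_threshold <- function(scores, f) {
  pos <- f == levels(f)[2L]
  u <- sort(unique(scores))
  cand <- if (length(u) == 1L) u else
    c(u[1L] - 1, (u[-length(u)] + u[-1L]) / 2, u[length(u)] + 1)
  j <- vapply(cand, function(t) {
    sum(scores[pos] >= t) / sum(pos) -
      sum(scores[!pos] >= t) / sum(!pos)
  }, 0)
  cand[which.max(j)]
}

#' Cross-validated accuracy of nested biomarker panels
#'
#' For k = 1..|panel|, fits a single-component PLS-DA on the first k
#' panel bins within each training fold, picks the score threshold
#' maximizing the training-fold Youden index, and pools the held-out
#' classifications into a cross-validated accuracy.
#'
#' @param matrix a `processed_matrix` or samples-by-bins matrix.
#' @param labels two-class factor.
#' @param panel ordered bin names or indices.
#' @param folds CV folds (collapses to leave-one-out on tiny classes).
#' @param seed RNG seed for fold assignment.
#' @param subject optional per-sample subject IDs; in paired designs
#'   folds hold out whole subjects.
#' @return Numeric vector of accuracies, one per panel size.
#' @export
panel_accuracy <- function(matrix, labels, panel, folds = 10L,
                           seed = NULL, subject = NULL) {
  x <- if (inherits(matrix, "processed_matrix")) matrix$values else
    as.matrix(matrix)
  if (length(panel) == 0L) stop("panel must be nonempty")
  if (is.character(panel)) {
    missing <- setdiff(panel, colnames(x))
    if (length(missing)) {
      stop("panel references bins absent from the matrix: ",
           paste(missing, collapse = ", "))
    }
  } else if (any(panel < 1L | panel > ncol(x))) {
    stop("panel indices out of range")
  }
  f <- .as_two_level_factor(labels)
  y <- .y_pm1(f)
  .with_seed(seed, {
    fold_list <- .stratified_folds(f, folds, subject)
    vapply(seq_along(panel), function(k) {
      xs <- x[, panel[seq_len(k)], drop = FALSE]
      correct <- 0L
      for (idx in fold_list) {
        tr <- setdiff(seq_along(y), idx)
        ytr <- y[tr]
        mu <- colMeans(xs[tr, , drop = FALSE])
        Xtr <- sweep(xs[tr, , drop = FALSE], 2L, mu)
        fit <- .pls1(Xtr, ytr - mean(ytr))
        if (is.null(fit)) {
          pred_tr <- rep(mean(ytr), length(tr))
          pred_te <- rep(mean(ytr), length(idx))
        } else {
          pred_tr <- fit$scores * fit$q + mean(ytr)
          Xte <- sweep(xs[idx, , drop = FALSE], 2L, mu)
          pred_te <- as.vector(Xte %*% fit$w) * fit$q + mean(ytr)
        }
        thr <- .youden_threshold(pred_tr, f[tr])
        correct <- correct + sum((pred_te >= thr) == (y[idx] > 0))
      }
      correct / length(y)
    }, 0)
  })
}
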