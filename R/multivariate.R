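# Multivariate models: PCA, OPLS-DA (single predictive component plus
# orthogonal-signal-correction components), double cross-validated Q2,
# permutation testing, and Ward hierarchical clustering for heat maps.

#' Principal components analysis of a processed matrix
#'
#' Thin wrapper around [stats::prcomp()] (centered, unscaled) returning
#' scores, loadings, and explained-variance fractions.
#'
#' @param matrix a `processed_matrix` or samples-by-bins matrix.
#' @param n_components number of components; truncated to the matrix rank
#'   with a warning when it exceeds it.
#' @return List: `scores`, `loadings`, `explained` (fractions,
#'   non-increasing, summing to <= 1), `prcomp` (the underlying fit).
#' @export
pca_model <- function(matrix, n_components = 2L) {
  x <- if (inherits(matrix, "processed_matrix")) matrix$values else
    as.matrix(matrix)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1L] * 1e-12)
  if (n_components > rank) {
    warning("n_components exceeds the matrix rank (", rank,
            "); truncated")
    n_components <- rank
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
       explained = expl[seq_len(n_components)],
       prcomp = pc)
}

#' Fit an OPLS-DA model
#'
#' Class labels are coded -1/+1 (second factor level positive) and
#' centered. `n_orthogonal` orthogonal-signal-correction components
#' (variation in X orthogonal to y) are removed iteratively, then a
#' single predictive PLS component is fitted to the deflated matrix.
#' Predictive scores carry the between-group variation and orthogonal
#' scores the within-group variation. With `n_orthogonal = 0` the model
#' reduces exactly to single-component PLS1-DA.
#'
#' @param matrix a `processed_matrix` or samples-by-bins matrix.
#' @param labels two-class factor (or coercible), one entry per sample.
#' @param n_orthogonal number of orthogonal components to remove.
#' @return An `oplsda_fit`: predictive weights/loadings/scores,
#'   orthogonal weights/loadings/scores, `R2Y`, centers, and the label
#'   coding.
#' @export
fit_oplsda <- function(matrix, labels, n_orthogonal = 0L) {
  x <- if (inherits(matrix, "processed_matrix")) matrix$values else
    as.matrix(matrix)
  f <- .as_two_level_factor(labels)
  if (min(table(f)) < 2L) stop("each class needs at least 2 samples")
  y <- .y_pm1(f)
  ybar <- mean(y)
  yc <- y - ybar
  xbar <- colMeans(x)
  Xd <- sweep(x, 2L, xbar)
  W_o <- P_o <- NULL
  T_o <- NULL
  for (i in seq_len(n_orthogonal)) {
    w <- crossprod(Xd, yc)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- as.vector(Xd %*% w)
    p <- crossprod(Xd, t)[, 1L] / sum(t^2)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) break # no orthogonal variation left
    wo <- wo / nwo
    to <- as.vector(Xd %*% wo)
    po <- crossprod(Xd, to)[, 1L] / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    W_o <- cbind(W_o, wo)
    P_o <- cbind(P_o, po)
    T_o <- cbind(T_o, to)
  }
  fit <- .pls1(Xd, yc)
  if (is.null(fit)) stop("no covariance between X and the class labels")
  yhat <- fit$scores * fit$q
  r2y <- 1 - sum((yc - yhat)^2) / sum(yc^2)
  structure(
    list(weights = fit$w, loadings = fit$p, q = fit$q,
         scores = fit$scores,
         ortho_weights = W_o, ortho_loadings = P_o, ortho_scores = T_o,
         n_orthogonal = if (is.null(W_o)) 0L else ncol(W_o),
         R2Y = r2y, x_center = xbar, y_center = ybar,
         levels = levels(f)),
    class = "oplsda_fit"
  )
}

#' @export
print.oplsda_fit <- function(x, ...) {
  cat(sprintf("<oplsda_fit> 1 predictive + %d orthogonal component(s); R2Y = %.3f\n",
              x$n_orthogonal, x$R2Y))
  invisible(x)
}

#' Predict from an OPLS-DA fit
#'
#' @param object an `oplsda_fit`.
#' @param newdata samples-by-bins matrix on the training columns.
#' @param ... unused.
#' @return List: `yhat` (continuous prediction on the -1/+1 scale),
#'   `scores` (predictive scores), `class` (predicted labels at the 0
#'   threshold).
#' @export
predict.oplsda_fit <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  Xd <- sweep(x, 2L, object$x_center)
  if (object$n_orthogonal > 0L) {
    for (i in seq_len(object$n_orthogonal)) {
      to <- as.vector(Xd %*% object$ortho_weights[, i])
      Xd <- Xd - tcrossprod(to, object$ortho_loadings[, i])
    }
  }
  t <- as.vector(Xd %*% object$weights)
  yhat <- t * object$q + object$y_center
  cls <- factor(ifelse(yhat >= 0, object$levels[2L], object$levels[1L]),
                levels = object$levels)
  list(yhat = yhat, scores = t, class = cls)
}

# Outer-CV Q2 with the orthogonal-component count fixed; folds is a list
# of held-out index vectors.
.cv_q2_fixed <- function(x, labels, folds, n_orthogonal) {
  y <- .y_pm1(labels)
  preds <- rep(NA_real_, length(y))
  for (idx in folds) {
    tr <- setdiff(seq_along(y), idx)
    fit <- tryCatch(
      fit_oplsda(x[tr, , drop = FALSE], labels[tr], n_orthogonal),
      error = function(e) NULL)
    preds[idx] <- if (is.null(fit)) mean(y[tr]) else
      predict(fit, x[idx, , drop = FALSE])$yhat
  }
  1 - sum((y - preds)^2) / sum((y - mean(y))^2)
}

#' Double (nested) cross-validated Q2 for OPLS-DA
#'
#' The outer loop holds out each sample at least once (stratified
#' k-fold, collapsing to leave-one-out when a class is smaller than the
#' fold count); the inner loop selects the number of orthogonal
#' components (0..`max_orthogonal`) by inner-CV Q2 on the training
#' fold. The whole validation is repeated `repeats` times with fresh
#' fold assignments — every sample enters the test set at least once
#' per repetition — and Q2 = 1 - PRESS/TSS pooled over all held-out
#' predictions, which removes most fold-assignment noise at small n.
#'
#' @param matrix a `processed_matrix` or samples-by-bins matrix.
#' @param labels two-class factor.
#' @param outer_folds,inner_folds fold counts (capped at sample counts).
#' @param max_orthogonal largest orthogonal-component count considered;
#'   capped low because tiny cohorts make deeper models unstable.
#' @param seed RNG seed for fold assignment; same seed, same Q2.
#' @param subject optional per-sample subject IDs; in paired designs
#'   folds hold out whole subjects so a sample's within-subject twin
#'   never leaks into its training fold.
#' @param repeats repetitions of the outer validation with fresh fold
#'   assignments.
#' @return List: `Q2`, `n_orthogonal` (selected per outer fold and
#'   repetition), `predictions` (held-out continuous predictions from
#'   the first repetition).
#' @export
double_cv_q2 <- function(matrix, labels, outer_folds = 10L,
                         inner_folds = 10L, max_orthogonal = 3L,
                         seed = NULL, subject = NULL, repeats = 3L) {
  x <- if (inherits(matrix, "processed_matrix")) matrix$values else
    as.matrix(matrix)
  f <- .as_two_level_factor(labels)
  if (min(table(f)) < 2L) stop("each class needs at least 2 samples")
  .with_seed(seed, {
    y <- .y_pm1(f)
    press <- tss <- 0
    sel <- integer(0)
    first_preds <- NULL
    for (rep in seq_len(repeats)) {
      folds <- .stratified_folds(f, outer_folds, subject)
      preds <- rep(NA_real_, length(y))
      for (k in seq_along(folds)) {
        idx <- folds[[k]]
        tr <- setdiff(seq_along(y), idx)
        inner <- .stratified_folds(f[tr], inner_folds, subject[tr])
        q2s <- vapply(0:max_orthogonal, function(no) {
          .cv_q2_fixed(x[tr, , drop = FALSE], f[tr], inner, no)
        }, 0)
        sel <- c(sel, which.max(q2s) - 1L)
        fit <- tryCatch(
          fit_oplsda(x[tr, , drop = FALSE], f[tr], sel[length(sel)]),
          error = function(e) NULL)
        preds[idx] <- if (is.null(fit)) mean(y[tr]) else
          predict(fit, x[idx, , drop = FALSE])$yhat
      }
      press <- press + sum((y - preds)^2)
      tss <- tss + sum((y - mean(y))^2)
      if (rep == 1L) first_preds <- preds
    }
    list(Q2 = 1 - press / tss, n_orthogonal = sel,
         predictions = first_preds)
  })
}

#' Permutation test for OPLS-DA model statistics
#'
#' Class labels are permuted `n_perm` times and the statistic recomputed
#' each time; p = (#\{permuted >= observed\} + 1) / (n_perm + 1). For
#' `statistic = "R2Y"` each permutation refits the model with the stated
#' orthogonal-component count. For `statistic = "Q2"` each permutation
#' re-runs the repeated outer cross-validation with the orthogonal-component
#' count fixed at the observed model's inner-CV choice (the inner
#' selection is not repeated per permutation).
#'
#' @param matrix a `processed_matrix` or samples-by-bins matrix.
#' @param labels two-class factor.
#' @param statistic `"R2Y"` or `"Q2"`.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param n_orthogonal orthogonal components for R2Y refits.
#' @param outer_folds,inner_folds,max_orthogonal passed to the Q2 machinery.
#' @param subject optional subject IDs for paired-design fold grouping.
#' @return List: `p.value`, `observed`, `permuted` (vector of permuted
#'   statistics).
#' @export
permutation_test <- function(matrix, labels, statistic = c("R2Y", "Q2"),
                             n_perm = 2000L, seed = NULL,
                             n_orthogonal = 0L, outer_folds = 10L,
                             inner_folds = 10L, max_orthogonal = 3L,
                             subject = NULL, repeats = 3L) {
  statistic <- match.arg(statistic)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  x <- if (inherits(matrix, "processed_matrix")) matrix$values else
    as.matrix(matrix)
  f <- .as_two_level_factor(labels)
  .with_seed(seed, {
    if (statistic == "R2Y") {
      obs <- fit_oplsda(x, f, n_orthogonal)$R2Y
      stat_fun <- function(lab) {
        tryCatch(fit_oplsda(x, lab, n_orthogonal)$R2Y,
                 error = function(e) -Inf)
      }
    } else {
      dcv <- double_cv_q2(x, f, outer_folds, inner_folds, max_orthogonal,
                          subject = subject, repeats = repeats)
      obs <- dcv$Q2
      no_fix <- as.integer(round(stats::median(dcv$n_orthogonal)))
      fold_sets <- lapply(seq_len(repeats), function(i) {
        .stratified_folds(f, outer_folds, subject)
      })
      stat_fun <- function(lab) {
        tryCatch(
          mean(vapply(fold_sets, function(fs) {
            .cv_q2_fixed(x, lab, fs, no_fix)
          }, 0)),
          error = function(e) -Inf)
      }
    }
    perm <- vapply(seq_len(n_perm), function(i) {
      stat_fun(f[sample.int(length(f))])
    }, 0)
    if (n_perm > 1L && stats::sd(perm) == 0) {
      warning("permutation statistic is constant across permutations")
    }
    list(p.value = (sum(perm >= obs) + 1) / (n_perm + 1),
         observed = obs, permuted = perm)
  })
}

#' Ward hierarchical clustering order for heat maps
#'
#' Agglomerative clustering with Euclidean distance and Ward linkage
#' (`ward.D2`) on rows (samples) and columns (bins); leaf orders are
#' deterministic with ties broken by input index.
#'
#' @param matrix a `processed_matrix` or matrix with >= 2 rows.
#' @return List of class `cluster_order`: `row_hclust`, `col_hclust`
#'   (NULL when fewer than 2 columns), `row_order`, `col_order`.
#' @export
hierarchical_heatmap_order <- function(matrix) {
  x <- if (inherits(matrix, "processed_matrix")) matrix$values else
    as.matrix(matrix)
  if (nrow(x) < 2L) {
    return(structure(list(row_hclust = NULL, col_hclust = NULL,
                          row_order = seq_len(nrow(x)),
                          col_order = seq_len(ncol(x))),
                     class = "cluster_order"))
  }
  rh <- stats::hclust(stats::dist(x), method = "ward.D2")
  ch <- if (ncol(x) >= 2L) {
    stats::hclust(stats::dist(t(x)), method = "ward.D2")
  } else NULL
  structure(list(row_hclust = rh, col_hclust = ch,
                 row_order = rh$order,
                 col_order = if (is.null(ch)) seq_len(ncol(x)) else
                   ch$order),
            class = "cluster_order")
}
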