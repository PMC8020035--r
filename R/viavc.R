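# VIAVC: variable-importance analysis based on random variable
# combinations. Importance is the gain in cross-validated AUC when a bin
# is included in random bin subsets drawn from a binary resampling
# matrix; the best subset is the nested head of the importance ranking
# that maximizes cross-validated AUC.

#' Binary random-combination matrix
#'
#' `n_rows` independent Bernoulli(`inclusion_prob`) inclusion vectors
#' over `n_bins` bins; all-zero rows are resampled so every row selects
#' at least one bin.
#'
#' @param n_bins,n_rows dimensions.
#' @param inclusion_prob per-bin inclusion probability, in (0, 1).
#' @param seed RNG seed.
#' @return `n_rows` x `n_bins` 0/1 matrix.
#' @export
random_combination_matrix <- function(n_bins, n_rows = 500L,
                                      inclusion_prob = 0.5, seed = NULL) {
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (n_rows < 1L) stop("n_rows must be >= 1")
  .check_prob(inclusion_prob, "inclusion_prob")
  .with_seed(seed, {
    m <- matrix(stats::rbinom(n_rows * n_bins, 1L, inclusion_prob),
                n_rows, n_bins)
    empty <- which(rowSums(m) == 0L)
    while (length(empty)) {
      m[empty, ] <- stats::rbinom(length(empty) * n_bins, 1L,
                                  inclusion_prob)
      empty <- which(rowSums(m) == 0L)
    }
    m
  })
}

#' Cross-validated AUC of a bin subset
#'
#' Fits a single-component PLS-DA on the subset's columns within each
#' training fold, pools the held-out predictive scores, and computes the
#' rank AUC against the labels. Scores are oriented so the reported AUC
#' is >= 0.5 when `orient = TRUE` (the orientation convention used for
#' subset comparison); `orient = FALSE` returns the raw AUC of the
#' second-level class.
#'
#' @param matrix a `processed_matrix` or samples-by-bins matrix.
#' @param labels two-class factor.
#' @param subset column names or indices.
#' @param folds fold count (collapses to leave-one-out on tiny classes).
#' @param seed RNG seed for fold assignment.
#' @param orient orient AUC above 0.5.
#' @param subject optional per-sample subject IDs; in paired designs
#'   folds hold out whole subjects so a sample's within-subject twin
#'   never leaks into its training fold.
#' @return AUC (numeric scalar); attribute `"scores"` holds the pooled
#'   cross-validated scores.
#' @export
subset_auc <- function(matrix, labels, subset, folds = 10L, seed = NULL,
                       orient = TRUE, subject = NULL) {
  x <- if (inherits(matrix, "processed_matrix")) matrix$values else
    as.matrix(matrix)
  if (length(subset) == 0L) stop("subset must be nonempty")
  if (is.character(subset)) {
    missing <- setdiff(subset, colnames(x))
    if (length(missing)) {
      stop("subset references unknown bins: ",
           paste(missing, collapse = ", "))
    }
  } else if (any(subset < 1L | subset > ncol(x))) {
    stop("subset indices out of range")
  }
  f <- .as_two_level_factor(labels)
  xs <- x[, subset, drop = FALSE]
  .with_seed(seed, {
    scores <- .cv_scores(xs, f, folds, subject)
    auc <- .auc_rank(scores, f)
    if (orient) auc <- max(auc, 1 - auc)
    attr(auc, "scores") <- scores
    auc
  })
}

# Pooled held-out continuous predictions of single-component PLS-DA.
.cv_scores <- function(x, f, folds, group = NULL) {
  y <- .y_pm1(f)
  fold_list <- .stratified_folds(f, folds, group)
  preds <- rep(NA_real_, length(y))
  for (idx in fold_list) {
    tr <- setdiff(seq_along(y), idx)
    ytr <- y[tr]
    Xtr <- sweep(x[tr, , drop = FALSE], 2L, colMeans(x[tr, , drop = FALSE]))
    fit <- .pls1(Xtr, ytr - mean(ytr))
    preds[idx] <- if (is.null(fit)) mean(ytr) else {
      Xte <- sweep(x[idx, , drop = FALSE], 2L,
                   colMeans(x[tr, , drop = FALSE]))
      as.vector(Xte %*% fit$w) * fit$q + mean(ytr)
    }
  }
  preds
}

# One binary-matrix resampling round over the given columns. Returns
# per-column importance (mean AUC gain from inclusion) and the row AUCs.
.viavc_round <- function(x, f, n_rows, inclusion_prob, folds,
                         subject = NULL) {
  comb <- random_combination_matrix(ncol(x), n_rows, inclusion_prob)
  row_auc <- vapply(seq_len(n_rows), function(r) {
    cols <- which(comb[r, ] == 1L)
    scores <- .cv_scores(x[, cols, drop = FALSE], f, folds, subject)
    a <- .auc_rank(scores, f)
    max(a, 1 - a)
  }, 0)
  importance <- rep(NA_real_, ncol(x))
  for (j in seq_len(ncol(x))) {
    inc <- row_auc[comb[, j] == 1L]
    exc <- row_auc[comb[, j] == 0L]
    if (!length(inc) || !length(exc)) next # never sampled in one arm
    importance[j] <- mean(inc) - mean(exc)
  }
  list(importance = importance, row_auc = row_auc, combinations = comb)
}

#' VIAVC importance ranking
#'
#' Each round draws a binary random-combination matrix, computes the
#' cross-validated AUC of every row's bin subset, and scores each bin as
#' the difference between the mean AUC of subsets containing it and the
#' mean AUC of subsets excluding it. While more than `max_round_bins`
#' bins remain, the lower-scoring half is eliminated and the survivors
#' re-ranked, so the inclusion signal is not diluted across hundreds of
#' uninformative bins; the final round ranks the survivors, and
#' eliminated bins follow in reverse elimination order. Bins are sorted
#' by descending importance (the F-ranking). Categories are calibrated
#' by max-statistic label permutation (Westfall-Young): the labels are
#' permuted `n_perm_category` times, a full resampling round is re-run
#' each time, and a surviving bin is `"positive"` only when its
#' importance exceeds the largest importance any bin attained in every
#' permuted round (`"negative"` mirrors this below the smallest), which
#' controls the family-wise error at 1 / (`n_perm_category` + 1). A
#' per-bin include-vs-exclude rank test cannot be used here: each bin's
#' chance association with the labels is fixed in the data, so under
#' label noise such a test flags the largest chance association as
#' real. Bins eliminated before the final round are `"neutral"`.
#'
#' @param matrix a `processed_matrix` or samples-by-bins matrix.
#' @param labels two-class factor.
#' @param n_rows random combinations per round.
#' @param inclusion_prob per-bin inclusion probability.
#' @param folds CV folds inside each subset AUC.
#' @param n_perm_category label permutations for the category
#'   calibration (0 skips categorization, leaving every bin neutral);
#'   the default 20 gives family-wise level 1/21.
#' @param max_round_bins bin count at or below which elimination stops.
#' @param subject optional subject IDs for paired-design fold grouping.
#' @param seed RNG seed; the whole run is a pure function of
#'   (matrix, labels, parameters, seed).
#' @return List of class `viavc_ranking`: `table` (data frame: bin,
#'   importance, category, round, rank, sorted by rank), `row_auc` and
#'   `combinations` (final round), `n_rounds`.
#' @export
rank_variables <- function(matrix, labels, n_rows = 500L,
                           inclusion_prob = 0.5, folds = 10L,
                           n_perm_category = 20L, max_round_bins = 30L,
                           subject = NULL, seed = NULL) {
  x <- if (inherits(matrix, "processed_matrix")) matrix$values else
    as.matrix(matrix)
  if (ncol(x) < 2L) stop("at least 2 bins are required")
  f <- .as_two_level_factor(labels)
  bins <- colnames(x)
  if (is.null(bins)) bins <- paste0("bin", seq_len(ncol(x)))
  colnames(x) <- bins
  .with_seed(seed, {
    active <- seq_len(ncol(x))
    eliminated <- list() # per round, ordered by importance descending
    round <- 0L
    repeat {
      round <- round + 1L
      res <- .viavc_round(x[, active, drop = FALSE], f, n_rows,
                          inclusion_prob, folds, subject)
      ord <- order(-res$importance, seq_along(active), na.last = TRUE)
      if (length(active) <= max_round_bins) break
      keep_n <- ceiling(length(active) / 2)
      cut <- ord[(keep_n + 1L):length(active)]
      eliminated[[round]] <- data.frame(
        col = active[cut], importance = res$importance[cut],
        category = "neutral", round = round)
      active <- active[ord[seq_len(keep_n)]]
    }
    # max-statistic permutation calibration of the survivors' categories
    category <- rep("neutral", length(active))
    if (n_perm_category > 0L) {
      perm_hi <- perm_lo <- numeric(n_perm_category)
      for (b in seq_len(n_perm_category)) {
        fp <- f[sample.int(length(f))]
        rp <- .viavc_round(x[, active, drop = FALSE], fp, n_rows,
                           inclusion_prob, folds, subject)
        perm_hi[b] <- max(rp$importance, na.rm = TRUE)
        perm_lo[b] <- min(rp$importance, na.rm = TRUE)
      }
      category[!is.na(res$importance) &
                 res$importance > max(perm_hi)] <- "positive"
      category[!is.na(res$importance) &
                 res$importance < min(perm_lo)] <- "negative"
    }
    final <- data.frame(
      col = active[ord], importance = res$importance[ord],
      category = category[ord], round = round)
    tail_rows <- if (length(eliminated)) {
      do.call(rbind, rev(eliminated)) # later rounds rank better
    } else NULL
    all_rows <- rbind(final, tail_rows)
    tab <- data.frame(bin = bins[all_rows$col],
                      importance = all_rows$importance,
                      category = all_rows$category,
                      round = all_rows$round,
                      rank = seq_len(nrow(all_rows)),
                      stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    structure(list(table = tab, row_auc = res$row_auc,
                   combinations = res$combinations, n_rounds = round,
                   undefined = tab$bin[is.na(tab$importance)]),
              class = "viavc_ranking")
  })
}

#' Top of the F-ranking
#'
#' @param ranking a `viavc_ranking`.
#' @param n head size (e.g. 19 bins for the correlation screen).
#' @return Character vector of the top-`n` ranked bins.
#' @export
top_ranked <- function(ranking, n = 19L) {
  stopifnot(inherits(ranking, "viavc_ranking"))
  utils::head(ranking$table$bin, n)
}

#' VIAVC best-subset selection
#'
#' Evaluates the nested subsets top-1, top-2, ..., top-`max_k` of the
#' importance ranking by cross-validated AUC and returns the subset
#' maximizing AUC, ties broken toward fewer bins. Per-size
#' cross-validated classification accuracies are computed alongside.
#'
#' @param ranking a `viavc_ranking`.
#' @param matrix,labels the data the ranking was computed on.
#' @param max_k largest subset size considered (capped with a warning).
#' @param folds CV folds.
#' @param subject optional subject IDs for paired-design fold grouping.
#' @param seed RNG seed.
#' @return List of class `viavc_result`: `best_subset`, `best_auc`,
#'   `subset_auc` (per size), `accuracy` (per size), `ranking`, `seed`.
#' @export
best_subset <- function(ranking, matrix, labels, max_k = 10L,
                        folds = 10L, subject = NULL, seed = NULL) {
  stopifnot(inherits(ranking, "viavc_ranking"))
  ranked <- ranking$table$bin[!is.na(ranking$table$importance)]
  if (!length(ranked)) stop("ranking is empty")
  if (max_k > length(ranked)) {
    warning("max_k exceeds the number of ranked bins; capped at ",
            length(ranked))
    max_k <- length(ranked)
  }
  .with_seed(seed, {
    aucs <- vapply(seq_len(max_k), function(k) {
      as.numeric(subset_auc(matrix, labels, ranked[seq_len(k)], folds,
                            subject = subject))
    }, 0)
    acc <- panel_accuracy(matrix, labels, ranked[seq_len(max_k)], folds,
                          subject = subject)
    best_k <- which(aucs >= max(aucs) - 1e-12)[1L] # ties -> fewer bins
    structure(
      list(best_subset = ranked[seq_len(best_k)], best_auc = aucs[best_k],
           subset_auc = aucs, accuracy = acc, ranking = ranking,
           n_rows = nrow(ranking$combinations)),
      class = "viavc_result"
    )
  })
}

#' @export
print.viavc_result <- function(x, ...) {
  cat("<viavc_result> best subset:",
      paste(x$best_subset, collapse = ", "),
      sprintf("(CV-AUC %.3f)\n", x$best_auc))
  invisible(x)
}

#' Run the full VIAVC analysis
#'
#' [rank_variables()] followed by [best_subset()] under one seed.
#'
#' @inheritParams rank_variables
#' @inheritParams best_subset
#' @return A `viavc_result`.
#' @export
viavc <- function(matrix, labels, n_rows = 500L, inclusion_prob = 0.5,
                  folds = 10L, max_k = 10L, n_perm_category = 20L,
                  subject = NULL, seed = NULL) {
  .with_seed(seed, {
    ranking <- rank_variables(matrix, labels, n_rows, inclusion_prob,
                              folds, n_perm_category,
                              subject = subject)
    best_subset(ranking, matrix, labels, max_k, folds, subject = subject)
  })
}
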