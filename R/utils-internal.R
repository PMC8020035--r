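# Internal numerical helpers shared across modules.

# Single-component PLS1 on centered X and centered y.
# Returns NULL when X carries no covariance with y (degenerate).
.pls1 <- function(X, y) {
  w <- crossprod(X, y)[, 1L]
  nw <- sqrt(sum(w^2))
  if (!is.finite(nw) || nw < 1e-12) return(NULL)
  w <- w / nw
  t <- as.vector(X %*% w)
  tt <- sum(t^2)
  if (tt < 1e-24) return(NULL)
  p <- crossprod(X, t)[, 1L] / tt
  q <- sum(y * t) / tt
  list(w = w, p = p, q = q, scores = t)
}

# Stratified k-fold assignment; collapses to leave-one-out when the
# smaller class has fewer members than the requested fold count. When a
# grouping vector is given (paired designs: group = subject), whole
# groups are held out together, so a sample's within-subject twin never
# leaks into its training fold.
.stratified_folds <- function(labels, k, group = NULL) {
  n <- length(labels)
  if (!is.null(group)) {
    g <- unique(group)
    if (length(g) <= k) {
      return(unname(lapply(g, function(gg) which(group == gg))))
    }
    fold_of <- stats::setNames(sample(rep_len(seq_len(k), length(g))), g)
    return(unname(split(seq_len(n), fold_of[group])))
  }
  counts <- table(labels)
  if (min(counts) < k || k >= n) {
    return(as.list(seq_len(n)))
  }
  fold <- integer(n)
  for (lv in names(counts)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  unname(split(seq_len(n), fold))
}

# Rank-based (Mann-Whitney) AUC of scores for the second factor level,
# ties counted one half.
.auc_rank <- function(scores, labels) {
  lv <- levels(labels)
  pos <- labels == lv[2L]
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.as_two_level_factor <- function(labels) {
  f <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (nlevels(f) != 2L) {
    stop("labels must contain exactly two classes, got ", nlevels(f))
  }
  f
}

# -1/+1 coding, second level positive.
.y_pm1 <- function(labels) {
  f <- .as_two_level_factor(labels)
  ifelse(f == levels(f)[2L], 1, -1)
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stop(name, " must be a single number in (0, 1)")
  }
  invisible(x)
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}
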