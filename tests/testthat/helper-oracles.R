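# Independent brute-force oracles used to check the package's
# implementations on small inputs.

# Two-sided Wilcoxon signed-rank p by explicit enumeration of all 2^n
# sign assignments (tied midranks kept).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
}

# AUC by exhaustive pair counting, ties one half.
oracle_auc <- function(scores, labels) {
  lv <- levels(factor(labels))
  pos <- scores[labels == lv[2]]
  neg <- scores[labels == lv[1]]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Exact betweenness centrality by brute-force enumeration of all
# shortest paths on a small undirected graph (edge matrix over `nodes`).
oracle_betweenness <- function(nodes, edges) {
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  adj <- matrix(FALSE, n, n)
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      i <- idx[[edges[e, 1]]]; j <- idx[[edges[e, 2]]]
      adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  dist_from <- function(s) {
    d <- rep(Inf, n); d[s] <- 0; frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (u in frontier) for (v in which(adj[u, ])) {
        if (!is.finite(d[v])) { d[v] <- d[u] + 1; nxt <- c(nxt, v) }
      }
      frontier <- unique(nxt)
    }
    d
  }
  D <- t(vapply(seq_len(n), dist_from, numeric(n)))
  paths <- function(s, t) { # all shortest s->t paths as vertex vectors
    if (s == t) return(list(s))
    out <- list()
    for (u in which(adj[, t])) {
      if (is.finite(D[s, u]) && D[s, u] == D[s, t] - 1) {
        for (p in paths(s, u)) out[[length(out) + 1L]] <- c(p, t)
      }
    }
    out
  }
  btw <- stats::setNames(numeric(n), nodes)
  if (n < 2L) return(btw)
  for (s in seq_len(n - 1L)) for (t in seq.int(s + 1L, n)) {
    if (!is.finite(D[s, t]) || D[s, t] == 0) next
    ps <- paths(s, t)
    for (p in ps) {
      for (v in setdiff(p, c(s, t))) btw[v] <- btw[v] + 1 / length(ps)
    }
  }
  btw
}

# Hypergeometric upper tail by direct combinatorial enumeration.
oracle_hyper_upper <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Single-component PLS1-DA scores computed inline (independent of the
# package's fit path).
oracle_pls1_scores <- function(x, y) {
  xc <- scale(x, scale = FALSE)
  yc <- y - mean(y)
  w <- t(xc) %*% yc
  w <- w / sqrt(sum(w^2))
  as.vector(xc %*% w)
}
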