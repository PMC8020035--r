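two_class <- function(n_per_class) {
  factor(rep(c("t1", "t2"), each = n_per_class), levels = c("t1", "t2"))
}

test_that("PCA explains rank-1 data fully and reconstructs the matrix", {
  direction <- c(1, 2, -1, 0.5)
  x <- outer(c(-2, -1, 0, 1, 2), direction) # points on a line
  p <- suppressWarnings(pca_model(x, n_components = 4))
  expect_equal(p$explained[1], 1, tolerance = 1e-12)

  set.seed(3)
  y <- matrix(rnorm(6 * 4), 6, 4)
  pf <- pca_model(y, n_components = 4)
  recon <- pf$scores %*% t(pf$loadings)
  expect_equal(recon, unname(scale(y, scale = FALSE)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(pf$explained) <= 1e-12))
  expect_lte(sum(pf$explained), 1 + 1e-12)

  # two samples: PC1 score separation equals the Euclidean distance
  z <- rbind(c(0, 0, 0), c(3, 4, 0))
  pz <- suppressWarnings(pca_model(z, n_components = 1))
  expect_equal(abs(diff(pz$scores[, 1])), 5, tolerance = 1e-12)
})

test_that("OPLS-DA with zero orthogonal components is single-component PLS1-DA", {
  set.seed(12)
  x <- matrix(rnorm(10 * 8), 10, 8)
  labels <- two_class(5)
  fit <- fit_oplsda(x, labels, n_orthogonal = 0)
  oracle <- oracle_pls1_scores(x, .y <- ifelse(labels == "t2", 1, -1))
  expect_lt(max(abs(abs(fit$scores) - abs(oracle))), 1e-8)
  expect_equal(fit$n_orthogonal, 0L)
})

test_that("an orthogonal confound is removed without touching predictive loadings", {
  set.seed(13)
  y <- ifelse(two_class(5) == "t2", 1, -1)
  a <- rnorm(12)
  clean <- outer(y, a) + matrix(rnorm(10 * 12, 0, 1e-4), 10, 12)
  t_orth <- rnorm(10)
  t_orth <- t_orth - mean(t_orth)
  t_orth <- t_orth - y * sum(t_orth * y) / sum(y * y) # orthogonal to y
  confounded <- clean + outer(t_orth, rnorm(12))
  f_clean <- fit_oplsda(clean, two_class(5), 0)
  f_conf <- fit_oplsda(confounded, two_class(5), 1)
  expect_lt(max(abs(abs(f_conf$weights) - abs(f_clean$weights))), 1e-6)
  expect_equal(f_conf$n_orthogonal, 1L)

  # perfectly separable constant rows give R2Y = 1
  perf <- rbind(matrix(1, 3, 4), matrix(-1, 3, 4)) +
    outer(rep(c(0.01, -0.01, 0), 2), rep(1, 4))
  fp <- fit_oplsda(outer(ifelse(two_class(3) == "t2", 1, -1), rnorm(4)),
                   two_class(3), 0)
  expect_equal(fp$R2Y, 1, tolerance = 1e-10)
  expect_error(fit_oplsda(matrix(rnorm(8), 4, 2),
                          factor(rep("a", 4))), "two classes")
})

test_that("double cross-validated Q2 rewards signal and is seed-stable", {
  set.seed(14)
  labels <- two_class(10)
  strong <- outer(ifelse(labels == "t2", 1, -1), rep(1, 6)) +
    matrix(rnorm(20 * 6, 0, 0.05), 20, 6)
  d1 <- double_cv_q2(strong, labels, seed = 5)
  expect_gt(d1$Q2, 0.9)
  d2 <- double_cv_q2(strong, labels, seed = 5)
  expect_identical(d1$Q2, d2$Q2)
  # model-fit invariants
  fit <- fit_oplsda(strong, labels, 0)
  expect_true(fit$R2Y >= 0 && fit$R2Y <= 1)
  expect_lte(d1$Q2, fit$R2Y)
  expect_error(double_cv_q2(strong[c(1, 11), ], labels[c(1, 11)]),
               "at least 2")
})

test_that("permutation p-values respect the add-one formula and the seed", {
  set.seed(15)
  labels <- two_class(10) # large enough that permutations rarely
  strong <- outer(ifelse(labels == "t2", 1, -1), rep(1, 4)) + # recreate
    matrix(rnorm(80, 0, 0.05), 20, 4) # the original labelling
  p <- permutation_test(strong, labels, "R2Y", n_perm = 99, seed = 2)
  expect_equal(p$p.value, 1 / 100) # observed beats every permutation
  expect_true(all(p$permuted < p$observed))
  p2 <- permutation_test(strong, labels, "R2Y", n_perm = 99, seed = 2)
  expect_identical(p$p.value, p2$p.value)
  expect_gte(p$p.value, 1 / 100)
  expect_lte(p$p.value, 1)

  # p floor: (#{perm >= obs} + 1) / (n_perm + 1) stays in (0, 1]
  noise <- matrix(rnorm(80), 20, 4)
  pn <- permutation_test(noise, labels, "R2Y", n_perm = 19, seed = 3)
  expect_gte(pn$p.value, 1 / 20)
  expect_lte(pn$p.value, 1)
})

test_that("Ward clustering order matches brute-force agglomeration", {
  # Lance-Williams update for ward.D2 on squared distances
  oracle_merges <- function(x) {
    n <- nrow(x)
    d2 <- as.matrix(dist(x))^2
    size <- rep(1, n)
    active <- seq_len(n)
    id <- -seq_len(n) # hclust convention: negatives are leaves
    merges <- list()
    for (step in seq_len(n - 1)) {
      best <- c(NA, NA); bv <- Inf
      for (i in seq_along(active)) for (j in seq_along(active)) {
        if (i >= j) next
        v <- d2[active[i], active[j]]
        if (v < bv - 1e-12) { bv <- v; best <- c(i, j) }
      }
      i <- best[1]; j <- best[2]
      ai <- active[i]; aj <- active[j]
      merges[[step]] <- sort(c(id[ai], id[aj]))
      ni <- size[ai]; nj <- size[aj]
      for (k in seq_along(active)) {
        ak <- active[k]
        if (ak %in% c(ai, aj)) next
        nk <- size[ak]
        d2[ai, ak] <- d2[ak, ai] <-
          ((ni + nk) * d2[ai, ak] + (nj + nk) * d2[aj, ak] -
             nk * d2[ai, aj]) / (ni + nj + nk)
      }
      size[ai] <- ni + nj
      id[ai] <- step
      active <- active[-j]
    }
    merges
  }
  set.seed(16)
  x <- matrix(rnorm(8 * 3), 8, 3)
  co <- hierarchical_heatmap_order(x)
  got <- lapply(seq_len(nrow(co$row_hclust$merge)), function(i) {
    sort(co$row_hclust$merge[i, ])
  })
  expect_identical(got, oracle_merges(x))
  expect_true(all(diff(co$row_hclust$height) >= -1e-12))
  expect_identical(sort(co$row_order), 1:8)

  # nearest identical rows merge first
  y <- rbind(c(0, 0), c(0, 0), c(9, 9))
  cy <- hierarchical_heatmap_order(y)
  expect_identical(sort(cy$row_hclust$merge[1, ]), c(-2L, -1L))

  # permuting rows preserves the dendrogram topology (sorted heights)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  cp <- hierarchical_heatmap_order(x[perm, ])
  expect_equal(sort(cp$row_hclust$height), sort(co$row_hclust$height),
               tolerance = 1e-12)

  single <- hierarchical_heatmap_order(x[1, , drop = FALSE])
  expect_identical(single$row_order, 1L)
})
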