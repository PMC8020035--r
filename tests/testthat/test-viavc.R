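test_that("random combination matrices are Bernoulli, seeded, and never empty", {
  m <- random_combination_matrix(200, 1000, 0.5, seed = 1)
  rate <- colMeans(m)
  expect_gte(mean(rate >= 0.45 & rate <= 0.55), 0.99)
  expect_identical(m, random_combination_matrix(200, 1000, 0.5, seed = 1))
  # forced all-zero draws are regenerated
  sparse <- random_combination_matrix(3, 200, 0.1, seed = 2)
  expect_true(all(rowSums(sparse) > 0))
  expect_error(random_combination_matrix(0, 10), ">= 1")
  expect_error(random_combination_matrix(10, 10, 1.5), "inclusion_prob")
})

test_that("subset AUC honours separation, symmetry, and the null range", {
  labels <- factor(rep(c("a", "b"), each = 6))
  x <- cbind(sep = rep(c(0, 1), each = 6),
             noise = rnorm(12))
  expect_equal(as.numeric(subset_auc(x, labels, "sep", seed = 1)), 1)

  set.seed(30)
  xr <- matrix(rnorm(40 * 5), 40, 5)
  colnames(xr) <- paste0("bin", 1:5)
  l40 <- factor(rep(c("a", "b"), each = 20))
  # with the scores held fixed, flipping the positive class maps the raw
  # AUC to its complement; retraining under flipped labels flips the
  # scores too, leaving the raw AUC invariant (leave-one-out folds make
  # the fold assignment deterministic)
  a <- subset_auc(xr, l40, 1:5, folds = 40, orient = FALSE)
  s <- attr(a, "scores")
  lf <- factor(as.character(l40), levels = c("b", "a"))
  expect_equal(urometab:::.auc_rank(s, lf), 1 - as.numeric(a),
               tolerance = 1e-12)
  refit <- subset_auc(xr, lf, 1:5, folds = 40, orient = FALSE)
  expect_equal(as.numeric(refit), as.numeric(a), tolerance = 1e-12)
  expect_gte(as.numeric(subset_auc(xr, lf, 1:5, folds = 40)), 0.5)

  # null CV-AUC stays within two SDs of chance (the null spread of a
  # cross-validated AUC at n = 40 is about 0.14)
  inside <- vapply(1:40, function(r) {
    set.seed(400 + r)
    xn <- matrix(rnorm(40 * 5), 40, 5)
    a <- as.numeric(subset_auc(xn, l40, 1:5, seed = r))
    a >= 0.25 && a <= 0.75
  }, TRUE)
  expect_gte(mean(inside), 0.9)

  expect_error(subset_auc(xr, l40, "nope"), "unknown")
  expect_error(subset_auc(xr, l40, character()), "nonempty")
})

test_that("the ranking recovers a planted bin and respects redundancy", {
  l40 <- factor(rep(c("a", "b"), each = 20))
  first <- vapply(1:10, function(sd) {
    set.seed(sd)
    x <- matrix(rnorm(40 * 50), 40, 50)
    x[21:40, 7] <- x[21:40, 7] + 2
    colnames(x) <- paste0("bin", 1:50)
    r <- rank_variables(x, l40, n_rows = 200, n_perm_category = 0,
                        seed = sd + 100)
    r$table$bin[1] == "bin7"
  }, TRUE)
  expect_gte(sum(first), 9)

  # two duplicated informative bins both rank near the top
  set.seed(31)
  x <- matrix(rnorm(40 * 20), 40, 20)
  x[21:40, 3] <- x[21:40, 3] + 2
  x[, 4] <- x[, 3] + rnorm(40, 0, 0.05)
  colnames(x) <- paste0("bin", 1:20)
  r <- rank_variables(x, l40, n_rows = 300, n_perm_category = 0,
                      seed = 32)
  expect_true(all(c("bin3", "bin4") %in% r$table$bin[1:3]))
  expect_setequal(r$table$bin, colnames(x)) # ranking is a permutation
})

test_that("shuffled labels rarely categorize any bin as significant", {
  clean <- vapply(1:20, function(r) {
    set.seed(600 + r)
    x <- matrix(rnorm(40 * 30), 40, 30)
    colnames(x) <- paste0("bin", 1:30)
    l <- factor(sample(rep(c("a", "b"), each = 20)))
    rk <- rank_variables(x, l, n_rows = 100, seed = 700 + r)
    !any(rk$table$category == "positive")
  }, TRUE)
  expect_gte(mean(clean), 0.9)
})

test_that("best-subset selection is parsimonious and pure in its seed", {
  l40 <- factor(rep(c("a", "b"), each = 20))
  set.seed(33)
  x <- matrix(rnorm(40 * 20), 40, 20)
  x[21:40, 5] <- x[21:40, 5] + 4 # one dominant bin
  colnames(x) <- paste0("bin", 1:20)
  v1 <- viavc(x, l40, n_rows = 200, n_perm_category = 0, seed = 9)
  expect_identical(v1$best_subset, "bin5") # parsimony tie-break
  v2 <- viavc(x, l40, n_rows = 200, n_perm_category = 0, seed = 9)
  expect_identical(v1$ranking$table, v2$ranking$table)
  expect_identical(v1$best_auc, v2$best_auc)
  expect_true(all(v1$best_subset %in% v1$ranking$table$bin))
  expect_true(v1$best_auc >= 0.5 && v1$best_auc <= 1)

  # the F-ranked head is exactly the top of the ranking
  expect_identical(top_ranked(v1$ranking, 7), v1$ranking$table$bin[1:7])

  expect_warning(best_subset(v1$ranking, x, l40, max_k = 99),
                 "capped")
})

test_that("appending a noise bin cannot buy more than Monte-Carlo noise in AUC", {
  l40 <- factor(rep(c("a", "b"), each = 20))
  gains <- vapply(1:10, function(r) {
    set.seed(800 + r)
    x <- matrix(rnorm(40 * 10), 40, 10)
    x[21:40, 1] <- x[21:40, 1] + 3
    colnames(x) <- paste0("bin", 1:10)
    a1 <- as.numeric(subset_auc(x, l40, "bin1", seed = r))
    a2 <- as.numeric(subset_auc(x, l40, c("bin1", "bin2"), seed = r))
    a2 - a1
  }, 0)
  expect_lte(mean(gains), 0.02)
})
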