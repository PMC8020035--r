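# Paired univariate testing per bin: Shapiro-Wilk on the paired
# differences routes each bin to a paired t-test or a Wilcoxon
# signed-rank test (exact null distribution, ties handled, for n <= 25).

#' Exact Wilcoxon signed-rank test on paired differences
#'
#' Zeros are dropped; ranks of |d| use midranks for ties. The statistic V
#' is the sum of ranks of the positive differences. For `n <= exact_max`
#' the null distribution of V (each rank signed + with probability 1/2)
#' is computed exactly by convolution over doubled ranks, so tied ranks
#' remain exact; the two-sided p-value is P(|V - E| >= |v - E|) under
#' that symmetric distribution. Beyond `exact_max` a normal approximation
#' with tie-corrected variance is used.
#'
#' @param d numeric vector of paired differences.
#' @param exact_max largest n for which the exact distribution is used.
#' @return List: `statistic` (V), `p.value`, `n` (nonzero differences),
#'   `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(d, exact_max = 25L) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (n <= exact_max) {
    # doubled ranks are integers even with .5 midranks
    r2 <- as.integer(round(2 * r))
    # pmf of sum of a random subset of r2, via polynomial product
    pmf <- rep(0, sum(r2) + 1L)
    pmf[1L] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), pmf[seq_len(length(pmf) - ri)])
      pmf <- (pmf + shifted) / 2
    }
    support <- (seq_along(pmf) - 1L) / 2
    dev <- abs(support - mu)
    p <- sum(pmf[dev >= abs(v - mu) - 1e-9])
    exact <- TRUE
  } else {
    sigma2 <- sum(r^2) / 4
    z <- (v - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  list(statistic = v, p.value = min(1, p), n = n, exact = exact)
}

#' Shapiro-Wilk-routed paired test for one bin
#'
#' Normality is assessed on the paired differences (the quantity whose
#' distribution the paired t-test assumes). If the Shapiro-Wilk p-value
#' exceeds `alpha_normality` the bin is tested by a paired t-test,
#' otherwise by the Wilcoxon signed-rank test. Bins whose differences are
#' all identical are degenerate and reported untestable.
#'
#' @param t1,t2 per-subject values at the two timepoints (same order).
#' @param alpha_normality routing threshold for the Shapiro-Wilk p-value.
#' @return List of class `bin_test_result`: `test` ("paired-t",
#'   "wilcoxon-signed-rank", or "untestable"), `statistic`, `p.value`,
#'   `direction` (sign of the mean paired difference t2 - t1),
#'   `shapiro_p`.
#' @export
route_and_test <- function(t1, t2, alpha_normality = 0.05) {
  if (length(t1) != length(t2)) stop("t1 and t2 must pair up")
  if (anyNA(t1) || anyNA(t2)) stop("missing pair values are not allowed")
  if (length(t1) < 3L) stop("at least 3 complete pairs are required")
  .check_prob(alpha_normality, "alpha_normality")
  d <- t2 - t1
  direction <- sign(mean(d))
  if (stats::sd(d) == 0) {
    return(structure(list(test = "untestable", statistic = NA_real_,
                          p.value = NA_real_, direction = direction,
                          shapiro_p = NA_real_),
                     class = "bin_test_result"))
  }
  sw <- stats::shapiro.test(d)$p.value
  if (sw > alpha_normality) {
    tt <- stats::t.test(d)
    structure(list(test = "paired-t",
                   statistic = unname(tt$statistic),
                   p.value = tt$p.value, direction = direction,
                   shapiro_p = sw),
              class = "bin_test_result")
  } else {
    wt <- wilcoxon_signed_rank(d)
    structure(list(test = "wilcoxon-signed-rank",
                   statistic = wt$statistic, p.value = wt$p.value,
                   direction = direction, shapiro_p = sw),
              class = "bin_test_result")
  }
}

#' Paired testing of every bin between timepoints
#'
#' No multiplicity correction is applied at this stage; the significant
#' set at level `alpha` feeds the multivariate and pathway stages.
#'
#' @param matrix a `processed_matrix` or samples-by-bins matrix.
#' @param subject,timepoint sample metadata vectors; taken from the
#'   `processed_matrix` metadata when omitted. Every subject must have
#'   exactly one sample per timepoint.
#' @param alpha significance level for the returned significant set.
#' @param alpha_normality Shapiro-Wilk routing threshold.
#' @return List: `results` (data frame: bin, test, statistic, p,
#'   direction, shapiro_p), `significant` (bin column names with
#'   p < alpha).
#' @export
test_all_bins <- function(matrix, subject = NULL, timepoint = NULL,
                          alpha = 0.05, alpha_normality = 0.05) {
  x <- if (inherits(matrix, "processed_matrix")) matrix$values else
    as.matrix(matrix)
  if (is.null(subject) || is.null(timepoint)) {
    meta <- if (inherits(matrix, "processed_matrix")) matrix$meta else NULL
    if (is.null(meta)) stop("subject and timepoint metadata are required")
    subject <- meta$subject
    timepoint <- meta$timepoint
  }
  tps <- sort(unique(timepoint))
  if (length(tps) != 2L) stop("exactly two timepoints are required")
  i1 <- which(timepoint == tps[1L])
  i2 <- which(timepoint == tps[2L])
  if (length(i1) != length(i2) ||
      !setequal(subject[i1], subject[i2]) ||
      anyDuplicated(subject[i1]) || anyDuplicated(subject[i2])) {
    stop("design is not fully paired: every subject needs both timepoints")
  }
  i2 <- i2[match(subject[i1], subject[i2])]
  if (ncol(x) == 0L) {
    return(list(results = data.frame(bin = character(), test = character(),
                                     statistic = numeric(), p = numeric(),
                                     direction = numeric(),
                                     shapiro_p = numeric()),
                significant = character()))
  }
  rows <- lapply(seq_len(ncol(x)), function(b) {
    r <- route_and_test(x[i1, b], x[i2, b], alpha_normality)
    data.frame(bin = colnames(x)[b], test = r$test,
               statistic = r$statistic, p = r$p.value,
               direction = r$direction, shapiro_p = r$shapiro_p,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  sig <- results$bin[!is.na(results$p) & results$p < alpha]
  list(results = results, significant = sig)
}
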