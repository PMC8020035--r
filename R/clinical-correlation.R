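# Clinical prognostic analysis: SCIM percent-difference, metabolite
# deltas, and Bonferroni-screened Pearson correlations between clinical
# improvement and metabolite levels.

#' SCIM percent difference
#'
#' 100 * (post - pre) / ((post + pre) / 2): the change between the two
#' assessments expressed relative to their mean, so the measure is
#' antisymmetric under swapping pre and post.
#'
#' @param pre,post SCIM scores (0-100); vectorized.
#' @return Percent difference(s).
#' @export
#' @examples
#' scim_pct_diff(77, 100) # 25.99
scim_pct_diff <- function(pre, post) {
  if (any(pre + post <= 0)) {
    stop("percent difference is undefined when pre + post = 0")
  }
  100 * (post - pre) / ((post + pre) / 2)
}

#' Mean and SD of raw SCIM improvement
#'
#' @param records data frame with columns `scim_pre` and `scim_post`
#'   (one row per subject).
#' @return List: `mean`, `sd` (sample, n-1) of post - pre, plus the
#'   per-subject differences.
#' @export
improvement_summary <- function(records) {
  if (nrow(records) < 2L) stop("at least 2 records are required")
  d <- records$scim_post - records$scim_pre
  list(mean = mean(d), sd = stats::sd(d), differences = d)
}

#' Metabolite delta between timepoints
#'
#' delta = initial - post (initial concentration minus post-recovery
#' concentration); `convention = "post_minus_initial"` flips the sign
#' for the more common convention.
#'
#' @param initial,post numeric vectors or matrices (element-wise).
#' @param convention sign convention.
#' @return delta, same shape as the inputs.
#' @export
metabolite_delta <- function(initial, post,
                             convention = c("initial_minus_post",
                                            "post_minus_initial")) {
  convention <- match.arg(convention)
  if (any(!is.finite(initial)) || any(!is.finite(post))) {
    stop("metabolite levels must be finite")
  }
  if (convention == "initial_minus_post") initial - post else post - initial
}

#' Load a clinical table
#'
#' @param path CSV with columns `subject`, `sci_type`, `asia`,
#'   `lesion_location`, `comorbidities`, `age`, `scim_pre`, `scim_post`
#'   (extra columns are kept).
#' @return Validated data frame.
#' @export
load_clinical <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject", "scim_pre", "scim_post")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("clinical table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (any(is.na(d$scim_pre)) || any(is.na(d$scim_post))) {
    stop("pre and post SCIM scores must both be present for every subject")
  }
  if (any(d$scim_pre < 0 | d$scim_pre > 100 |
          d$scim_post < 0 | d$scim_post > 100)) {
    stop("SCIM scores must lie within [0, 100]")
  }
  d
}

#' Bundled six-patient spinal-cord-injury pilot cohort
#'
#' Clinical characteristics of a six-patient male SCI pilot cohort
#' (SCI type, ASIA grade, lesion location, age, and SCIM scores at about
#' one month and six months post-injury), shipped with the package as a
#' worked clinical input.
#'
#' @return Data frame with one row per patient.
#' @export
#' @examples
#' cohort <- sci_pilot_cohort()
#' improvement_summary(cohort)
sci_pilot_cohort <- function() {
  load_clinical(system.file("extdata", "sci_pilot_clinical.csv",
                            package = "urometab", mustWork = TRUE))
}

#' Bonferroni-screened Pearson correlations with clinical improvement
#'
#' For each tested bin and each predictor family (initial level at the
#' first timepoint; delta between timepoints) the Pearson R against the
#' SCIM percent difference is computed with its two-sided p-value from
#' the exact t transform (df = n - 2). Each family is Bonferroni
#' corrected over the same tested-bin list (alpha / n_tested);
#' `pool_families = TRUE` corrects over both families jointly
#' (alpha / (2 n_tested)) instead.
#'
#' @param initial_matrix subjects-by-bins matrix of initial levels.
#' @param delta_matrix subjects-by-bins matrix of deltas (same columns).
#' @param pct_diffs per-subject SCIM percent differences.
#' @param tested_bins bin names to screen (e.g. the 19-bin F-ranked head).
#' @param alpha family-wise level before Bonferroni division.
#' @param pool_families pool the two predictor families into one
#'   Bonferroni family.
#' @return Data frame of class `correlation_screen`: bin, predictor
#'   (`"initial"` or `"delta"`), `r`, `p`, `threshold`, `significant`;
#'   sorted by |R| descending. Zero-variance predictors yield NA and are
#'   never significant.
#' @export
correlate_biomarkers <- function(initial_matrix, delta_matrix, pct_diffs,
                                 tested_bins, alpha = 0.05,
                                 pool_families = FALSE) {
  if (length(tested_bins) == 0L) stop("tested_bins must be nonempty")
  n <- length(pct_diffs)
  if (n < 3L) stop("at least 3 subjects are required")
  init <- as.matrix(initial_matrix)
  delt <- as.matrix(delta_matrix)
  missing <- setdiff(tested_bins, colnames(init))
  if (length(missing)) {
    stop("tested bins absent from the matrices: ",
         paste(missing, collapse = ", "))
  }
  n_tests <- if (pool_families) 2L * length(tested_bins) else
    length(tested_bins)
  threshold <- alpha / n_tests
  one <- function(xv, kind, bin) {
    if (stats::sd(xv) == 0 || stats::sd(pct_diffs) == 0) {
      return(data.frame(bin = bin, predictor = kind, r = NA_real_,
                        p = NA_real_, threshold = threshold,
                        significant = FALSE, stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(xv, pct_diffs, method = "pearson")
    data.frame(bin = bin, predictor = kind, r = unname(ct$estimate),
               p = ct$p.value, threshold = threshold,
               significant = ct$p.value < threshold,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(
    lapply(tested_bins, function(b) one(init[, b], "initial", b)),
    lapply(tested_bins, function(b) one(delt[, b], "delta", b))
  ))
  out <- out[order(-abs(out$r), out$bin, out$predictor, na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("correlation_screen", "data.frame")
  out
}
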