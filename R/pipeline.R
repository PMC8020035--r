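# End-to-end pipeline: simulate (or load) spectra, align, bin,
# preprocess, univariate + VIAVC selection, multivariate models on the
# union of significant bins, ROC on the best subset, clinical
# correlations on the top F-ranked bins, pathway screen. Every stage
# writes plain-text artifacts plus a provenance manifest, and the whole
# run is a deterministic function of its configuration and seed.

#' Assign bins to metabolites and pathway compounds
#'
#' A bin is assigned to the library metabolite whose highest-intensity
#' peak centre falls inside the bin's ppm interval; bins containing no
#' library peak stay unassigned.
#'
#' @param bins bin data frame (from [adaptive_bin()]).
#' @param library a peak library.
#' @return Data frame: `bin` (bin%03d name), `metabolite`, `compound_id`
#'   (NA when unassigned).
#' @export
assign_bins <- function(bins, library = default_peak_library()) {
  out <- data.frame(bin = sprintf("bin%03d", bins$bin),
                    metabolite = NA_character_,
                    compound_id = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(bins))) {
    hit <- library[library$ppm_center >= bins$ppm_lo[i] &
                     library$ppm_center < bins$ppm_hi[i], , drop = FALSE]
    if (nrow(hit)) {
      best <- hit[which.max(hit$rel_intensity), ]
      out$metabolite[i] <- best$metabolite
      out$compound_id[i] <- best$compound_id
    }
  }
  out
}

#' Run the full paired-metabolomics analysis pipeline
#'
#' Stages: simulate (or load) -> align -> bin -> preprocess ->
#' univariate -> viavc -> multivariate -> roc -> correlate -> pathway.
#' Bins carried into the multivariate stage are the union of the
#' univariate-significant bins and the VIAVC best subset. Artifacts are
#' written to `out_dir` as CSV/JSON with a provenance manifest.
#'
#' @param out_dir output directory (created; pass `NULL` to skip writing).
#' @param config a [cohort_config()] used to simulate when no spectra
#'   are supplied; its seed also seeds every downstream stage.
#' @param spectra optional list of `urometab_spectrum` (skips simulation).
#' @param clinical optional clinical data frame (required with `spectra`).
#' @param library peak library used for simulation and bin assignment.
#' @param pathway_library a `pathway_library`.
#' @param alpha significance level for the univariate screen and the
#'   correlation threshold's numerator.
#' @param n_perm permutations for the R2Y and Q2 permutation tests.
#' @param viavc_rows random combinations in the VIAVC ranking.
#' @param max_k largest VIAVC subset size.
#' @param folds CV folds (collapses to leave-one-out on tiny classes).
#' @param top_f size of the F-ranked head screened for clinical
#'   correlations.
#' @return List of class `urometab_run` with every stage's results and
#'   the manifest.
#' @export
run_pipeline <- function(out_dir = NULL, config = cohort_config(),
                         spectra = NULL, clinical = NULL,
                         library = default_peak_library(),
                         pathway_library = load_pathway_library(),
                         alpha = 0.05, n_perm = 2000L,
                         viavc_rows = 500L, max_k = 10L, folds = 10L,
                         top_f = 19L) {
  seed <- config$seed
  stages <- character()
  write_dir <- !is.null(out_dir)
  if (write_dir) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit_csv <- function(obj, name) {
    if (write_dir) utils::write.csv(obj, file.path(out_dir, name),
                                    row.names = FALSE)
  }

  # -- simulate / load ------------------------------------------------
  truth <- NULL
  if (is.null(spectra)) {
    cohort <- generate_cohort(config, library)
    spectra <- cohort$spectra
    clinical <- cohort$clinical
    truth <- cohort$truth
    stages <- c(stages, "simulate")
  } else if (is.null(clinical)) {
    stop("clinical table is required when spectra are supplied")
  }

  # -- align ----------------------------------------------------------
  ref <- mean_spectrum(spectra)
  aligned <- lapply(spectra, align_to_reference, reference = ref)
  ref2 <- mean_spectrum(aligned) # reference recomputed once after pass 1
  aligned <- lapply(aligned, align_to_reference, reference = ref2)
  stages <- c(stages, "align")

  # -- bin + integrate ------------------------------------------------
  bins <- adaptive_bin(mean_spectrum(aligned))
  table <- integrate_bins(aligned, bins)
  emit_csv(bins, "bins.csv")
  emit_csv(data.frame(sample_id = rownames(table$values), table$values),
           "bin_table.csv")
  stages <- c(stages, "bin")

  # -- preprocess -----------------------------------------------------
  pm <- preprocess(table)
  emit_csv(data.frame(sample_id = rownames(pm$values), pm$values),
           "processed.csv")
  stages <- c(stages, "preprocess")

  labels <- factor(table$meta$timepoint)
  subject <- table$meta$subject

  # -- univariate -----------------------------------------------------
  uni <- test_all_bins(pm, subject, as.character(labels), alpha = alpha)
  emit_csv(uni$results, "univariate.csv")
  stages <- c(stages, "univariate")

  # -- viavc ----------------------------------------------------------
  vres <- viavc(pm, labels, n_rows = viavc_rows, folds = folds,
                max_k = max_k, subject = subject, seed = seed)
  emit_csv(vres$ranking$table, "viavc_ranking.csv")
  stages <- c(stages, "viavc")

  # -- multivariate on the union of significant bins ------------------
  union_bins <- union(uni$significant, vres$best_subset)
  if (length(union_bins) < 2L) {
    union_bins <- top_ranked(vres$ranking, max(2L, length(union_bins)))
  }
  xm <- pm$values[, union_bins, drop = FALSE]
  pca <- pca_model(xm, n_components = 2L)
  dcv <- double_cv_q2(xm, labels, folds, folds, seed = seed,
                      subject = subject)
  n_ortho <- as.integer(round(stats::median(dcv$n_orthogonal)))
  model <- fit_oplsda(xm, labels, n_ortho)
  p_r2y <- permutation_test(xm, labels, "R2Y", n_perm = n_perm,
                            seed = seed, n_orthogonal = n_ortho)
  p_q2 <- permutation_test(xm, labels, "Q2", n_perm = n_perm,
                           seed = seed, outer_folds = folds,
                           inner_folds = folds, subject = subject)
  clust <- hierarchical_heatmap_order(xm)
  stages <- c(stages, "multivariate")

  # -- roc on the best subset -----------------------------------------
  bs_auc <- subset_auc(pm, labels, vres$best_subset, folds, seed = seed,
                       subject = subject)
  roc <- roc_curve(attr(bs_auc, "scores"), labels)
  ci <- bootstrap_ci(attr(bs_auc, "scores"), labels, seed = seed)
  emit_csv(roc$curve, "roc_curve.csv")
  stages <- c(stages, "roc")

  # -- clinical correlations on the top F-ranked bins -----------------
  normalized <- attr(pm, "normalized")
  i1 <- which(table$meta$timepoint == levels(labels)[1L])
  i2 <- which(table$meta$timepoint == levels(labels)[2L])
  i2 <- i2[match(subject[i1], subject[i2])]
  init_mat <- normalized$values[i1, , drop = FALSE]
  post_mat <- normalized$values[i2, , drop = FALSE]
  rownames(init_mat) <- rownames(post_mat) <- subject[i1]
  delta_mat <- metabolite_delta(init_mat, post_mat)
  cl <- clinical[match(subject[i1], clinical$subject), ]
  pct <- scim_pct_diff(cl$scim_pre, cl$scim_post)
  tested <- intersect(top_ranked(vres$ranking, top_f),
                      colnames(init_mat))
  correlations <- correlate_biomarkers(init_mat, delta_mat, pct, tested,
                                       alpha = alpha)
  emit_csv(correlations, "correlations.csv")
  stages <- c(stages, "correlate")

  # -- pathway screen -------------------------------------------------
  amap <- assign_bins(table$bins, library)
  emit_csv(amap, "bin_assignment.csv")
  sig_compounds <- unique(stats::na.omit(
    amap$compound_id[amap$bin %in% union_bins]))
  pathways <- pathway_screen(sig_compounds, pathway_library,
                             alpha = alpha)
  emit_csv(as.data.frame(pathways), "pathways.csv")
  stages <- c(stages, "pathway")

  manifest <- list(
    stages = stages, seed = seed,
    parameters = list(alpha = alpha, n_perm = n_perm,
                      viavc_rows = viavc_rows, max_k = max_k,
                      folds = folds, top_f = top_f),
    n_samples = nrow(table$values), n_bins = ncol(table$values),
    n_signal_bins = sum(table$bins$signal),
    n_significant_univariate = length(uni$significant),
    best_subset = vres$best_subset,
    model = list(R2Y = model$R2Y, Q2 = dcv$Q2,
                 n_orthogonal = n_ortho,
                 p_R2Y = p_r2y$p.value, p_Q2 = p_q2$p.value),
    roc = list(auc = as.numeric(bs_auc), ci = as.numeric(ci))
  )
  if (write_dir) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(
    list(manifest = manifest, clinical = clinical, truth = truth,
         bins = bins, table = table, processed = pm,
         univariate = uni, viavc = vres,
         pca = pca, model = model, dcv = dcv,
         perm_r2y = p_r2y, perm_q2 = p_q2, cluster = clust,
         roc = roc, roc_ci = ci, correlations = correlations,
         pathways = pathways, assignment = amap),
    class = "urometab_run"
  )
}

#' Summarize a pipeline run
#'
#' One table-like summary mirroring the analysis outputs: significant
#' bins, model statistics, best subset, top correlations, top pathways.
#'
#' @param object a `urometab_run`.
#' @param ... unused.
#' @return Invisibly, a list of summary components (also printed).
#' @export
summary.urometab_run <- function(object, ...) {
  m <- object$manifest
  cat("Paired urinary NMR metabolomics run\n")
  cat(sprintf("  samples: %d   bins: %d (%d signal)\n", m$n_samples,
              m$n_bins, m$n_signal_bins))
  cat(sprintf("  univariate-significant bins: %d\n",
              m$n_significant_univariate))
  cat(sprintf("  VIAVC best subset: %s (CV-AUC %.3f)\n",
              paste(m$best_subset, collapse = ", "), m$roc$auc))
  cat(sprintf("  OPLS-DA: R2Y = %.3f (p = %.4g), Q2 = %.3f (p = %.4g)\n",
              m$model$R2Y, m$model$p_R2Y, m$model$Q2, m$model$p_Q2))
  cat(sprintf("  ROC AUC = %.3f, 95%% CI %.3f-%.3f\n", m$roc$auc,
              m$roc$ci[1], m$roc$ci[2]))
  sig_cor <- object$correlations[object$correlations$significant, ]
  cat(sprintf("  significant clinical correlations: %d\n", nrow(sig_cor)))
  if (nrow(sig_cor)) {
    for (i in seq_len(min(5L, nrow(sig_cor)))) {
      cat(sprintf("    %s (%s): R = %.2f, p = %.3g\n", sig_cor$bin[i],
                  sig_cor$predictor[i], sig_cor$r[i], sig_cor$p[i]))
    }
  }
  cat(sprintf("  top pathway: %s (p = %.3g, impact %.2f)\n",
              object$pathways$name[1], object$pathways$p[1],
              object$pathways$impact[1]))
  invisible(list(manifest = m, correlations = sig_cor,
                 pathways = utils::head(object$pathways, 3L)))
}

#' @export
print.urometab_run <- function(x, ...) {
  summary(x)
  invisible(x)
}
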