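# Synthetic paired-cohort generator: Lorentzian/Gaussian mixture spectra
# with chemical-shift jitter, subject random effects, planted between-
# timepoint biomarkers, and clinical scores linearly coupled to designated
# biomarker levels.

#' Default simulated chemical-shift axis
#'
#' 0.5 to 9.5 ppm on 2048 points, increasing; dense enough that adaptive
#' binning is non-trivial yet small enough for fast simulation.
#'
#' @param n number of points.
#' @param range ppm window.
#' @return Numeric vector of chemical shifts (ppm).
#' @export
default_ppm_axis <- function(n = 2048L, range = c(0.5, 9.5)) {
  seq(range[1], range[2], length.out = n)
}

#' Construct an NMR spectrum object
#'
#' @param ppm strictly monotone chemical-shift axis (ppm).
#' @param intensity real intensities, same length as `ppm`.
#' @param sample_id sample identifier.
#' @param timepoint timepoint label (e.g. `"t1"`, `"t2"`).
#' @return An object of class `urometab_spectrum`.
#' @export
new_spectrum <- function(ppm, intensity, sample_id = NA_character_,
                         timepoint = NA_character_) {
  if (length(ppm) != length(intensity)) {
    stop("ppm and intensity must have the same length")
  }
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) stop("ppm axis must be strictly monotone")
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  structure(
    list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
         sample_id = sample_id, timepoint = timepoint),
    class = "urometab_spectrum"
  )
}

#' @export
print.urometab_spectrum <- function(x, ...) {
  cat("<urometab_spectrum>", x$sample_id,
      sprintf("[%s] %d points, %.2f-%.2f ppm\n", x$timepoint,
              length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Simulate one 1H NMR spectrum from a peak library
#'
#' Each metabolite contributes `concentration * rel_intensity` times a
#' unit-height lineshape at each of its library peaks. Chemical-shift
#' jitter is drawn once per metabolite (not per peak), mimicking the
#' pH-driven whole-multiplet shifts that phosphate buffering suppresses
#' but never fully removes. Gaussian read noise is added pointwise.
#'
#' @param concentrations named non-negative vector, metabolite -> level.
#' @param library peak library (see [default_peak_library()]).
#' @param jitter_sd SD of the per-metabolite ppm jitter.
#' @param noise_sd SD of additive Gaussian intensity noise.
#' @param baseline constant baseline amplitude (spectra are assumed
#'   baseline-corrected upstream, so the default is 0).
#' @param lineshape `"lorentzian"` (natural NMR lineshape) or `"gaussian"`.
#' @param ppm chemical-shift axis.
#' @param seed optional integer; same seed, same spectrum.
#' @param sample_id,timepoint labels stored on the spectrum.
#' @return An `urometab_spectrum`.
#' @export
#' @examples
#' sp <- generate_spectrum(c(creatinine = 1), default_peak_library(),
#'                         jitter_sd = 0, noise_sd = 0, seed = 1)
generate_spectrum <- function(concentrations, library,
                              jitter_sd = 0, noise_sd = 0, baseline = 0,
                              lineshape = c("lorentzian", "gaussian"),
                              ppm = default_ppm_axis(), seed = NULL,
                              sample_id = NA_character_,
                              timepoint = NA_character_) {
  lineshape <- match.arg(lineshape)
  validate_peak_library(library, range(ppm))
  if (is.null(names(concentrations)) && length(concentrations) > 0L) {
    stop("concentrations must be a named vector (metabolite -> level)")
  }
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  unknown <- setdiff(names(concentrations), library$metabolite)
  if (length(unknown)) {
    stop("concentrations reference metabolites absent from the library: ",
         paste(unknown, collapse = ", "))
  }
  .with_seed(seed, {
    intensity <- rep(baseline, length(ppm))
    mets <- names(concentrations)
    jitter <- stats::rnorm(length(mets), 0, jitter_sd)
    names(jitter) <- mets
    for (m in mets) {
      conc <- concentrations[[m]]
      if (conc == 0) next
      rows <- library[library$metabolite == m, , drop = FALSE]
      for (i in seq_len(nrow(rows))) {
        centre <- rows$ppm_center[i] + jitter[[m]]
        hw <- rows$linewidth_ppm[i] / 2 # half width at half maximum
        shape <- if (lineshape == "lorentzian") {
          hw^2 / ((ppm - centre)^2 + hw^2)
        } else {
          exp(-(ppm - centre)^2 / (2 * (rows$linewidth_ppm[i] / 2.355)^2))
        }
        intensity <- intensity + conc * rows$rel_intensity[i] * shape
      }
    }
    if (noise_sd > 0) {
      intensity <- intensity + stats::rnorm(length(ppm), 0, noise_sd)
    }
    new_spectrum(ppm, intensity, sample_id, timepoint)
  })
}

#' Configuration for the paired synthetic cohort
#'
#' Defaults emulate a small paired urinary NMR study: six subjects sampled
#' at two timepoints, three planted purine biomarkers shifting about
#' two-fold between timepoints, subject-level random effects and
#' within-subject biological noise on the natural-log concentration scale,
#' small chemical-shift jitter, and a SCIM-like 0-100 clinical score whose
#' improvement is linearly coupled (with noise) to a planted biomarker's
#' initial level.
#'
#' @param n_subjects number of subjects (>= 3); each contributes both
#'   timepoints.
#' @param planted named vector of natural-log fold effects applied at the
#'   second timepoint (names must be library metabolites).
#' @param subject_sd SD of the per-subject, per-metabolite random effect
#'   (natural-log scale).
#' @param sample_sd SD of the within-subject biological noise per sample
#'   (natural-log scale).
#' @param jitter_sd chemical-shift jitter SD (ppm).
#' @param baseline constant spectral baseline amplitude.
#' @param noise_sd spectral Gaussian noise SD (intensity units).
#' @param coupling named vector: SCIM improvement points per log10-unit of
#'   the metabolite's initial concentration (relative to its baseline).
#' @param coupling_sd SD of the clinical noise term (points).
#' @param scim_pre_mean,scim_pre_sd distribution of the initial score.
#' @param improvement_mean mean improvement in points.
#' @param lineshape lineshape passed to [generate_spectrum()].
#' @param seed integer RNG seed; fixed seed => bit-reproducible cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 6L,
                          planted = c(hypoxanthine = 0.7, inosine = 0.7,
                                      xanthine = -0.7),
                          subject_sd = 0.35, sample_sd = 0.28,
                          jitter_sd = 0.003, baseline = 0, noise_sd = 0.05,
                          coupling = c(hypoxanthine = -25),
                          coupling_sd = 4,
                          scim_pre_mean = 65, scim_pre_sd = 12,
                          improvement_mean = 11,
                          lineshape = "lorentzian", seed = 1L) {
  if (n_subjects < 3L) stop("n_subjects must be >= 3")
  sds <- c(subject_sd = subject_sd, sample_sd = sample_sd,
           jitter_sd = jitter_sd, noise_sd = noise_sd,
           coupling_sd = coupling_sd)
  if (any(sds < 0)) {
    stop("all SDs must be >= 0; offending: ",
         paste(names(sds)[sds < 0], collapse = ", "))
  }
  structure(
    list(n_subjects = as.integer(n_subjects), planted = planted,
         subject_sd = subject_sd, sample_sd = sample_sd,
         jitter_sd = jitter_sd, baseline = baseline, noise_sd = noise_sd,
         coupling = coupling, coupling_sd = coupling_sd,
         scim_pre_mean = scim_pre_mean, scim_pre_sd = scim_pre_sd,
         improvement_mean = improvement_mean,
         lineshape = lineshape, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a paired synthetic cohort with known ground truth
#'
#' One spectrum per subject per timepoint. Planted biomarkers shift by the
#' configured natural-log effect between timepoints; clinical scores are
#' generated by the configured linear coupling to initial biomarker levels
#' and clipped to \[0, 100\].
#'
#' @param config a [cohort_config()].
#' @param library a peak library.
#' @param base_levels named baseline concentrations per metabolite.
#' @return A list with elements `spectra` (list of `urometab_spectrum`,
#'   t1 then t2 blocks ordered by subject), `clinical` (data frame:
#'   subject, sci_type, asia, age, scim_pre, scim_post), and `truth`
#'   (list: concentrations array, planted effects, coupling).
#' @export
generate_cohort <- function(config = cohort_config(),
                            library = default_peak_library(),
                            base_levels = default_base_levels(library)) {
  stopifnot(inherits(config, "cohort_config"))
  validate_peak_library(library)
  mets <- unique(library$metabolite)
  bad <- setdiff(names(config$planted), mets)
  if (length(bad)) {
    stop("planted effects reference unknown metabolites: ",
         paste(bad, collapse = ", "))
  }
  bad <- setdiff(names(config$coupling), mets)
  if (length(bad)) {
    stop("clinical coupling references unknown metabolites: ",
         paste(bad, collapse = ", "))
  }
  base <- base_levels[mets]
  if (any(is.na(base))) stop("base_levels must cover every library metabolite")

  .with_seed(config$seed, {
    n <- config$n_subjects
    subjects <- sprintf("S%02d", seq_len(n))
    conc <- array(NA_real_, dim = c(n, length(mets), 2L),
                  dimnames = list(subjects, mets, c("t1", "t2")))
    effects <- stats::setNames(rep(0, length(mets)), mets)
    effects[names(config$planted)] <- config$planted
    for (s in seq_len(n)) {
      u <- stats::rnorm(length(mets), 0, config$subject_sd)
      for (tp in 1:2) {
        e <- stats::rnorm(length(mets), 0, config$sample_sd)
        lfc <- if (tp == 2L) effects else 0
        conc[s, , tp] <- base * exp(u + lfc + e)
      }
    }
    spectra <- vector("list", 2L * n)
    k <- 0L
    for (tp in 1:2) {
      for (s in seq_len(n)) {
        k <- k + 1L
        spectra[[k]] <- generate_spectrum(
          stats::setNames(conc[s, , tp], mets), library,
          jitter_sd = config$jitter_sd, noise_sd = config$noise_sd,
          baseline = config$baseline, lineshape = config$lineshape,
          sample_id = sprintf("%s_t%d", subjects[s], tp),
          timepoint = paste0("t", tp)
        )
      }
    }
    pre <- pmin(100, pmax(0, round(
      stats::rnorm(n, config$scim_pre_mean, config$scim_pre_sd))))
    improv <- config$improvement_mean +
      stats::rnorm(n, 0, config$coupling_sd)
    for (m in names(config$coupling)) {
      improv <- improv +
        config$coupling[[m]] * log10(conc[, m, "t1"] / base[[m]])
    }
    post <- pmin(100, pmax(0, round(pre + improv)))
    clinical <- data.frame(
      subject = subjects,
      sci_type = sample(c("complete", "incomplete"), n, replace = TRUE),
      asia = sample(LETTERS[1:4], n, replace = TRUE),
      age = pmin(90, pmax(18, round(stats::rnorm(n, 55, 20)))),
      scim_pre = pre, scim_post = post,
      stringsAsFactors = FALSE
    )
    list(
      spectra = spectra,
      clinical = clinical,
      truth = list(concentrations = conc, planted = config$planted,
                   coupling = config$coupling,
                   coupling_sd = config$coupling_sd,
                   base_levels = base)
    )
  })
}

#' Simulate a paired cohort directly at the bin level
#'
#' Generates a samples-by-bins log10-abundance matrix with the same paired
#' structure as [generate_cohort()] but skipping the spectral layer, so
#' that statistical calibration studies can run at realistic bin counts
#' (e.g. 500 bins) that a 2048-point simulated axis cannot resolve into
#' distinct peaks. Planted bins shift by `effect` log10-units at the
#' second timepoint; an optional clinical score is coupled to the first
#' planted bin's initial level.
#'
#' @param n_subjects subjects (each contributes both timepoints).
#' @param n_bins number of bins.
#' @param planted named numeric: bin index (as character) -> log10 effect.
#' @param subject_sd,noise_sd SDs of the subject random effect and the
#'   per-sample noise (log10 scale).
#' @param coupling SCIM points per log10-unit of the coupled bin's initial
#'   level; named by bin index, `NULL` for no clinical score.
#' @param coupling_sd clinical noise SD (points).
#' @param seed RNG seed.
#' @return List: `x` (2n x bins matrix, log10 abundances), `labels`
#'   (factor t1/t2), `subject`, `clinical` (or NULL), `truth`.
#' @export
simulate_bin_matrix <- function(n_subjects = 6L, n_bins = 500L,
                                planted = c(`1` = 0.3, `2` = 0.3,
                                            `3` = -0.3),
                                subject_sd = 0.15, noise_sd = 0.12,
                                coupling = c(`1` = -25), coupling_sd = 4,
                                seed = 1L) {
  if (n_subjects < 3L) stop("n_subjects must be >= 3")
  if (n_bins < 1L) stop("n_bins must be >= 1")
  pl_idx <- as.integer(names(planted))
  if (any(is.na(pl_idx)) || any(pl_idx < 1L | pl_idx > n_bins)) {
    stop("planted bin indices out of range")
  }
  .with_seed(seed, {
    n <- n_subjects
    subjects <- sprintf("S%02d", seq_len(n))
    eff <- numeric(n_bins)
    eff[pl_idx] <- planted
    u <- matrix(stats::rnorm(n * n_bins, 0, subject_sd), n, n_bins)
    x1 <- u + matrix(stats::rnorm(n * n_bins, 0, noise_sd), n, n_bins)
    x2 <- u + matrix(stats::rnorm(n * n_bins, 0, noise_sd), n, n_bins) +
      matrix(eff, n, n_bins, byrow = TRUE)
    x <- rbind(x1, x2)
    rownames(x) <- c(paste0(subjects, "_t1"), paste0(subjects, "_t2"))
    colnames(x) <- paste0("bin", seq_len(n_bins))
    labels <- factor(rep(c("t1", "t2"), each = n), levels = c("t1", "t2"))
    clinical <- NULL
    if (!is.null(coupling)) {
      cp_idx <- as.integer(names(coupling))
      if (any(is.na(cp_idx)) || any(cp_idx < 1L | cp_idx > n_bins)) {
        stop("coupling bin indices out of range")
      }
      pre <- pmin(100, pmax(0, round(stats::rnorm(n, 65, 12))))
      improv <- 11 + stats::rnorm(n, 0, coupling_sd)
      for (j in seq_along(cp_idx)) {
        improv <- improv + coupling[[j]] * x1[, cp_idx[j]]
      }
      post <- pmin(100, pmax(0, round(pre + improv)))
      clinical <- data.frame(subject = subjects, scim_pre = pre,
                             scim_post = post, stringsAsFactors = FALSE)
    }
    list(x = x, labels = labels, subject = rep(subjects, 2L),
         clinical = clinical,
         truth = list(planted = planted, coupling = coupling))
  })
}

#' Write a simulated cohort to disk as plain-text artifacts
#'
#' One two-column CSV (`ppm`, `intensity`) per spectrum plus a clinical CSV.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in cohort$spectra) {
    utils::write.csv(
      data.frame(ppm = sp$ppm, intensity = sp$intensity),
      file.path(dir, paste0(sp$sample_id, ".csv")), row.names = FALSE)
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read spectra written by [write_cohort()]
#'
#' @param dir directory of per-sample `ppm,intensity` CSVs named
#'   `<subject>_<timepoint>.csv`.
#' @return List of `urometab_spectrum`.
#' @export
read_spectra <- function(dir) {
  files <- sort(list.files(dir, pattern = "_t[0-9]+\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no spectrum CSVs found in ", dir)
  lapply(files, function(f) {
    d <- utils::read.csv(f)
    id <- sub("\\.csv$", "", basename(f))
    tp <- sub("^.*_(t[0-9]+)$", "\\1", id)
    new_spectrum(d$ppm, d$intensity, sample_id = id, timepoint = tp)
  })
}
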