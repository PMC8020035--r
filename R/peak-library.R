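#' Built-in urinary metabolite peak library
#'
#' A peak library maps each metabolite to one or more resonances (chemical
#' shift of the peak centre in ppm, relative intensity, linewidth in ppm)
#' plus a pathway-compound identifier used by the pathway module. The
#' built-in library covers common urinary metabolites observed by 1D 1H NMR
#' at pH 7.4, with approximate literature chemical shifts; it is intended
#' for simulation and for bin-to-compound assignment, not for quantitative
#' metabolite identification.
#'
#' @return A data frame with columns `metabolite`, `ppm_center`,
#'   `rel_intensity`, `linewidth_ppm`, `compound_id` (one row per peak).
#' @export
#' @examples
#' lib <- default_peak_library()
#' head(lib)
default_peak_library <- function() {
  peak <- function(metabolite, compound_id, centers, intensities,
                   linewidth = 0.02) {
    data.frame(
      metabolite = metabolite,
      ppm_center = centers,
      rel_intensity = intensities,
      linewidth_ppm = linewidth,
      compound_id = compound_id,
      stringsAsFactors = FALSE
    )
  }
  lib <- rbind(
    peak("creatinine", "C00791", c(3.05, 4.06), c(1.0, 0.67)),
    peak("citrate", "C00158", c(2.54, 2.66), c(0.5, 0.5)),
    peak("hippurate", "C01586", c(3.97, 7.55, 7.64, 7.84), c(0.4, 0.4, 0.2, 0.4)),
    peak("glycine", "C00037", 3.56, 1.0),
    peak("L-alanine", "C00041", 1.48, 1.0),
    peak("lactate", "C00186", c(1.33, 4.12), c(1.0, 0.33)),
    peak("L-valine", "C00183", c(0.99, 1.04, 3.61), c(0.6, 0.6, 0.2)),
    peak("L-leucine", "C00123", c(0.96, 1.71), c(1.0, 0.3)),
    peak("L-isoleucine", "C00407", 1.01, 0.8),
    peak("taurine", "C00245", c(3.27, 3.43), c(0.8, 0.8)),
    peak("betaine", "C00719", c(3.26, 3.90), c(1.0, 0.3)),
    peak("trimethylamine-N-oxide", "C01104", 3.25, 1.0),
    peak("dimethylamine", "C00543", 2.72, 1.0),
    peak("D-glucose", "C00031", c(5.23, 3.47, 3.72), c(0.3, 0.8, 0.6)),
    peak("formate", "C00058", 8.46, 1.0),
    peak("caffeine", "C07481", c(3.31, 3.49, 7.88), c(0.9, 0.9, 0.3)),
    peak("dopamine", "C03758", c(2.79, 3.21, 6.74, 6.89), c(0.6, 0.6, 0.4, 0.4)),
    peak("hypoxanthine", "C00262", c(8.19, 8.21), c(1.0, 1.0)),
    peak("xanthine", "C00385", 7.94, 1.0),
    peak("inosine", "C00294", c(6.10, 8.35), c(0.5, 0.8)),
    peak("L-tyrosine", "C00082", c(6.90, 7.19), c(0.5, 0.5)),
    peak("3-hydroxymandelate", "C11527", c(6.82, 7.25), c(0.5, 0.5)),
    peak("N-methylhydantoin", "C02565", c(2.92, 4.08), c(1.0, 0.4)),
    peak("2-furoylglycine", "C21593", c(6.62, 7.18, 7.67), c(0.4, 0.3, 0.3)),
    peak("trigonelline", "C01004", c(4.44, 8.08, 9.12), c(0.5, 0.6, 0.3)),
    peak("L-histidine", "C00135", c(7.07, 7.76), c(0.5, 0.3)),
    peak("1-methylnicotinamide", "C02918", c(8.90, 8.97, 9.28), c(0.4, 0.4, 0.3)),
    peak("succinate", "C00042", 2.41, 1.0),
    peak("acetate", "C00033", 1.92, 1.0),
    peak("pyruvate", "C00022", 2.37, 0.8),
    peak("3-hydroxybutyrate", "C01089", c(1.20, 2.31), c(0.8, 0.4)),
    peak("allantoin", "C01551", 5.39, 0.5)
  )
  rownames(lib) <- NULL
  validate_peak_library(lib)
  lib
}

#' Baseline urinary abundance levels for the built-in library
#'
#' Relative (arbitrary-unit) baseline concentrations used by the cohort
#' simulator; roughly ordered like typical urinary abundances (creatinine
#' and hippurate high, trace aromatics low).
#'
#' @param library a peak library data frame.
#' @return Named numeric vector, one entry per metabolite in `library`.
#' @export
default_base_levels <- function(library = default_peak_library()) {
  mets <- unique(library$metabolite)
  base <- rep(1, length(mets))
  names(base) <- mets
  high <- c(creatinine = 6, hippurate = 3, citrate = 2.5, glycine = 2,
            taurine = 1.5, "D-glucose" = 1.5)
  base[names(high)[names(high) %in% mets]] <-
    high[names(high) %in% mets]
  low <- c(dopamine = 0.6, hypoxanthine = 0.8, xanthine = 0.7,
           inosine = 0.7, "3-hydroxymandelate" = 0.5,
           "N-methylhydantoin" = 0.6, "2-furoylglycine" = 0.5)
  base[names(low)[names(low) %in% mets]] <- low[names(low) %in% mets]
  base
}

#' Validate a peak library
#'
#' @param library data frame with columns `metabolite`, `ppm_center`,
#'   `rel_intensity`, `linewidth_ppm`, `compound_id`.
#' @param ppm_range simulated chemical-shift window the centres must fall in.
#' @return The library, invisibly, or an error.
#' @export
validate_peak_library <- function(library, ppm_range = c(0.5, 9.5)) {
  required <- c("metabolite", "ppm_center", "rel_intensity",
                "linewidth_ppm", "compound_id")
  missing <- setdiff(required, names(library))
  if (length(missing)) {
    stop("peak library lacks columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(library) == 0L) stop("peak library is empty")
  if (any(library$ppm_center < ppm_range[1] | library$ppm_center > ppm_range[2])) {
    stop("peak centres must lie within the simulated ppm window [",
         ppm_range[1], ", ", ppm_range[2], "]")
  }
  if (any(library$rel_intensity <= 0)) stop("relative intensities must be > 0")
  if (any(library$linewidth_ppm <= 0)) stop("linewidths must be > 0")
  invisible(library)
}

#' Read / write a peak library as CSV
#'
#' @param path file path.
#' @return `read_peak_library` returns a validated library data frame.
#' @export
read_peak_library <- function(path) {
  validate_peak_library(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_peak_library
#' @param library a peak library data frame.
#' @export
write_peak_library <- function(library, path) {
  validate_peak_library(library)
  utils::write.csv(library, path, row.names = FALSE)
  invisible(path)
}
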