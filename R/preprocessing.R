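# Preprocessing in the fixed order: total-metabolome normalization
# (excluding water/urea regions and noise bins), log10 transform with a
# half-minimum offset, then pareto scaling.

#' Default excluded chemical-shift regions
#'
#' Residual water and urea resonances are excluded from the total-
#' metabolome normalization; defaults are 4.5-5.0 ppm (water) and
#' 5.5-6.0 ppm (urea), both configurable.
#'
#' @return List of 2-vectors (ppm intervals).
#' @export
default_excluded_regions <- function() {
  list(water = c(4.5, 5.0), urea = c(5.5, 6.0))
}

#' Bins overlapping a set of excluded ppm regions
#'
#' @param bins bin data frame (from [adaptive_bin()]).
#' @param regions list of ppm intervals.
#' @return Integer vector of bin numbers overlapping any region.
#' @export
exclusion_bins <- function(bins, regions = default_excluded_regions()) {
  hit <- rep(FALSE, nrow(bins))
  for (r in regions) {
    hit <- hit | (bins$ppm_lo < max(r) & bins$ppm_hi > min(r))
  }
  bins$bin[hit]
}

#' Total-metabolome normalization
#'
#' Drops excluded bins (noise bins plus any explicitly excluded, e.g.
#' water/urea regions) and divides each sample's retained-bin vector by
#' its sum, so every row sums to one. Within-sample ratios of retained
#' bins are preserved.
#'
#' @param table a `bin_table` or a plain samples-by-bins matrix.
#' @param excluded bin numbers (for a `bin_table`) or column indices
#'   (for a matrix) to drop before normalizing. For a `bin_table`,
#'   non-signal (noise) bins are always dropped as well.
#' @return Same type as the input, restricted to retained bins, rows
#'   summing to 1; attribute `"excluded"` records what was dropped.
#' @export
normalize_total <- function(table, excluded = integer()) {
  if (inherits(table, "bin_table")) {
    drop <- union(table$bins$bin[!table$bins$signal], excluded)
    keep <- setdiff(table$bins$bin, drop)
    keep_col <- match(keep, table$bins$bin)
    vals <- table$values[, keep_col, drop = FALSE]
    tot <- rowSums(vals)
    bad <- which(tot <= 0)
    if (length(bad)) {
      stop("zero retained total for sample(s): ",
           paste(rownames(vals)[bad], collapse = ", "))
    }
    out <- table
    out$values <- vals / tot
    out$bins <- table$bins[keep_col, , drop = FALSE]
    attr(out, "excluded") <- drop
    out
  } else {
    x <- as.matrix(table)
    keep <- setdiff(seq_len(ncol(x)), excluded)
    vals <- x[, keep, drop = FALSE]
    tot <- rowSums(vals)
    bad <- which(tot <= 0)
    if (length(bad)) {
      nm <- rownames(x)
      if (is.null(nm)) nm <- as.character(seq_len(nrow(x)))
      stop("zero retained total for sample(s): ",
           paste(nm[bad], collapse = ", "))
    }
    out <- vals / tot
    attr(out, "excluded") <- excluded
    out
  }
}

#' Zero-safe log10 transform
#'
#' x -> log10(x + eps) with eps equal to half the smallest positive value
#' in the matrix, making the transform monotone and defined at zero.
#'
#' @param table a `bin_table` or matrix of non-negative values.
#' @param eps offset; computed from the data when `NULL`.
#' @return Same type as input; attribute `"eps"` records the offset.
#' @export
log_transform <- function(table, eps = NULL) {
  x <- if (inherits(table, "bin_table")) table$values else as.matrix(table)
  if (any(x < 0)) stop("log transform requires non-negative values")
  if (is.null(eps)) {
    pos <- x[x > 0]
    if (!length(pos)) {
      eps <- 1e-12
    } else {
      eps <- min(pos) / 2
    }
  }
  y <- log10(x + eps)
  if (inherits(table, "bin_table")) {
    out <- table
    out$values <- y
    attr(out, "eps") <- eps
    out
  } else {
    attr(y, "eps") <- eps
    y
  }
}

#' Pareto scaling
#'
#' Per column: subtract the mean and divide by the square root of the
#' sample (n-1) standard deviation, damping high-abundance dominance less
#' aggressively than unit-variance scaling. Columns with zero SD are
#' dropped and reported.
#'
#' @param table a `bin_table` or matrix with at least two rows.
#' @return A `processed_matrix`: list with `values`, `center`, `scale_sd`
#'   (the pre-scaling SDs), `dropped` (zero-variance columns), `meta`
#'   (sample metadata when available).
#' @export
pareto_scale <- function(table) {
  x <- if (inherits(table, "bin_table")) table$values else as.matrix(table)
  if (nrow(x) < 2L) stop("pareto scaling requires at least 2 samples")
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  dropped <- colnames(x)[sd == 0]
  if (is.null(dropped)) dropped <- which(sd == 0)
  keep <- sd > 0
  y <- sweep(x[, keep, drop = FALSE], 2L, mu[keep])
  y <- sweep(y, 2L, sqrt(sd[keep]), "/")
  meta <- if (inherits(table, "bin_table")) table$meta else NULL
  bins <- if (inherits(table, "bin_table")) {
    table$bins[keep, , drop = FALSE]
  } else NULL
  structure(
    list(values = y, center = mu[keep], scale_sd = sd[keep],
         dropped = dropped, meta = meta, bins = bins),
    class = "processed_matrix"
  )
}

#' @export
print.processed_matrix <- function(x, ...) {
  cat("<processed_matrix>", nrow(x$values), "samples x", ncol(x$values),
      "bins;", length(x$dropped), "zero-variance column(s) dropped\n")
  invisible(x)
}

#' Undo pareto scaling using the recorded means and SDs
#'
#' @param pm a `processed_matrix`.
#' @return The pre-scaling matrix.
#' @export
unscale_pareto <- function(pm) {
  stopifnot(inherits(pm, "processed_matrix"))
  sweep(sweep(pm$values, 2L, sqrt(pm$scale_sd), "*"), 2L, pm$center, "+")
}

#' Run the full preprocessing chain on a bin table
#'
#' normalize (dropping noise bins and excluded regions) -> log10 ->
#' pareto, in that fixed order.
#'
#' @param table a `bin_table`.
#' @param excluded_regions ppm intervals excluded from normalization.
#' @return A `processed_matrix`; attributes `"normalized"` and
#'   `"logged"` keep the intermediate matrices for modules that need
#'   unscaled normalized concentrations.
#' @export
preprocess <- function(table, excluded_regions = default_excluded_regions()) {
  stopifnot(inherits(table, "bin_table"))
  excl <- exclusion_bins(table$bins, excluded_regions)
  nt <- normalize_total(table, excl)
  lt <- log_transform(nt)
  pm <- pareto_scale(lt)
  attr(pm, "normalized") <- nt
  attr(pm, "logged") <- lt
  pm
}
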