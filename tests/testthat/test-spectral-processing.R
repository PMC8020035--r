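make_peak_spectrum <- function(centres, heights = rep(1, length(centres)),
                               gamma = 0.06, n = 512, range = c(0, 5)) {
  ppm <- default_ppm_axis(n, range)
  x <- rep(0, n)
  for (i in seq_along(centres)) {
    x <- x + heights[i] * (gamma / 2)^2 /
      ((ppm - centres[i])^2 + (gamma / 2)^2)
  }
  new_spectrum(ppm, x)
}

test_that("alignment is the identity on self and recovers point shifts", {
  ref <- make_peak_spectrum(2.5)
  self <- align_to_reference(ref, ref)
  expect_equal(self$intensity, ref$intensity, tolerance = 1e-12)
  expect_true(all(attr(self, "segments")$shift == 0))

  # displace by +5 points; exhaustive search over all shifts is the oracle
  step <- diff(ref$ppm)[1]
  shifted <- new_spectrum(ref$ppm, c(rep(0, 5),
                                     ref$intensity[1:(512 - 5)]))
  oracle_best <- which.max(vapply(-10:10, function(s) {
    xs <- if (s > 0) c(rep(0, s), shifted$intensity[1:(512 - s)]) else
      if (s < 0) c(shifted$intensity[(1 - s):512], rep(0, -s)) else
        shifted$intensity
    sum(xs * ref$intensity)
  }, 0))
  expect_identical((-10:10)[oracle_best], -5L)

  al <- align_to_reference(shifted, ref, max_shift = 10 * step,
                           min_segment = 600)
  expect_identical(attr(al, "segments")$shift[1], -5L)
  expect_identical(which.max(al$intensity), which.max(ref$intensity))
})

test_that("displacements beyond the window leave the segment unshifted and flagged", {
  ref <- make_peak_spectrum(2.5, gamma = 0.02)
  step <- diff(ref$ppm)[1]
  far <- new_spectrum(ref$ppm, c(rep(0, 20), ref$intensity[1:(512 - 20)]))
  al <- align_to_reference(far, ref, max_shift = 10 * step,
                           min_segment = 600)
  expect_identical(al$intensity, far$intensity)
  expect_false(attr(al, "segments")$aligned[1])
})

test_that("alignment preserves segment intensity up to padding", {
  set.seed(4)
  ref <- make_peak_spectrum(c(1.5, 3.5), c(1, 0.8))
  jig <- new_spectrum(ref$ppm, c(rep(0, 3), ref$intensity[1:(512 - 3)]) +
                        rnorm(512, 0, 0.001))
  al <- align_to_reference(jig, ref)
  expect_lt(abs(sum(al$intensity) - sum(jig$intensity)) /
              sum(abs(jig$intensity)), 0.01)
  expect_error(align_to_reference(
    new_spectrum(seq(0, 1, length.out = 10), rep(0, 10)), ref),
    "identical ppm axis")
})

test_that("adaptive binning places boundaries at inter-peak minima", {
  ms <- make_peak_spectrum(c(1.5, 3.5), c(1, 0.8))
  b <- adaptive_bin(ms, min_width = 0.05, noise_threshold = 0.01)
  sig <- b[b$signal, ]
  expect_identical(nrow(sig), 2L)
  half <- length(ms$ppm) %/% 2
  apex <- c(which.max(ms$intensity[1:half]),
            half + which.max(ms$intensity[(half + 1):512]))
  expect_true(any(sig$idx_lo <= min(apex) & sig$idx_hi >= min(apex)))
  expect_true(any(sig$idx_lo <= max(apex) & sig$idx_hi >= max(apex)))
  # boundary coincides with the brute-force global minimum between apexes
  sm <- stats::filter(c(rep(ms$intensity[1], 5), ms$intensity,
                        rep(ms$intensity[512], 5)),
                      rep(1 / 11, 11), sides = 2)[6:517]
  inner <- (min(apex) + 1):(max(apex) - 1)
  oracle_boundary <- inner[which.min(sm[inner])]
  expect_identical(sig$idx_hi[1], oracle_boundary)

  # deterministic
  expect_identical(b, adaptive_bin(ms, min_width = 0.05,
                                   noise_threshold = 0.01))
})

test_that("binning handles flat spectra, shallow minima, and bad widths", {
  flat <- new_spectrum(default_ppm_axis(256, c(0, 5)), rep(0, 256))
  expect_identical(sum(adaptive_bin(flat, min_width = 0.05)$signal), 0L)

  # a shallow split narrower than min_width is merged back to one bin
  shallow <- make_peak_spectrum(c(2.50, 2.56), c(1, 0.7))
  b <- adaptive_bin(shallow, min_width = 0.2, noise_threshold = 0.01)
  expect_identical(sum(b$signal), 1L)

  expect_error(adaptive_bin(shallow, min_width = 10), "exceeds")
})

test_that("bin boundaries match brute-force minima for three isolated peaks", {
  ms <- make_peak_spectrum(c(1.0, 2.5, 4.0), c(1, 0.9, 0.8))
  b <- adaptive_bin(ms, min_width = 0.05, noise_threshold = 0.01)
  sig <- b[b$signal, ]
  expect_identical(nrow(sig), 3L)
  sm <- stats::filter(c(rep(ms$intensity[1], 5), ms$intensity,
                        rep(ms$intensity[512], 5)),
                      rep(1 / 11, 11), sides = 2)[6:517]
  apex <- vapply(c(1.0, 2.5, 4.0), function(c0) {
    which.min(abs(ms$ppm - c0))
  }, 0L)
  for (i in 1:2) {
    inner <- (apex[i] + 1):(apex[i + 1] - 1)
    expect_identical(sig$idx_hi[i], inner[which.min(sm[inner])])
  }
})

test_that("integration is exact on rectangles and additive under splits", {
  ppm <- default_ppm_axis(1001, c(0, 10))
  const <- new_spectrum(ppm, rep(1, 1001))
  bins <- data.frame(bin = 1L, ppm_lo = 2, ppm_hi = 3,
                     idx_lo = which.min(abs(ppm - 2)),
                     idx_hi = which.min(abs(ppm - 3)), signal = TRUE)
  bt <- integrate_bins(list(const), bins)
  expect_equal(unname(bt$values[1, 1]), 1, tolerance = 1e-12)

  set.seed(1)
  wavy <- new_spectrum(ppm, runif(1001))
  split_at <- which.min(abs(ppm - 2.4))
  bins2 <- data.frame(bin = 1:2, ppm_lo = c(2, ppm[split_at]),
                      ppm_hi = c(ppm[split_at], 3),
                      idx_lo = c(bins$idx_lo, split_at),
                      idx_hi = c(split_at, bins$idx_hi),
                      signal = TRUE)
  whole <- integrate_bins(list(wavy), bins)$values[1, 1]
  parts <- integrate_bins(list(wavy), bins2)$values[1, ]
  expect_equal(sum(parts), whole, tolerance = 1e-12)

  zero <- new_spectrum(ppm, rep(0, 1001))
  expect_true(all(integrate_bins(list(zero), bins2)$values == 0))
  bad <- bins; bad$ppm_hi <- 99
  expect_error(integrate_bins(list(const), bad), "outside")
})

test_that("manual bin edits are deterministic and validated", {
  ms <- make_peak_spectrum(c(1.0, 2.5, 4.0))
  b <- adaptive_bin(ms, min_width = 0.05, noise_threshold = 0.01)
  expect_identical(apply_manual_edits(b, list()), {
    b2 <- b; b2$bin <- seq_len(nrow(b2)); rownames(b2) <- NULL; b2
  })
  merged <- apply_manual_edits(b, list(list(op = "merge", bins = c(1, 2))))
  expect_identical(nrow(merged), nrow(b) - 1L)
  expect_identical(merged$ppm_lo[1], b$ppm_lo[1])
  expect_identical(merged$ppm_hi[1], b$ppm_hi[2])

  excluded <- apply_manual_edits(b, list(list(op = "exclude", bin = 2)))
  expect_false(excluded$signal[2])
  expect_identical(excluded[, c("ppm_lo", "ppm_hi")],
                   b[, c("ppm_lo", "ppm_hi")])

  sp <- apply_manual_edits(b, list(list(op = "split", bin = 2, at = 2.0)),
                           ppm = ms$ppm)
  expect_identical(nrow(sp), nrow(b) + 1L)
  expect_error(apply_manual_edits(b, list(list(op = "merge",
                                               bins = c(1, 3)))),
               "adjacent")
  expect_error(apply_manual_edits(b, list(list(op = "exclude", bin = 99))),
               "non-existent")
})

test_that("planted bin integrals track true concentrations under jitter", {
  # pooled over replicate cohorts at jitter SD 0.01 ppm; 25 cohorts give
  # 300 paired points, plenty to resolve a 0.95 correlation floor
  areas <- NULL; truth <- NULL
  for (r in 1:25) {
    cfg <- cohort_config(jitter_sd = 0.01, seed = 2000 + r)
    ch <- generate_cohort(cfg)
    ppm <- ch$spectra[[1]]$ppm
    win <- ppm >= 8.10 & ppm <= 8.31
    areas <- c(areas, vapply(ch$spectra,
                             function(sp) sum(sp$intensity[win]), 0))
    truth <- c(truth, c(ch$truth$concentrations[, "hypoxanthine", "t1"],
                        ch$truth$concentrations[, "hypoxanthine", "t2"]))
  }
  expect_gte(cor(areas, truth), 0.95)
})
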