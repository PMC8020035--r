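test_that("spectrum generation obeys the mixture model contracts", {
  lib <- default_peak_library()
  ppm <- default_ppm_axis(512)
  zero <- generate_spectrum(c(creatinine = 0, glycine = 0), lib,
                            jitter_sd = 0, noise_sd = 0, ppm = ppm)
  expect_true(all(zero$intensity == 0))

  one <- generate_spectrum(c(glycine = 1), lib, jitter_sd = 0,
                           noise_sd = 0, ppm = ppm)
  expect_equal(one$ppm[which.max(one$intensity)], 3.56,
               tolerance = diff(ppm)[1])

  two <- generate_spectrum(c(glycine = 2), lib, jitter_sd = 0,
                           noise_sd = 0, ppm = ppm)
  expect_equal(two$intensity, 2 * one$intensity, tolerance = 1e-12)

  expect_error(generate_spectrum(c(glycine = -1), lib),
               "non-negative")
  expect_error(generate_spectrum(c(glycine = 1), lib[0, ]), "empty")
  expect_error(generate_spectrum(c(nosuch = 1), lib), "absent")

  a <- generate_spectrum(c(glycine = 1), lib, jitter_sd = 0.01,
                         noise_sd = 0.1, ppm = ppm, seed = 7)
  b <- generate_spectrum(c(glycine = 1), lib, jitter_sd = 0.01,
                         noise_sd = 0.1, ppm = ppm, seed = 7)
  expect_identical(a$intensity, b$intensity)
})

test_that("null cohort yields identical paired spectra within subject", {
  cfg <- cohort_config(n_subjects = 3, planted = c(hypoxanthine = 0),
                       subject_sd = 0.2, sample_sd = 0, jitter_sd = 0,
                       noise_sd = 0, coupling_sd = 0, seed = 5)
  ch <- generate_cohort(cfg)
  for (s in 1:3) {
    expect_equal(ch$spectra[[s]]$intensity, ch$spectra[[s + 3]]$intensity,
                 tolerance = 1e-12)
  }
})

test_that("planted log-fold effect scales the integrated peak area", {
  cfg <- cohort_config(n_subjects = 3, planted = c(formate = 1),
                       subject_sd = 0.1, sample_sd = 0, jitter_sd = 0,
                       noise_sd = 0, seed = 2)
  ch <- generate_cohort(cfg)
  ppm <- ch$spectra[[1]]$ppm
  win <- ppm >= 8.42 & ppm <= 8.50 # isolated formate singlet at 8.46
  area <- vapply(ch$spectra, function(sp) sum(sp$intensity[win]), 0)
  for (s in 1:3) {
    # tolerance covers Lorentzian tail leakage from unplanted neighbours
    expect_equal(area[s + 3] / area[s], exp(1), tolerance = 0.05)
  }
})

test_that("cohort generation is reproducible and clinically sane", {
  a <- generate_cohort(cohort_config(seed = 11))
  b <- generate_cohort(cohort_config(seed = 11))
  expect_identical(a$clinical, b$clinical)
  expect_equal(a$spectra[[5]]$intensity, b$spectra[[5]]$intensity,
               tolerance = 1e-12)

  expect_true(all(a$clinical$scim_pre >= 0 & a$clinical$scim_pre <= 100))
  expect_true(all(a$clinical$scim_post >= 0 & a$clinical$scim_post <= 100))
  ids <- vapply(a$spectra, function(s) s$sample_id, "")
  subj <- sub("_t[0-9]$", "", ids)
  expect_true(all(table(subj) == 2)) # complete pairs

  expect_error(generate_cohort(cohort_config(coupling = c(unobtainium = 1))),
               "unknown")
  expect_error(cohort_config(n_subjects = 2), ">= 3")
  expect_error(cohort_config(noise_sd = -1), "SD")
})

test_that("empirical between-timepoint log-ratio matches the configured effect", {
  # Monte-Carlo average of the planted hypoxanthine bin's log area ratio
  # over replicate cohorts; 60 replicates keep the check under a few
  # seconds while the SE (~0.02) comfortably resolves the +/-10% band.
  cfg0 <- cohort_config()
  ratios <- vapply(1:60, function(r) {
    cfg <- cohort_config(seed = 1000 + r)
    ch <- generate_cohort(cfg)
    ppm <- ch$spectra[[1]]$ppm
    win <- ppm >= 8.12 & ppm <= 8.30 # hypoxanthine doublet
    area <- vapply(ch$spectra, function(sp) sum(sp$intensity[win]), 0)
    n <- cfg$n_subjects
    mean(log(area[(n + 1):(2 * n)] / area[1:n]))
  }, 0)
  expect_equal(mean(ratios), cfg0$planted[["hypoxanthine"]],
               tolerance = 0.1)
})

test_that("bin-level cohort simulator plants effects and couples scores", {
  sim <- simulate_bin_matrix(n_subjects = 50, n_bins = 20,
                             planted = c(`4` = 0.3, `5` = -0.3),
                             seed = 3)
  d <- colMeans(sim$x[sim$labels == "t2", ]) -
    colMeans(sim$x[sim$labels == "t1", ])
  expect_equal(unname(d[4]), 0.3, tolerance = 0.12)
  expect_equal(unname(d[5]), -0.3, tolerance = 0.12)
  expect_lt(max(abs(d[-(4:5)])), 0.15)
  expect_true(all(sim$clinical$scim_post >= 0 &
                    sim$clinical$scim_post <= 100))

  again <- simulate_bin_matrix(n_subjects = 50, n_bins = 20,
                               planted = c(`4` = 0.3, `5` = -0.3),
                               seed = 3)
  expect_identical(sim$x, again$x)
  expect_error(simulate_bin_matrix(planted = c(`999` = 1)),
               "out of range")
})

test_that("cohorts round-trip through the CSV artifacts", {
  dir <- withr::local_tempdir()
  ch <- generate_cohort(cohort_config(n_subjects = 3, seed = 9))
  write_cohort(ch, dir)
  back <- read_spectra(dir)
  expect_length(back, 6)
  orig <- ch$spectra[order(vapply(ch$spectra, `[[`, "", "sample_id"))]
  expect_equal(back[[1]]$intensity, orig[[1]]$intensity,
               tolerance = 1e-12)
  expect_identical(back[[1]]$sample_id, orig[[1]]$sample_id)
})
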