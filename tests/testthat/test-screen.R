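test_that("a planted precursor/fragment pair is recovered as a putative adduct", {
  panel <- planted_panel(529.2973, rt = 10.6, abundance = 5000,
                        fragmentation_efficiency = 0.6)
  sim <- simulate_run(panel, high_scheme(), seed = 5, gradient_length = 15,
                      jitter_ppm = 0, noise_peaks = 0)
  pa <- screen_run(sim$run, scr = screen_params(scan_lo = 350, scan_hi = 600))
  expect_equal(nrow(pa), 1)
  expect_equal(pa$precursor_mz, 529.2973, tolerance = 1e-4)
  # the planted fragment is precursor - 116.04734 (exact monoisotopic),
  # giving an observed loss within 5 ppm of the 116.0473 screening mass
  expect_equal(pa$observed_loss, DEOXYRIBOSE_LOSS, tolerance = 1e-4)
  expect_lte(abs(pa$loss_ppm_error), 5)
  expect_equal(pa$rt, 10.6, tolerance = 0.02)
  expect_equal(pa$mass_class, "high")
})

test_that("no fragment means no pair, and runs without MS2 error out", {
  # precursor only: fragmentation efficiency effectively zero is not
  # allowed, so plant the precursor outside any fragment by simulating and
  # then stripping the MS2 signal
  panel <- planted_panel(529.2973, 10.6, 5000, 0.5)
  sim <- simulate_run(panel, high_scheme(), seed = 6, gradient_length = 15,
                      noise_peaks = 0)
  stripped <- sim$run
  stripped$spectra <- lapply(stripped$spectra, function(s) {
    if (s$ms_level == 2) { s$mz <- numeric(); s$intensity <- numeric() }
    s
  })
  expect_equal(nrow(screen_run(stripped,
                               scr = screen_params(scan_lo = 350,
                                                   scan_hi = 600))), 0)
  ms1only <- stripped
  ms1only$spectra <- Filter(function(s) s$ms_level == 1, ms1only$spectra)
  expect_error(screen_run(ms1only), "no DIA spectra")
})

test_that("every emitted pair satisfies the precursor-referenced loss criterion", {
  sim <- simulate_run(demo_panel(), high_scheme(), seed = 7,
                      gradient_length = 15)
  pa <- screen_run(sim$run, scr = screen_params(scan_lo = 350, scan_hi = 600))
  expect_gte(nrow(pa), 3)
  lhs <- abs(pa$precursor_mz - pa$fragment_mz - 116.0473) /
    pa$precursor_mz * 1e6
  expect_true(all(lhs <= 5))
})

test_that("screening is invariant to spectrum ordering within the run", {
  sim <- simulate_run(demo_panel(), high_scheme(), seed = 8,
                      gradient_length = 12)
  pa1 <- screen_run(sim$run, scr = screen_params(scan_lo = 350,
                                                 scan_hi = 600))
  shuffled <- sim$run
  set.seed(1)
  # permute the spectrum list, then restore RT order: the run invariant
  # requires RT-sorted spectra, and screening must not depend on how the
  # sorted list was assembled
  tmp <- sim$run$spectra[sample(length(sim$run$spectra))]
  shuffled$spectra <- tmp[order(vapply(tmp, `[[`, numeric(1), "rt"))]
  pa2 <- screen_run(shuffled, scr = screen_params(scan_lo = 350,
                                                  scan_hi = 600))
  expect_equal(pa1, pa2)
})

test_that("master-list merging groups within tolerance and is idempotent", {
  a <- data.frame(sample_id = "s1", precursor_mz = 529.2973, rt = 10.6,
                  mass_class = "high")
  b <- data.frame(sample_id = "s2", precursor_mz = 529.2975, rt = 10.62,
                  mass_class = "high")
  m <- build_master_list(a, b)
  expect_equal(nrow(m), 1)
  expect_equal(m$n_samples_detected, 2L)
  expect_equal(m$mz, median(c(529.2973, 529.2975)))
  expect_equal(m$adduct_id, "H1")
  # 20 ppm apart -> two entries
  c2 <- data.frame(sample_id = "s1", precursor_mz = c(500.000, 500.010),
                   rt = c(5, 5), mass_class = "high")
  expect_equal(nrow(build_master_list(c2)), 2)
  # idempotence: merging a master list with itself reproduces it
  m2 <- build_master_list(m, m)
  expect_equal(m2$mz, m$mz)
  expect_equal(m2$rt, m$rt)
  expect_equal(nrow(m2), nrow(m))
  # ids ordered by ascending m/z within class, L before H naming
  d <- data.frame(sample_id = "s1", precursor_mz = c(300.1, 210.05),
                  rt = c(3, 2), mass_class = "low")
  ml <- build_master_list(d)
  expect_equal(ml$adduct_id, c("L1", "L2"))
  expect_equal(ml$mz, c(210.05, 300.1))
  expect_equal(nrow(build_master_list(list())), 0)
})

test_that("per-sample lists from the simulator merge to the planted panel size", {
  panel <- demo_panel()
  per_sample <- lapply(1:4, function(i) {
    sim <- simulate_run(panel, high_scheme(), seed = 100 + i,
                        gradient_length = 13)
    screen_run(sim$run, scr = screen_params(scan_lo = 350, scan_hi = 600),
               sample_id = paste0("s", i))
  })
  m <- build_master_list(per_sample)
  expect_equal(nrow(m), nrow(panel))
  expect_equal(sort(m$n_samples_detected), rep(4L, 3))
})
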