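test_that("targeted integration confirms planted peaks and rejects mismatches", {
  panel <- demo_panel()
  sim <- simulate_run(panel, high_scheme(), seed = 31, gradient_length = 13)
  master <- data.frame(adduct_id = c("H1", "H2", "H3"),
                       mz = panel$precursor_mz, rt = panel$rt)
  res <- integrate_targets(sim$run, master)
  expect_true(all(res$detected))
  expect_equal(res$area, panel$abundance, tolerance = 0.05)
  # entry with no signal -> not detected, area 0
  ghost <- data.frame(adduct_id = "H9", mz = 555.5, rt = 6)
  g <- integrate_targets(sim$run, ghost)
  expect_false(g$detected)
  expect_equal(g$area, 0)
  # peak 6 ppm off the master m/z is outside a 5 ppm tolerance
  # (jitter-free run so the planted centroids sit exactly at their m/z)
  clean <- simulate_run(panel, high_scheme(), seed = 32,
                        gradient_length = 13, jitter_ppm = 1e-9,
                        noise_peaks = 0)
  off <- data.frame(adduct_id = "H1", mz = panel$precursor_mz[1] *
                      (1 + 6e-6), rt = panel$rt[1])
  expect_false(integrate_targets(clean$run, off)$detected)
  # comparable-RT requirement: same m/z, wrong retention time
  wrong_rt <- data.frame(adduct_id = "H1", mz = panel$precursor_mz[1],
                         rt = panel$rt[1] + 1)
  expect_false(integrate_targets(sim$run, wrong_rt)$detected)
})

test_that("dG normalisation follows area * 100 / dG and validates inputs", {
  raw <- matrix(c(50, 0, 30, 10), 2, 2,
                dimnames = list(c("a", "b"), c("x", "y")))
  norm <- normalize_to_dg(raw, c(a = 1000, b = 100))
  expect_equal(norm["a", "x"], 5.0)
  expect_equal(norm["b", "x"], 0)
  expect_equal(norm["b", "y"], 10.0)
  expect_error(normalize_to_dg(raw, c(a = 1000, b = 0)), "b")
  # scale invariance under a common instrument-response factor
  norm2 <- normalize_to_dg(raw * 3.7, c(a = 1000, b = 100) * 3.7)
  expect_equal(norm2, norm)
})

test_that("replicate RSD filter applies the strict 20% rule per animal", {
  m <- cbind(
    flat = c(5, 5, 5, 8, 8, 8),
    spread = c(1, 2, 3, 1, 2, 3),
    boundary = c(10, 10, 10, 8, 10, 12)
  )
  rownames(m) <- paste0("s", 1:6)
  animal <- rep(c("A", "B"), each = 3)
  kept <- rsd_filter(m, animal)
  rsd <- attr(kept, "rsd")
  expect_true("flat" %in% kept)             # RSD 0
  expect_false("spread" %in% kept)          # sd 1, mean 2 -> 50%
  expect_equal(unname(rsd["spread"]), 50)
  # RSD exactly 20.0%: "below 20%" is strict -> excluded
  expect_equal(unname(rsd["boundary"]), 20)
  expect_false("boundary" %in% kept)
  # zero-mean adduct excluded with a message
  m0 <- cbind(m, dead = c(0, 0, 0, 1, 1, 1))
  expect_message(k0 <- rsd_filter(m0, animal), "zero replicate mean")
  expect_false("dead" %in% k0)
})

test_that("RSD filter is invariant to replicate relabeling and scaling", {
  set.seed(7)
  m <- matrix(rlnorm(18, 1, 0.1), 6, 3,
              dimnames = list(paste0("s", 1:6), c("a", "b", "c")))
  animal <- rep(c("A", "B"), each = 3)
  k1 <- rsd_filter(m, animal)
  # relabel animals and permute rows consistently
  perm <- c(4, 5, 6, 1, 2, 3)
  k2 <- rsd_filter(m[perm, ], animal[perm])
  expect_equal(sort(as.character(k1)), sort(as.character(k2)))
  # multiplying one adduct's areas by a constant leaves its RSD unchanged
  m3 <- m; m3[, "b"] <- m3[, "b"] * 123
  k3 <- rsd_filter(m3, animal)
  expect_equal(attr(k3, "rsd")["b"], attr(k1, "rsd")["b"])
})

test_that("recovered normalised ratios round-trip through the simulator", {
  panel <- demo_panel()
  # plant a dG-like reference peak alongside the adducts
  dg_mz <- monoisotopic_mass("C10H13N5O4", "protonated")
  full <- rbind(panel,
                planted_panel(360.5, rt = 3, abundance = 50000,
                              fragmentation_efficiency = 0.5))
  sim <- simulate_run(full, high_scheme(), seed = 41, gradient_length = 13)
  master <- data.frame(adduct_id = c("H1", "H2", "H3"),
                       mz = panel$precursor_mz, rt = panel$rt)
  res <- integrate_targets(sim$run, master)
  dg <- integrate_targets(sim$run, data.frame(adduct_id = "dG", mz = 360.5,
                                              rt = 3))
  norm <- normalize_to_dg(matrix(res$area, 1,
                                 dimnames = list("s1", res$adduct_id)),
                          c(s1 = dg$area))
  truth <- panel$abundance * 100 / 50000
  expect_equal(unname(norm["s1", ]), truth, tolerance = 0.05)
})
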