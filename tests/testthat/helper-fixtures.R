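# Shared fixtures: tiny chromatograms and runs built in code.

# Gaussian chromatogram on a regular grid; area of the analytic peak = A.
gauss_chrom <- function(A = 1000, rt0 = 5, sigma = 0.05, noise_sd = 0,
                        lo = 0, hi = 10, dt = 1 / 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rt <- seq(lo, hi, by = dt)
  y <- A / (sigma * sqrt(2 * pi)) * exp(-(rt - rt0)^2 / (2 * sigma^2))
  if (noise_sd > 0) y <- pmax(y + rnorm(length(rt), 0, noise_sd), 0)
  structure(list(rt = rt, intensity = y, mz_obs = rep(NA_real_, length(rt)),
                 target_mz = 500, ppm_tol = 5), class = "chromatogram")
}

# A hand-built run: one MS1 + one MS2 spectrum per time point.
tiny_run <- function(ms1_peaks, ms2_peaks = NULL, scheme = NULL,
                     rts = 1) {
  if (is.null(scheme)) scheme <- build_dia_scheme(195, 355, 10)
  spectra <- list()
  for (t in rts) {
    spectra[[length(spectra) + 1]] <- list(
      ms_level = 1, rt = t, mz = ms1_peaks[, 1], intensity = ms1_peaks[, 2])
    if (!is.null(ms2_peaks)) {
      spectra[[length(spectra) + 1]] <- list(
        ms_level = 2, rt = t + 1e-3, mz = ms2_peaks[, 1],
        intensity = ms2_peaks[, 2],
        isolation_center = scheme$centers[1],
        isolation_width = scheme$window_width)
    }
  }
  ms_run(spectra, scheme, validate = FALSE)
}

# Default panel used in several simulator tests: three high-mass adducts.
demo_panel <- function() {
  planted_panel(precursor_mz = c(406.2178, 466.2640, 529.2973),
                rt = c(5, 8, 11), abundance = c(3000, 8000, 5000),
                fragmentation_efficiency = 0.5)
}

high_scheme <- function() build_dia_scheme(347, 607, 10)
low_scheme <- function() build_dia_scheme(195, 355, 10)

# Same adducts on a short gradient, for fast write/read fixtures.
short_panel <- function() {
  planted_panel(precursor_mz = c(406.2178, 466.2640, 529.2973),
                rt = c(0.8, 1.5, 2.2), abundance = c(3000, 8000, 5000),
                fragmentation_efficiency = 0.5)
}

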