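#' Chromatographic peak-detection parameters
#'
#' Defaults are the screening settings used for deoxyribonucleoside adduct
#' detection: Gaussian smoothing sigma 0.075 min, noise-estimation window
#' 8.0 min, zero-area filter widths 0.085 and 0.165 min, minimum S/N 5.
#' All widths are in minutes of retention time.
#'
#' @param gauss_sigma Gaussian smoothing kernel sigma, minutes.
#' @param noise_window width of the sliding noise-estimation window, minutes.
#' @param zaf1_width,zaf2_width widths (sigma) of the two zero-area
#'   matched filters, minutes.
#' @param snr_min minimum apex signal-to-noise ratio.
#' @return list of class `peak_params`.
#' @export
peak_params <- function(gauss_sigma = 0.075, noise_window = 8.0,
                        zaf1_width = 0.085, zaf2_width = 0.165, snr_min = 5) {
  stopifnot(gauss_sigma > 0, noise_window > 0, zaf1_width > 0,
            zaf2_width > 0, snr_min > 0)
  structure(list(gauss_sigma = gauss_sigma, noise_window = noise_window,
                 zaf1_width = zaf1_width, zaf2_width = zaf2_width,
                 snr_min = snr_min), class = "peak_params")
}

#' Extract an ion chromatogram from a run
#'
#' Per-spectrum summed intensity of all centroids within
#' `target_mz * (1 +/- ppm_tol * 1e-6)`; spectra with no matching centroid
#' contribute zero (gaps are not interpolated). For MS2 extraction the DIA
#' window index selects which isolation window's scans are used, and the
#' ppm tolerance may instead be given as an absolute window via `abs_tol`
#' (used for precursor-referenced fragment tolerances).
#'
#' @param run an [ms_run()] object.
#' @param target_mz m/z to extract.
#' @param ppm_tol tolerance, ppm (ignored when `abs_tol` given).
#' @param ms_level 1 or 2.
#' @param window DIA window index, required for `ms_level = 2`.
#' @param abs_tol optional absolute half-window in m/z.
#' @return object of class `chromatogram`: list with `rt`, `intensity`,
#'   `mz_obs` (intensity-weighted observed m/z per point, NA where zero),
#'   `target_mz`, `ppm_tol`.
#' @export
extract_eic <- function(run, target_mz, ppm_tol = 5, ms_level = 1,
                        window = NULL, abs_tol = NULL) {
  stopifnot(inherits(run, "ms_run"), ppm_tol > 0 || !is.null(abs_tol))
  if (ms_level == 2 && is.null(window))
    stop("MS2 extraction requires a DIA window index")
  tol <- if (is.null(abs_tol)) target_mz * ppm_tol * 1e-6 else abs_tol
  lo <- target_mz - tol; hi <- target_mz + tol
  keep <- vapply(run$spectra, function(s) {
    if (s$ms_level != ms_level) return(FALSE)
    if (ms_level == 2)
      return(isTRUE(abs(s$isolation_center -
                          run$dia_scheme$centers[window]) < 1e-6))
    TRUE
  }, logical(1))
  sel <- run$spectra[keep]
  rt <- vapply(sel, `[[`, numeric(1), "rt")
  vals <- vapply(sel, function(s) {
    i <- which(s$mz >= lo & s$mz <= hi)
    if (!length(i)) return(c(0, NA_real_))
    w <- s$intensity[i]
    c(sum(w), if (sum(w) > 0) sum(s$mz[i] * w) / sum(w) else NA_real_)
  }, numeric(2))
  structure(list(rt = rt,
                 intensity = if (length(sel)) vals[1, ] else numeric(),
                 mz_obs = if (length(sel)) vals[2, ] else numeric(),
                 target_mz = target_mz, ppm_tol = ppm_tol),
            class = "chromatogram")
}

# Discrete Gaussian smoothing kernel (unit sum).
.gauss_kernel <- function(sigma_pts) {
  h <- max(1L, ceiling(4 * sigma_pts))
  x <- (-h):h
  k <- exp(-x^2 / (2 * sigma_pts^2))
  k / sum(k)
}

# Zero-area matched filter: Mexican hat (negated second derivative of a
# Gaussian), mean-subtracted so the coefficients sum to zero exactly.
.zaf_kernel <- function(sigma_pts) {
  h <- max(2L, ceiling(5 * sigma_pts))
  x <- (-h):h
  k <- (1 - (x / sigma_pts)^2) * exp(-x^2 / (2 * sigma_pts^2))
  k - mean(k)
}

# Symmetric convolution with zero padding, output same length as x.
.conv_same <- function(x, k) {
  h <- (length(k) - 1L) %/% 2L
  xp <- c(numeric(h), x, numeric(h))
  out <- stats::filter(xp, k, method = "convolution", sides = 2)
  as.numeric(out[(h + 1L):(h + length(x))])
}

#' Detect chromatographic peaks
#'
#' The detector (i) smooths the trace with a Gaussian kernel, (ii) requires
#' a positive response from two zero-area matched filters of different
#' widths at each candidate apex (a local maximum of the smoothed trace),
#' (iii) estimates the local baseline (median) and noise (1.4826 x median
#' absolute deviation) of the smoothed trace in a sliding window of
#' `noise_window` minutes that excludes the candidate peak region, and
#' (iv) keeps candidates with (apex - baseline)/noise >= `snr_min`. The
#' peak core is delimited by the zero crossings of the narrow filter's
#' response around the apex (about +/- 2 sigma for a Gaussian peak); the
#' integration region doubles the core half-width on each side so the
#' tails are not clipped, and area is the trapezoidal integral of the raw
#' trace over that region.
#' Candidates closer than the wide filter width are resolved in favour of
#' the higher apex.
#'
#' @param chrom a [extract_eic()] chromatogram (or any list with ascending
#'   `rt` in minutes and `intensity`).
#' @param params a [peak_params()] object.
#' @return data.frame with columns `apex_rt`, `apex_intensity`, `area`,
#'   `snr`, `left_rt`, `right_rt`, `mz_obs` (NA when the chromatogram
#'   carries no observed m/z); zero rows when nothing qualifies or the
#'   trace has fewer than 5 points.
#' @export
detect_peaks <- function(chrom, params = peak_params()) {
  empty <- data.frame(apex_rt = numeric(), apex_intensity = numeric(),
                      area = numeric(), snr = numeric(), left_rt = numeric(),
                      right_rt = numeric(), mz_obs = numeric())
  rt <- chrom$rt; y <- chrom$intensity
  n <- length(rt)
  if (n < 5 || all(y == 0)) return(empty)
  dt <- stats::median(diff(rt))
  sm <- .conv_same(y, .gauss_kernel(params$gauss_sigma / dt))
  r1 <- .conv_same(y, .zaf_kernel(params$zaf1_width / dt))
  r2 <- .conv_same(y, .zaf_kernel(params$zaf2_width / dt))
  i <- 2:(n - 1)
  cand <- i[sm[i] > sm[i - 1] & sm[i] >= sm[i + 1] & r1[i] > 0 & r2[i] > 0 &
              sm[i] > 0]
  if (!length(cand)) return(empty)
  # suppress neighbours within one wide-kernel width, keeping higher apexes
  cand <- cand[order(-sm[cand])]
  keep <- logical(length(cand)); kept_rt <- numeric(0)
  for (ji in seq_along(cand)) {
    j <- cand[ji]
    if (!length(kept_rt) || all(abs(rt[j] - kept_rt) > params$zaf2_width)) {
      keep[ji] <- TRUE; kept_rt <- c(kept_rt, rt[j])
    }
  }
  cand <- sort(cand[keep])
  rows <- lapply(cand, function(j) {
    # peak core: zero crossings of the narrow zero-area response (roughly
    # +/- 2 sigma for a Gaussian peak); the integration region doubles the
    # core half-width on each side so the tails are not clipped
    l0 <- j; while (l0 > 1 && r1[l0 - 1] > 0) l0 <- l0 - 1
    r0 <- j; while (r0 < n && r1[r0 + 1] > 0) r0 <- r0 + 1
    halfw <- max(rt[j] - rt[l0], rt[r0] - rt[j], dt)
    l <- l0; while (l > 1 && rt[j] - rt[l - 1] <= 2 * halfw) l <- l - 1
    r <- r0; while (r < n && rt[r + 1] - rt[j] <= 2 * halfw) r <- r + 1
    # noise and baseline: windowed median/MAD of the smoothed trace with
    # the candidate region excluded; the window is taken in sample indices
    # so detection is exactly shift-equivariant
    half_pts <- max(1L, round(params$noise_window / 2 / dt))
    win <- setdiff(max(1L, j - half_pts):min(n, j + half_pts), l:r)
    if (length(win) < 5) win <- setdiff(seq_len(n), l:r)
    baseline <- if (length(win)) stats::median(sm[win]) else 0
    noise <- if (length(win) >= 2) stats::mad(sm[win], constant = 1.4826)
             else 0
    snr <- if (noise > 0) (sm[j] - baseline) / noise
           else if (sm[j] > baseline) Inf else 0
    if (snr < params$snr_min) return(NULL)
    idx <- l:r
    area <- if (length(idx) > 1)
      sum(diff(rt[idx]) * (y[idx][-1] + y[idx][-length(idx)]) / 2) else 0
    mzo <- NA_real_
    if (!is.null(chrom$mz_obs)) {
      w <- y[idx]; m <- chrom$mz_obs[idx]
      ok <- !is.na(m) & w > 0
      if (any(ok)) mzo <- sum(m[ok] * w[ok]) / sum(w[ok])
    }
    data.frame(apex_rt = rt[j], apex_intensity = y[j], area = area, snr = snr,
               left_rt = rt[l], right_rt = rt[r], mz_obs = mzo)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
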