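#' Construct an in-memory LC-HRMS run
#'
#' A run is an RT-ordered list of spectra plus acquisition metadata. Each
#' spectrum is a list with fields `ms_level` (1 or 2), `rt` (minutes), `mz`
#' (strictly ascending), `intensity` (same length, non-negative) and, for
#' MS2 only, `isolation_center` / `isolation_width` (m/z) which must match a
#' window of the run's DIA scheme.
#'
#' @param spectra list of spectrum lists as described above.
#' @param scheme the [build_dia_scheme()] the MS2 scans were acquired under.
#' @param polarity `"positive"` or `"negative"`.
#' @param ms1_range numeric length-2, the MS1 scan range in m/z.
#' @param validate check all invariants (default TRUE).
#' @return object of class `ms_run`.
#' @export
ms_run <- function(spectra, scheme, polarity = "positive",
                   ms1_range = c(110, 650), validate = TRUE) {
  run <- structure(list(spectra = spectra, polarity = polarity,
                        ms1_range = ms1_range, dia_scheme = scheme),
                   class = "ms_run")
  if (validate) validate_ms_run(run)
  run
}

#' Validate an `ms_run` against its invariants
#'
#' Errors (naming the offending scan) on unsorted RT, non-ascending m/z,
#' length mismatches, or MS2 isolation centers that belong to no window of
#' the scheme.
#'
#' @param run an [ms_run()] object.
#' @return the run, invisibly.
#' @export
validate_ms_run <- function(run) {
  stopifnot(inherits(run, "ms_run"))
  rts <- vapply(run$spectra, `[[`, numeric(1), "rt")
  if (is.unsorted(rts)) stop("spectra are not sorted by retention time")
  for (i in seq_along(run$spectra)) {
    sp <- run$spectra[[i]]
    if (length(sp$mz) != length(sp$intensity))
      stop("scan ", i, ": mz and intensity lengths differ")
    if (length(sp$mz) > 1 && any(diff(sp$mz) <= 0))
      stop("scan ", i, ": m/z array not strictly ascending")
    if (any(sp$intensity < 0)) stop("scan ", i, ": negative intensity")
    if (sp$ms_level == 2) {
      if (is.null(sp$isolation_center))
        stop("scan ", i, ": MS2 scan lacks an isolation center")
      if (is.na(.window_for_center(run$dia_scheme, sp$isolation_center)))
        stop("scan ", i, ": isolation center ", sp$isolation_center,
             " matches no window of the DIA scheme")
    } else if (!is.null(sp$isolation_center)) {
      stop("scan ", i, ": MS1 scan carries isolation fields")
    }
  }
  invisible(run)
}

#' Number of spectra per MS level
#' @param run an [ms_run()] object.
#' @return named integer vector, counts of MS1 and MS2 spectra.
#' @export
ms_level_counts <- function(run) {
  lv <- vapply(run$spectra, `[[`, numeric(1), "ms_level")
  c(ms1 = sum(lv == 1), ms2 = sum(lv == 2))
}

#' @export
print.ms_run <- function(x, ...) {
  n <- ms_level_counts(x)
  rts <- vapply(x$spectra, `[[`, numeric(1), "rt")
  cat(sprintf("LC-HRMS run: %d MS1 + %d MS2 spectra, RT %.2f-%.2f min, %s mode\n",
              n["ms1"], n["ms2"],
              if (length(rts)) min(rts) else NA, if (length(rts)) max(rts) else NA,
              x$polarity))
  print(x$dia_scheme)
  invisible(x)
}

#' Centroid a profile spectrum
#'
#' Local maxima above zero become centroids; the m/z of each centroid is the
#' intensity-weighted mean of the maximum and its two neighbours, the
#' intensity is the local maximum. Deterministic and order-preserving.
#'
#' @param mz,intensity profile arrays (mz ascending).
#' @return list with centroided `mz` and `intensity`.
#' @export
centroid_spectrum <- function(mz, intensity) {
  n <- length(mz)
  if (n < 3) return(list(mz = mz[intensity > 0], intensity = intensity[intensity > 0]))
  i <- 2:(n - 1)
  is_max <- intensity[i] > 0 & intensity[i] >= intensity[i - 1] &
    intensity[i] > intensity[i + 1]
  idx <- i[is_max]
  if (!length(idx)) return(list(mz = numeric(), intensity = numeric()))
  wmz <- vapply(idx, function(j) {
    w <- intensity[(j - 1):(j + 1)]
    sum(mz[(j - 1):(j + 1)] * w) / sum(w)
  }, numeric(1))
  list(mz = wmz, intensity = intensity[idx])
}

#' Read a DIA mzML file into an `ms_run`
#'
#' Uses mzR for parsing. RT is converted to minutes. When `scheme` is not
#' supplied it is inferred from the MS2 isolation centers and offsets
#' (requires a contiguous, equal-width window set). Profile spectra are
#' centroided by [centroid_spectrum()] when `centroid = TRUE`.
#'
#' @param path path to an mzML file.
#' @param scheme optional [build_dia_scheme()]; inferred when `NULL`.
#' @param centroid apply local-maximum centroiding to every spectrum.
#' @return an [ms_run()] object.
#' @export
read_mzml <- function(path, scheme = NULL, centroid = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  fh <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("cannot read mzML '", path, "': ",
                                          conditionMessage(e)))
  on.exit(mzR::close(fh))
  hdr <- mzR::header(fh)
  if (nrow(hdr) == 0) {
    if (is.null(scheme)) scheme <- build_dia_scheme(0, 10, 10)
    return(ms_run(list(), scheme, validate = FALSE))
  }
  pol <- unique(hdr$polarity[hdr$polarity %in% c(0, 1)])
  if (length(pol) > 1) stop("mixed polarity in '", path, "'")
  pks <- mzR::peaks(fh)
  if (nrow(hdr) == 1 && is.matrix(pks)) pks <- list(pks)
  is2 <- hdr$msLevel == 2
  if (is.null(scheme)) {
    if (!any(is2)) stop("cannot infer a DIA scheme: no MS2 spectra in '",
                        path, "'")
    ctr <- sort(unique(round(hdr$isolationWindowTargetMZ[is2], 6)))
    w <- unique(round(hdr$isolationWindowLowerOffset[is2] +
                        hdr$isolationWindowUpperOffset[is2], 6))
    if (length(w) != 1 || any(abs(diff(ctr) - w) > 1e-6))
      stop("MS2 isolation windows in '", path,
           "' are not a contiguous equal-width DIA scheme")
    scheme <- build_dia_scheme(min(ctr) - w / 2, max(ctr) + w / 2, w)
  }
  spectra <- lapply(seq_len(nrow(hdr)), function(i) {
    p <- pks[[i]]
    mzv <- p[, 1]; inten <- p[, 2]
    ord <- order(mzv)
    mzv <- mzv[ord]; inten <- inten[ord]
    if (centroid) {
      cs <- centroid_spectrum(mzv, inten)
      mzv <- cs$mz; inten <- cs$intensity
    }
    sp <- list(ms_level = hdr$msLevel[i], rt = hdr$retentionTime[i] / 60,
               mz = as.numeric(mzv), intensity = as.numeric(inten))
    if (hdr$msLevel[i] == 2) {
      sp$isolation_center <- hdr$isolationWindowTargetMZ[i]
      sp$isolation_width <- hdr$isolationWindowLowerOffset[i] +
        hdr$isolationWindowUpperOffset[i]
    }
    sp
  })
  ms1 <- !is2
  rng <- if (any(ms1) && all(c("scanWindowLowerLimit", "scanWindowUpperLimit")
                             %in% names(hdr)) &&
             !all(is.na(hdr$scanWindowLowerLimit[ms1])))
    c(min(hdr$scanWindowLowerLimit[ms1], na.rm = TRUE),
      max(hdr$scanWindowUpperLimit[ms1], na.rm = TRUE))
  else c(110, 650)
  ms_run(spectra, scheme,
         polarity = if (length(pol) && pol == 0) "negative" else "positive",
         ms1_range = rng)
}

#' Write an `ms_run` to mzML
#'
#' Inverse of [read_mzml()] via mzR's mzML writer; the output is
#' byte-deterministic for a given run.
#'
#' @param run an [ms_run()] object.
#' @param path output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  n <- length(run$spectra)
  if (n == 0) stop("cannot write an empty run")
  lvl <- vapply(run$spectra, `[[`, numeric(1), "ms_level")
  rt <- vapply(run$spectra, `[[`, numeric(1), "rt")
  npk <- vapply(run$spectra, function(s) length(s$mz), integer(1))
  tic <- vapply(run$spectra, function(s) sum(s$intensity), numeric(1))
  iso <- vapply(run$spectra, function(s)
    if (s$ms_level == 2) s$isolation_center else NA_real_, numeric(1))
  isw <- vapply(run$spectra, function(s)
    if (s$ms_level == 2) s$isolation_width else NA_real_, numeric(1))
  bp <- vapply(run$spectra, function(s) {
    if (!length(s$intensity)) return(c(NA_real_, 0))
    j <- which.max(s$intensity); c(s$mz[j], s$intensity[j])
  }, numeric(2))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = as.integer(lvl),
    polarity = if (identical(run$polarity, "negative")) 0L else 1L,
    peaksCount = npk, totIonCurrent = tic, retentionTime = rt * 60,
    basePeakMZ = bp[1, ], basePeakIntensity = bp[2, ],
    collisionEnergy = ifelse(lvl == 2, 30, 0), ionisationEnergy = 0,
    lowMZ = vapply(run$spectra, function(s)
      if (length(s$mz)) min(s$mz) else 0, numeric(1)),
    highMZ = vapply(run$spectra, function(s)
      if (length(s$mz)) max(s$mz) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = ifelse(lvl == 2, iso, 0),
    precursorCharge = ifelse(lvl == 2, 1L, 0L), precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
    mergedResultEndScanNum = 0L, injectionTime = 0, filterString = "",
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = iso, isolationWindowLowerOffset = isw / 2,
    isolationWindowUpperOffset = isw / 2,
    scanWindowLowerLimit = run$ms1_range[1],
    scanWindowUpperLimit = run$ms1_range[2],
    stringsAsFactors = FALSE)
  pk <- lapply(run$spectra, function(s)
    cbind(mz = s$mz, intensity = s$intensity))
  mzR::writeMSData(pk, path, header = hdr)
  invisible(path)
}
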