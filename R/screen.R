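#' Neutral-loss screening parameters
#'
#' Defaults follow the untargeted deoxyribonucleoside-adduct screen: a
#' 116.0473 Da deoxyribose neutral loss matched at 5 ppm (referenced to the
#' precursor m/z), precursor/fragment apex co-elution within 0.1 min.
#' `scan_lo`/`scan_hi` restrict which MS1 precursors are considered (the
#' low-mass acquisition screens 195--355 m/z, the high-mass one 350--600).
#'
#' @param neutral_loss_mass neutral loss, Da.
#' @param ppm_tol mass tolerance, ppm, referenced to the precursor m/z.
#' @param coelution_tol maximum apex RT difference, minutes.
#' @param scan_lo,scan_hi precursor m/z range screened.
#' @param mass_class `"low"`, `"high"`, or `"auto"` (from `scan_hi`).
#' @param min_trace_points minimum number of MS1 centroids an m/z trace
#'   must collect before an EIC is built for it (noise suppression).
#' @return list of class `screen_params`.
#' @export
screen_params <- function(neutral_loss_mass = 116.0473, ppm_tol = 5,
                          coelution_tol = 0.1, scan_lo = 347, scan_hi = 607,
                          mass_class = c("auto", "low", "high"),
                          min_trace_points = 5) {
  stopifnot(neutral_loss_mass > 0, ppm_tol > 0, coelution_tol > 0,
            scan_hi > scan_lo)
  mass_class <- match.arg(mass_class)
  if (mass_class == "auto") mass_class <- if (scan_hi <= 360) "low" else "high"
  structure(list(neutral_loss_mass = neutral_loss_mass, ppm_tol = ppm_tol,
                 coelution_tol = coelution_tol, scan_lo = scan_lo,
                 scan_hi = scan_hi, mass_class = mass_class,
                 min_trace_points = min_trace_points),
            class = "screen_params")
}

# Group sorted m/z values by single linkage at a ppm gap threshold;
# returns integer group ids aligned to the input order.
.group_mz <- function(mz, ppm) {
  ord <- order(mz)
  s <- mz[ord]
  brk <- c(FALSE, diff(s) > ppm * 1e-6 * s[-length(s)])
  gid_sorted <- cumsum(brk) + 1L
  gid <- integer(length(mz))
  gid[ord] <- gid_sorted
  gid
}

#' Screen a DIA run for neutral-loss precursor/fragment pairs
#'
#' Untargeted detection of putative 2'-deoxyribonucleoside adducts: MS1
#' centroids within the screened scan range are grouped into m/z traces;
#' each trace's extracted-ion chromatogram is run through the peak
#' detector; for every detected precursor peak, the DIA window containing
#' the precursor is searched for an MS2 peak at
#' `precursor - neutral_loss_mass` (tolerance `ppm_tol` ppm of the
#' precursor m/z) whose apex co-elutes within `coelution_tol` minutes.
#' ESI adducts and isotopologues are deliberately not removed.
#'
#' @param run an [ms_run()] object with MS1 and DIA MS2 spectra.
#' @param det [peak_params()] used for both MS1 and MS2 peak detection.
#' @param scr [screen_params()].
#' @param sample_id label recorded on every emitted pair.
#' @return data.frame of putative adducts: `sample_id`, `precursor_mz`,
#'   `fragment_mz`, `rt`, `observed_loss`, `loss_ppm_error` (referenced to
#'   the precursor m/z), `precursor_snr`, `precursor_area`, `mass_class`.
#' @export
screen_run <- function(run, det = peak_params(), scr = screen_params(),
                       sample_id = "sample") {
  stopifnot(inherits(run, "ms_run"))
  counts <- ms_level_counts(run)
  if (counts["ms2"] == 0) stop("no DIA spectra in run")
  if (counts["ms1"] == 0) stop("no MS1 spectra in run")
  empty <- data.frame(sample_id = character(), precursor_mz = numeric(),
                      fragment_mz = numeric(), rt = numeric(),
                      observed_loss = numeric(), loss_ppm_error = numeric(),
                      precursor_snr = numeric(), precursor_area = numeric(),
                      mass_class = character())
  # candidate precursor m/z traces from all in-range MS1 centroids
  ms1 <- Filter(function(s) s$ms_level == 1, run$spectra)
  allmz <- unlist(lapply(ms1, function(s) {
    i <- s$mz >= scr$scan_lo & s$mz <= scr$scan_hi & s$intensity > 0
    s$mz[i]
  }))
  allint <- unlist(lapply(ms1, function(s) {
    i <- s$mz >= scr$scan_lo & s$mz <= scr$scan_hi & s$intensity > 0
    s$intensity[i]
  }))
  if (!length(allmz)) return(empty)
  gid <- .group_mz(allmz, scr$ppm_tol)
  sizes <- tabulate(gid)
  cand_mz <- vapply(which(sizes >= scr$min_trace_points), function(g) {
    i <- gid == g
    sum(allmz[i] * allint[i]) / sum(allint[i])
  }, numeric(1))
  cand_mz <- cand_mz[cand_mz >= run$dia_scheme$precursor_lo &
                       cand_mz < run$dia_scheme$precursor_hi]
  if (!length(cand_mz)) return(empty)
  rows <- lapply(cand_mz, function(pmz) {
    eic1 <- extract_eic(run, pmz, ppm_tol = scr$ppm_tol, ms_level = 1)
    pk1 <- detect_peaks(eic1, det)
    if (nrow(pk1) == 0) return(NULL)
    win <- window_for_mz(run$dia_scheme, pmz)
    fmz <- pmz - scr$neutral_loss_mass
    eic2 <- extract_eic(run, fmz, ms_level = 2, window = win,
                        abs_tol = scr$ppm_tol * 1e-6 * pmz)
    pk2 <- detect_peaks(eic2, det)
    if (nrow(pk2) == 0) return(NULL)
    out <- lapply(seq_len(nrow(pk1)), function(i) {
      d <- abs(pk2$apex_rt - pk1$apex_rt[i])
      j <- which.min(d)
      if (d[j] > scr$coelution_tol) return(NULL)
      prec_obs <- if (is.na(pk1$mz_obs[i])) pmz else pk1$mz_obs[i]
      frag_obs <- if (is.na(pk2$mz_obs[j])) fmz else pk2$mz_obs[j]
      loss <- prec_obs - frag_obs
      data.frame(sample_id = sample_id, precursor_mz = prec_obs,
                 fragment_mz = frag_obs, rt = pk1$apex_rt[i],
                 observed_loss = loss,
                 loss_ppm_error = (loss - scr$neutral_loss_mass) /
                   prec_obs * 1e6,
                 precursor_snr = pk1$snr[i], precursor_area = pk1$area[i],
                 mass_class = scr$mass_class)
    })
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out)) do.call(rbind, out) else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[abs(out$loss_ppm_error) <= scr$ppm_tol, , drop = FALSE]
  out <- out[order(out$precursor_mz, out$rt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge per-sample putative adducts into a master list
#'
#' Single-linkage grouping within `merge_ppm` (m/z) and `merge_rt` (RT);
#' consensus m/z and RT are medians over the grouped detections. IDs are
#' assigned `L1`, `L2`, ... / `H1`, `H2`, ... by ascending consensus m/z
#' within each mass class. Merging a master list with itself returns the
#' same entries (idempotence).
#'
#' @param ... data.frames from [screen_run()] (or a single list of them);
#'   required columns `precursor_mz` (or `mz`), `rt`, `mass_class`,
#'   `sample_id` (or `adduct_id`, reused as the sample label).
#' @param merge_ppm m/z merge tolerance, ppm.
#' @param merge_rt RT merge tolerance, minutes.
#' @return data.frame of class `master_list`: `adduct_id`, `mz`, `rt`,
#'   `mass_class`, `n_samples_detected`, `n_detections`.
#' @export
build_master_list <- function(..., merge_ppm = 5, merge_rt = 0.5) {
  stopifnot(merge_ppm > 0, merge_rt > 0)
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) && !is.data.frame(args[[1]]))
    args <- args[[1]]
  empty <- data.frame(adduct_id = character(), mz = numeric(), rt = numeric(),
                      mass_class = character(), n_samples_detected = integer(),
                      n_detections = integer())
  args <- Filter(function(d) is.data.frame(d) && nrow(d) > 0, args)
  if (!length(args)) return(structure(empty, class = c("master_list",
                                                       "data.frame")))
  norm1 <- function(d) {
    mz <- if ("precursor_mz" %in% names(d)) d$precursor_mz else d$mz
    sid <- if ("sample_id" %in% names(d)) d$sample_id else d$adduct_id
    data.frame(mz = mz, rt = d$rt, mass_class = d$mass_class,
               sample_id = sid, stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, lapply(args, norm1))
  res <- lapply(split(all, all$mass_class), function(d) {
    d <- d[order(d$mz, d$rt), , drop = FALSE]
    n <- nrow(d)
    # union-find over mz-sorted entries; link within both tolerances
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) {
      j <- i - 1L
      while (j >= 1 && (d$mz[i] - d$mz[j]) <= merge_ppm * 1e-6 * d$mz[i]) {
        if (abs(d$rt[i] - d$rt[j]) <= merge_rt) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
        j <- j - 1L
      }
    }
    root <- vapply(seq_len(n), find, integer(1))
    grp <- split(seq_len(n), root)
    ent <- lapply(grp, function(idx) data.frame(
      mz = stats::median(d$mz[idx]), rt = stats::median(d$rt[idx]),
      mass_class = d$mass_class[idx[1]],
      n_samples_detected = length(unique(d$sample_id[idx])),
      n_detections = length(idx)))
    ent <- do.call(rbind, ent)
    ent <- ent[order(ent$mz), , drop = FALSE]
    pre <- if (ent$mass_class[1] == "low") "L" else "H"
    ent$adduct_id <- paste0(pre, seq_len(nrow(ent)))
    ent[, c("adduct_id", "mz", "rt", "mass_class", "n_samples_detected",
            "n_detections")]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("master_list", "data.frame"))
}
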