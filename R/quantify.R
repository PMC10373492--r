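#' Targeted confirmation / quantification parameters
#'
#' A master-list entry counts as detected in a run when an MS1 peak is found
#' within 5 ppm of its consensus m/z at a comparable retention time
#' (+/- 0.2 min by default). Adducts whose replicate relative standard
#' deviation reaches 20 percent are dropped before statistics.
#'
#' @param ppm_tol mass tolerance, ppm.
#' @param rt_tol retention-time tolerance, minutes.
#' @param rsd_max RSD threshold, percent (retention requires RSD strictly
#'   below this value).
#' @return list of class `quant_params`.
#' @export
quant_params <- function(ppm_tol = 5, rt_tol = 0.2, rsd_max = 20) {
  stopifnot(ppm_tol > 0, rt_tol > 0, rsd_max > 0)
  structure(list(ppm_tol = ppm_tol, rt_tol = rt_tol, rsd_max = rsd_max),
            class = "quant_params")
}

#' Integrate master-list targets in a run
#'
#' For each master entry the MS1 EIC at `mz +/- ppm_tol` is extracted and
#' peak-detected; the entry is detected when a peak apex lies within
#' `rt_tol` of the consensus RT (the closest such peak is integrated).
#' Absence is data, not an error.
#'
#' @param run an [ms_run()] object.
#' @param master a [build_master_list()] data.frame (columns `adduct_id`,
#'   `mz`, `rt`).
#' @param q [quant_params()].
#' @param det [peak_params()].
#' @return data.frame `adduct_id`, `detected`, `area`, `apex_rt`, `snr`.
#' @export
integrate_targets <- function(run, master, q = quant_params(),
                              det = peak_params()) {
  stopifnot(nrow(master) > 0)
  rows <- lapply(seq_len(nrow(master)), function(i) {
    eic <- extract_eic(run, master$mz[i], ppm_tol = q$ppm_tol, ms_level = 1)
    pk <- detect_peaks(eic, det)
    hit <- if (nrow(pk)) which(abs(pk$apex_rt - master$rt[i]) <= q$rt_tol)
           else integer()
    if (length(hit)) {
      j <- hit[which.min(abs(pk$apex_rt[hit] - master$rt[i]))]
      data.frame(adduct_id = master$adduct_id[i], detected = TRUE,
                 area = pk$area[j], apex_rt = pk$apex_rt[j], snr = pk$snr[j])
    } else {
      data.frame(adduct_id = master$adduct_id[i], detected = FALSE,
                 area = 0, apex_rt = NA_real_, snr = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalise adduct areas to the dG peak area
#'
#' Semi-quantification relative to unmodified 2'-deoxyguanosine:
#' `norm = raw * 100 / dG` per sample, correcting DNA amount, digestion
#' losses and instrument drift.
#'
#' @param raw_area samples x adducts numeric matrix of peak areas.
#' @param dg_area per-sample dG peak areas (named or in row order).
#' @return matrix of dG-normalised areas, same dimnames as `raw_area`.
#' @export
normalize_to_dg <- function(raw_area, dg_area) {
  raw_area <- as.matrix(raw_area)
  if (!is.null(names(dg_area)) && !is.null(rownames(raw_area)))
    dg_area <- dg_area[rownames(raw_area)]
  stopifnot(length(dg_area) == nrow(raw_area))
  bad <- which(!(dg_area > 0))
  if (length(bad)) {
    lab <- if (!is.null(rownames(raw_area))) rownames(raw_area)[bad] else bad
    stop("non-positive dG area for sample(s): ", paste(lab, collapse = ", "))
  }
  sweep(raw_area, 1, dg_area, "/") * 100
}

#' Replicate-RSD repeatability filter
#'
#' Per adduct, the relative standard deviation (100 x sd / mean) of the
#' dG-normalised areas is computed across the replicates of each parent
#' animal and aggregated across animals (maximum by default, the most
#' conservative choice). Adducts are retained when the aggregated RSD is
#' strictly below `rsd_max`. Adducts with a zero replicate mean are
#' excluded with a message.
#'
#' @param norm_area samples x adducts matrix of dG-normalised areas.
#' @param replicate_of per-sample parent-animal labels (length =
#'   `nrow(norm_area)`); animals with fewer than 2 replicates are ignored.
#' @param rsd_max threshold, percent.
#' @param aggregate `"max"` (default) or `"mean"` across animals.
#' @return character vector of retained adduct ids, with the per-adduct
#'   aggregated RSD table in attribute `"rsd"`.
#' @export
rsd_filter <- function(norm_area, replicate_of, rsd_max = 20,
                       aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  norm_area <- as.matrix(norm_area)
  stopifnot(length(replicate_of) == nrow(norm_area))
  groups <- split(seq_len(nrow(norm_area)), replicate_of)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  if (!length(groups)) stop("no animal has >= 2 replicates")
  ids <- colnames(norm_area)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(norm_area)))
  agg_fun <- if (aggregate == "max") max else mean
  rsd <- numeric(ncol(norm_area)); excluded <- logical(ncol(norm_area))
  for (j in seq_len(ncol(norm_area))) {
    per_animal <- vapply(groups, function(idx) {
      x <- norm_area[idx, j]
      m <- mean(x)
      if (m == 0) return(NA_real_)
      100 * stats::sd(x) / m
    }, numeric(1))
    if (anyNA(per_animal)) {
      excluded[j] <- TRUE
      rsd[j] <- NA_real_
      message("adduct ", ids[j], " excluded: zero replicate mean")
    } else rsd[j] <- agg_fun(per_animal)
  }
  retained <- ids[!excluded & rsd < rsd_max]
  attr(retained, "rsd") <- stats::setNames(rsd, ids)
  retained
}

#' Assemble an adduct table from per-run integrations
#'
#' Combines [integrate_targets()] results across samples into the
#' samples x adducts container used downstream.
#'
#' @param integrations named list (one element per sample) of
#'   [integrate_targets()] data.frames.
#' @param dg_area per-sample dG areas, same names.
#' @param replicate_of optional per-sample parent-animal labels.
#' @return object of class `adduct_table`: list with `samples`, `adducts`,
#'   `raw_area`, `dg_area`, `norm_area`, `replicate_of`.
#' @export
adduct_table <- function(integrations, dg_area, replicate_of = NULL) {
  stopifnot(length(integrations) > 0, !is.null(names(integrations)))
  ids <- integrations[[1]]$adduct_id
  raw <- t(vapply(integrations, function(d) {
    stats::setNames(d$area, d$adduct_id)[ids]
  }, numeric(length(ids))))
  colnames(raw) <- ids
  rownames(raw) <- names(integrations)
  norm <- normalize_to_dg(raw, dg_area)
  structure(list(samples = rownames(raw), adducts = ids, raw_area = raw,
                 dg_area = dg_area, norm_area = norm,
                 replicate_of = replicate_of),
            class = "adduct_table")
}

#' @export
print.adduct_table <- function(x, ...) {
  cat(sprintf("Adduct table: %d samples x %d adducts (dG-normalised)\n",
              length(x$samples), length(x$adducts)))
  invisible(x)
}
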