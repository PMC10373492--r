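#' A panel of planted adducts for run simulation
#'
#' @param precursor_mz protonated precursor m/z values.
#' @param rt apex retention times, minutes.
#' @param abundance chromatographic peak areas (counts x min).
#' @param fragmentation_efficiency fraction of the precursor intensity
#'   appearing as the neutral-loss fragment in the DIA scan (scalar or
#'   per adduct), in (0, 1].
#' @return data.frame with one row per planted adduct.
#' @export
planted_panel <- function(precursor_mz, rt, abundance,
                          fragmentation_efficiency = 0.5) {
  stopifnot(all(abundance > 0), all(fragmentation_efficiency > 0),
            all(fragmentation_efficiency <= 1))
  data.frame(precursor_mz = precursor_mz, rt = rt, abundance = abundance,
             fragmentation_efficiency =
               rep_len(fragmentation_efficiency, length(precursor_mz)))
}

#' Simulate a DIA LC-HRMS run with planted adducts
#'
#' Generates an acquisition loop of one MS1 full scan followed by a sweep
#' of all DIA windows, repeated at a fixed cycle time. Planted adducts
#' elute as Gaussian profiles (sigma `peak_sigma` min, trapezoid area equal
#' to the requested abundance); each MS2 window scan carries the
#' `precursor - 116.0473` fragment of the planted adducts isolated in that
#' window at `fragmentation_efficiency` times the precursor intensity.
#' Centroid m/z values receive Gaussian ppm jitter; baseline noise adds a
#' Poisson-distributed number of exponential-intensity centroids per scan.
#' Identical seeds give identical runs (and byte-identical mzML files).
#'
#' @param panel [planted_panel()] data.frame (may have zero rows).
#' @param scheme [build_dia_scheme()]; all planted precursors must fall
#'   inside it.
#' @param seed RNG seed (required).
#' @param gradient_length run length, minutes.
#' @param cycle_time MS1-to-MS1 cycle time, minutes (default 1 s).
#' @param peak_sigma chromatographic Gaussian sigma, minutes.
#' @param jitter_ppm sd of the scan-to-scan centroid m/z jitter, ppm
#'   (default 1, the scan-to-scan mass precision of an Orbitrap at the
#'   120k resolution used for the MS1 scans).
#' @param noise_peaks mean number of baseline noise centroids per scan
#'   (0 disables noise).
#' @param noise_intensity mean intensity of a noise centroid.
#' @param ms1_range MS1 scan range, m/z.
#' @param path optional file path; when given the run is written as mzML.
#' @return list with `run` (an [ms_run()]), `manifest` (the panel plus the
#'   per-adduct ground-truth fragment m/z) and `path`.
#' @export
simulate_run <- function(panel, scheme, seed, gradient_length = 20,
                         cycle_time = 1 / 60, peak_sigma = 0.05,
                         jitter_ppm = 1, noise_peaks = 30,
                         noise_intensity = 50, ms1_range = c(110, 650),
                         path = NULL) {
  if (missing(seed)) stop("a simulation seed is required")
  stopifnot(inherits(scheme, "dia_scheme"))
  if (nrow(panel)) {
    if (any(panel$precursor_mz < scheme$precursor_lo |
              panel$precursor_mz >= scheme$precursor_hi))
      stop("planted precursor outside the DIA scheme")
    if (any(panel$rt <= 0 | panel$rt >= gradient_length))
      stop("planted RT outside the gradient")
  }
  set.seed(seed)
  frag_mz <- panel$precursor_mz - DEOXYRIBOSE_LOSS
  win <- if (nrow(panel)) window_for_mz(scheme, panel$precursor_mz) else integer()
  amp <- if (nrow(panel))
    panel$abundance / (peak_sigma * sqrt(2 * pi)) else numeric()
  n_cycles <- floor(gradient_length / cycle_time)
  dt_scan <- cycle_time / (scheme$n_windows + 1)
  min_int <- 1e-3
  spectra <- vector("list", n_cycles * (scheme$n_windows + 1))
  k <- 0L
  jitter <- function(mz) mz * (1 + stats::rnorm(length(mz)) * jitter_ppm * 1e-6)
  noise_centroids <- function(lo, hi) {
    n <- if (noise_peaks > 0) stats::rpois(1, noise_peaks) else 0L
    if (n == 0) return(list(mz = numeric(), intensity = numeric()))
    list(mz = stats::runif(n, lo, hi),
         intensity = stats::rexp(n, 1 / noise_intensity))
  }
  assemble <- function(mz, inten) {
    ok <- inten >= min_int
    mz <- mz[ok]; inten <- inten[ok]
    ord <- order(mz)
    mz <- mz[ord]; inten <- inten[ord]
    # merge pathological exact ties to keep m/z strictly ascending
    if (length(mz) > 1 && any(diff(mz) <= 0)) {
      g <- cumsum(c(TRUE, diff(mz) > 0))
      inten <- as.numeric(tapply(inten, g, sum))
      mz <- as.numeric(tapply(mz, g, min))
    }
    list(mz = mz, intensity = inten)
  }
  for (cy in seq_len(n_cycles)) {
    t0 <- (cy - 1) * cycle_time
    sig <- if (nrow(panel))
      amp * exp(-(t0 - panel$rt)^2 / (2 * peak_sigma^2)) else numeric()
    live <- which(sig >= min_int)
    nz <- noise_centroids(ms1_range[1], ms1_range[2])
    sp <- assemble(c(jitter(panel$precursor_mz[live]), nz$mz),
                   c(sig[live], nz$intensity))
    k <- k + 1L
    spectra[[k]] <- list(ms_level = 1, rt = t0, mz = sp$mz,
                         intensity = sp$intensity)
    for (w in seq_len(scheme$n_windows)) {
      tw <- t0 + w * dt_scan
      sigw <- if (nrow(panel))
        amp * panel$fragmentation_efficiency *
          exp(-(tw - panel$rt)^2 / (2 * peak_sigma^2)) else numeric()
      livew <- which(sigw >= min_int & win == w)
      nzw <- noise_centroids(50, scheme$centers[w] + scheme$window_width / 2)
      sp2 <- assemble(c(jitter(frag_mz[livew]), nzw$mz),
                      c(sigw[livew], nzw$intensity))
      k <- k + 1L
      spectra[[k]] <- list(ms_level = 2, rt = tw, mz = sp2$mz,
                           intensity = sp2$intensity,
                           isolation_center = scheme$centers[w],
                           isolation_width = scheme$window_width)
    }
  }
  run <- ms_run(spectra, scheme, ms1_range = ms1_range, validate = FALSE)
  manifest <- cbind(panel,
                    fragment_mz = if (nrow(panel)) frag_mz else numeric(),
                    window = if (nrow(panel)) win else integer())
  if (!is.null(path)) write_mzml(run, path)
  list(run = run, manifest = manifest, path = path)
}

#' Design of a synthetic exposure study
#'
#' Emulates a two-basin field design: contaminated and reference stations,
#' several individuals per station, a low/high-mass adduct panel with
#' planted log2 effect sizes, and station-level sediment contaminants
#' (11 PAH congeners with LmPAH/HmPAH sums, 10 trace metals, and a
#' pollution load index) tied to chosen adducts through a Gaussian copula
#' on the log scale.
#'
#' @param n_contaminated,n_reference numbers of stations per status.
#' @param individuals_per_station individuals sampled per station (scalar
#'   or per-station vector, contaminated stations first).
#' @param n_low,n_high numbers of low- and high-mass adducts.
#' @param effect_adducts named numeric vector of log2 fold changes
#'   (Contaminated vs Reference) keyed by adduct id (e.g. `c(H5 = 2)`).
#' @param correlation_targets data.frame with columns `adduct`,
#'   `contaminant`, `r`: target Pearson correlations (log scale).
#' @param noise_sd residual sd of log adduct abundance (natural log).
#' @param adduct_icc fraction of adduct log-variance at station level
#'   (drives how strongly station-level contaminants can correlate).
#' @param contaminant_shift log-scale elevation of every contaminant at
#'   contaminated stations.
#' @param seed RNG seed (required).
#' @return list of class `study_design`.
#' @export
study_design <- function(n_contaminated = 10, n_reference = 9,
                         individuals_per_station = NULL,
                         n_low = 53, n_high = 66,
                         effect_adducts = numeric(),
                         correlation_targets = NULL,
                         noise_sd = 0.5, adduct_icc = 0.5,
                         contaminant_shift = 1, seed) {
  if (missing(seed)) stop("a study seed is required")
  n_st <- n_contaminated + n_reference
  if (is.null(individuals_per_station)) {
    # ~28 contaminated + ~19 reference individuals, as in a 47-animal survey
    individuals_per_station <- c(rep_len(c(3, 3, 3, 3, 2), n_contaminated),
                                 rep_len(c(2, 2, 2, 2, 3), n_reference))
  } else individuals_per_station <- rep_len(individuals_per_station, n_st)
  structure(list(n_contaminated = n_contaminated, n_reference = n_reference,
                 individuals_per_station = individuals_per_station,
                 n_low = n_low, n_high = n_high,
                 effect_adducts = effect_adducts,
                 correlation_targets = correlation_targets,
                 noise_sd = noise_sd, adduct_icc = adduct_icc,
                 contaminant_shift = contaminant_shift, seed = seed),
            class = "study_design")
}

.PAH_NAMES <- c("Phe", "Ant", "Flu", "Pyr", "BaA", "Chr", "BbF", "BkF",
                "BaP", "DahA", "BghiP")
.METAL_NAMES <- c("As", "Cd", "Co", "Cr", "Cu", "Hg", "Ni", "Pb", "V", "Zn")

#' Simulate a study-level adduct table and site metadata
#'
#' Adduct abundances are lognormal with a station-level random component
#' (intraclass fraction `adduct_icc`); adducts listed in `effect_adducts`
#' are rescaled in contaminated samples so that the realized
#' contaminated/reference group-mean ratio equals `2^effect` exactly
#' (calibrated multiplicative planting, giving recovery tests exact
#' ground truth). Contaminant
#' concentrations are station-level lognormals, elevated at contaminated
#' stations, and linked to target adducts' station components so that the
#' sample-level Pearson correlation on the log scale approaches the
#' requested `r`. Per-sample dG areas are drawn so that dG normalisation is
#' exercised. Identical seeds give identical outputs.
#'
#' @param design a [study_design()].
#' @return list with `table` (an [adduct_table()]) and `meta` (data.frame:
#'   `sample_id`, `station`, `basin`, `status`, contaminant columns,
#'   `LmPAH`, `HmPAH`, `PLI`).
#' @export
simulate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  d <- design
  n_st <- d$n_contaminated + d$n_reference
  st_status <- rep(c("Contaminated", "Reference"),
                   c(d$n_contaminated, d$n_reference))
  st_names <- paste0(ifelse(st_status == "Contaminated", "C", "R"),
                     c(seq_len(d$n_contaminated), seq_len(d$n_reference)))
  st_basin <- rep_len(c("BS", "NBP"), n_st)
  nind <- d$individuals_per_station
  sample_station <- rep(seq_len(n_st), nind)
  n <- sum(nind)
  sample_id <- paste0(st_names[sample_station], "_",
                      unlist(lapply(nind, seq_len)))
  status <- st_status[sample_station]
  ids <- c(paste0("L", seq_len(d$n_low)), paste0("H", seq_len(d$n_high)))
  p <- length(ids)
  # latent station and individual components per adduct
  a <- sqrt(d$adduct_icc); b <- sqrt(1 - d$adduct_icc)
  S <- matrix(stats::rnorm(n_st * p), n_st, p)          # station latents
  E <- matrix(stats::rnorm(n * p), n, p)                # individual latents
  U <- a * S[sample_station, , drop = FALSE] + b * E
  base_log <- stats::runif(p, log(0.05), log(20))       # % of dG scale
  logA <- sweep(U * d$noise_sd, 2, base_log, "+")
  norm_area <- exp(logA)
  dimnames(norm_area) <- list(sample_id, ids)
  if (length(d$effect_adducts)) {
    # effects are planted as exact realized fold changes between the group
    # means: contaminated samples of each listed adduct are rescaled so
    # that mean(C)/mean(R) equals 2^effect, giving recovery tests exact
    # ground truth
    j <- match(names(d$effect_adducts), ids)
    if (anyNA(j)) stop("unknown effect adduct id")
    gc <- status == "Contaminated"
    for (k in seq_along(j)) {
      s <- 2^d$effect_adducts[k] * mean(norm_area[!gc, j[k]]) /
        mean(norm_area[gc, j[k]])
      norm_area[gc, j[k]] <- norm_area[gc, j[k]] * s
    }
  }
  # station-level contaminants
  cont_names <- c(.PAH_NAMES, .METAL_NAMES)
  cont_base <- c(stats::runif(length(.PAH_NAMES), log(5), log(80)),
                 stats::runif(length(.METAL_NAMES), log(1), log(50)))
  Zc <- matrix(stats::rnorm(n_st * length(cont_names)), n_st,
               dimnames = list(NULL, cont_names))
  targeted <- logical(length(cont_names))
  if (!is.null(d$correlation_targets)) {
    ct <- d$correlation_targets
    for (i in seq_len(nrow(ct))) {
      ja <- match(ct$adduct[i], ids)
      jc <- match(ct$contaminant[i], cont_names)
      if (is.na(ja) || is.na(jc)) stop("unknown correlation target name")
      rho_s <- ct$r[i] / a
      if (abs(rho_s) > 1)
        stop("infeasible correlation target r = ", ct$r[i],
             " with adduct_icc = ", d$adduct_icc)
      Zc[, jc] <- rho_s * S[, ja] + sqrt(1 - rho_s^2) * stats::rnorm(n_st)
      targeted[jc] <- TRUE
    }
  }
  # contaminants carrying a copula target skip the status elevation, which
  # would otherwise attenuate the requested correlation
  shift_vec <- d$contaminant_shift * !targeted
  logC <- sweep(0.6 * Zc, 2, cont_base, "+") +
    outer(as.numeric(st_status == "Contaminated"), shift_vec)
  conc <- exp(logC)
  lm_idx <- match(c("Phe", "Ant", "Flu"), cont_names)
  met_idx <- match(.METAL_NAMES, cont_names)
  LmPAH <- rowSums(conc[, lm_idx, drop = FALSE])
  HmPAH <- rowSums(conc[, setdiff(seq_along(.PAH_NAMES), lm_idx),
                        drop = FALSE])
  bg <- exp(cont_base[met_idx])                  # reference background level
  PLI <- exp(rowMeans(log(sweep(conc[, met_idx, drop = FALSE], 2, bg, "/"))))
  meta <- data.frame(sample_id = sample_id, station = st_names[sample_station],
                     basin = st_basin[sample_station], status = status,
                     conc[sample_station, , drop = FALSE],
                     LmPAH = LmPAH[sample_station],
                     HmPAH = HmPAH[sample_station],
                     PLI = PLI[sample_station], row.names = NULL)
  dg_area <- stats::setNames(stats::rlnorm(n, log(1e6), 0.2), sample_id)
  raw_area <- sweep(norm_area, 1, dg_area, "*") / 100
  tab <- structure(list(samples = sample_id, adducts = ids,
                        raw_area = raw_area, dg_area = dg_area,
                        norm_area = norm_area,
                        replicate_of = NULL),
                   class = "adduct_table")
  list(table = tab, meta = meta)
}
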