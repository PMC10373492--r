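# Most-abundant-isotope masses (IUPAC/CODATA), Da.
.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163
)

#' Mass of the proton, Da
#'
#' Used to convert a neutral monoisotopic mass to the m/z of the
#' singly protonated even-electron ion \eqn{[M+H]^+}.
#' @export
PROTON_MASS <- 1.0072765

#' Monoisotopic mass of the 2'-deoxyribose neutral loss (C5H8O3), Da
#'
#' The mass difference between a protonated 2'-deoxyribonucleoside and its
#' protonated nucleobase fragment; the diagnostic signature used for
#' untargeted adduct screening.
#' @export
DEOXYRIBOSE_LOSS <- 116.04734412

#' Parse a molecular formula
#'
#' Accepts Hill-style formula strings such as `"C22H44N2O12"` (spaces
#' allowed, element order free, no multipliers or charges).
#'
#' @param formula formula string, or an already-parsed named integer vector
#'   of element counts.
#' @return named integer vector of element counts (elements among
#'   C, H, N, O, S, P).
#' @examples
#' parse_formula("C5H8O3")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    counts <- formula
    if (is.null(names(counts)) || any(!nzchar(names(counts))))
      stop("element counts must be named")
  } else {
    s <- gsub("[[:space:]]", "", formula)
    if (!nzchar(s)) stop("empty composition")
    toks <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
    if (sum(nchar(toks)) != nchar(s))
      stop("cannot parse formula: ", formula)
    el <- sub("[0-9]*$", "", toks)
    n <- sub("^[A-Za-z]+", "", toks)
    counts <- ifelse(nzchar(n), as.integer(n), 1L)
    names(counts) <- el
    counts <- tapply(counts, names(counts), sum)
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  bad <- setdiff(names(counts), names(.ATOMIC_MASS))
  if (length(bad)) stop("unknown element symbol: ", paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("negative element count")
  if (sum(counts) == 0) stop("empty composition")
  counts[counts > 0]
}

#' Format element counts in Hill notation
#'
#' @param counts named integer vector of element counts.
#' @return formula string with C first, H second, remaining elements
#'   alphabetical (`"C22H44N2O12"`).
#' @export
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  el <- names(counts)
  ord <- c(intersect(c("C", "H"), el), sort(setdiff(el, c("C", "H"))))
  paste0(ord, ifelse(counts[ord] > 1, counts[ord], ""), collapse = "")
}

#' Monoisotopic mass of a composition
#'
#' Sum of most-abundant-isotope masses. For `species = "protonated"` one
#' proton mass is added and the value is the m/z of the singly charged
#' \eqn{[M+H]^+} ion.
#'
#' @param composition formula string or named element-count vector.
#' @param species `"neutral"` (default) or `"protonated"`.
#' @return mass in Da (m/z for the protonated species).
#' @examples
#' monoisotopic_mass("C5H8O3")                    # deoxyribose loss, 116.0473
#' monoisotopic_mass("C10H13N5O4", "protonated")  # dG [M+H]+, 268.1040
#' @export
monoisotopic_mass <- function(composition, species = c("neutral", "protonated")) {
  species <- match.arg(species)
  counts <- parse_formula(composition)
  m <- sum(.ATOMIC_MASS[names(counts)] * counts)
  if (species == "protonated") m <- m + PROTON_MASS
  unname(m)
}

#' Mass accuracy in parts per million
#'
#' @param observed observed m/z.
#' @param theoretical theoretical m/z (> 0).
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  (observed - theoretical) / theoretical * 1e6
}

#' Rings-plus-double-bonds equivalent
#'
#' `RDB = C - H/2 + N/2 + 1`; oxygen and sulfur contribute nothing,
#' phosphorus counts like nitrogen (trivalent-equivalent convention).
#' Half-integer values indicate an even-electron ion composition.
#'
#' @param composition formula string or named element-count vector.
#' @return RDB equivalents (may be half-integer or negative).
#' @examples
#' rdb("C22H44O12N2")  # 2
#' @export
rdb <- function(composition) {
  counts <- parse_formula(composition)
  g <- function(e) if (e %in% names(counts)) counts[[e]] else 0L
  g("C") - g("H") / 2 + (g("N") + g("P")) / 2 + 1
}

#' Enumeration constraints for formula annotation
#'
#' Defaults follow the annotation settings used for nucleoside adducts:
#' minimum 9 C, 3 O and 2 N; charge 1; 5 ppm tolerance. Upper bounds keep
#' the CHNO search space finite.
#'
#' @param min_C,min_H,min_N,min_O element lower bounds.
#' @param max_C,max_H,max_N,max_O element upper bounds.
#' @param ppm_tol search tolerance, ppm.
#' @param parity_filter drop candidates whose neutral RDB is negative or
#'   non-integer (even-electron protonated species hygiene). Disable to see
#'   every mass-compatible CHNO composition.
#' @return list of class `enum_constraints`.
#' @export
enum_constraints <- function(min_C = 9, min_H = 0, min_N = 2, min_O = 3,
                             max_C = 40, max_H = 80, max_N = 12, max_O = 20,
                             ppm_tol = 5, parity_filter = TRUE) {
  stopifnot(min_C <= max_C, min_H <= max_H, min_N <= max_N, min_O <= max_O,
            ppm_tol > 0)
  structure(list(min_C = min_C, min_H = min_H, min_N = min_N, min_O = min_O,
                 max_C = max_C, max_H = max_H, max_N = max_N, max_O = max_O,
                 ppm_tol = ppm_tol, parity_filter = parity_filter),
            class = "enum_constraints")
}

#' Enumerate CHNO compositions matching an observed m/z
#'
#' Finds every CHNO composition whose protonated monoisotopic m/z lies
#' within `ppm_tol` of `target_mz`, subject to element bounds and
#' (optionally) to non-negative integer neutral RDB. Candidates are ranked
#' by absolute mass deviation.
#'
#' @param target_mz observed m/z of the (assumed singly protonated) ion.
#' @param constraints an [enum_constraints()] object.
#' @return data.frame with columns `formula`, `C`, `H`, `N`, `O`,
#'   `theoretical_mz`, `delta_ppm`, `rdb`, sorted by `abs(delta_ppm)`;
#'   zero rows when no composition fits.
#' @examples
#' enumerate_compositions(529.2973)
#' @export
enumerate_compositions <- function(target_mz, constraints = enum_constraints()) {
  ct <- constraints
  target_neutral <- target_mz - PROTON_MASS
  tol <- ct$ppm_tol * 1e-6 * target_mz
  lo <- target_neutral - tol
  hi <- target_neutral + tol
  mC <- .ATOMIC_MASS[["C"]]; mH <- .ATOMIC_MASS[["H"]]
  mN <- .ATOMIC_MASS[["N"]]; mO <- .ATOMIC_MASS[["O"]]
  out <- vector("list", 64L); k <- 0L
  c_hi <- min(ct$max_C, floor(hi / mC))
  if (c_hi >= ct$min_C) for (nc in ct$min_C:c_hi) {
    rem_c <- hi - nc * mC
    n_hi <- min(ct$max_N, floor(rem_c / mN))
    if (n_hi < ct$min_N) next
    for (nn in ct$min_N:n_hi) {
      rem_n <- rem_c - nn * mN
      o_hi <- min(ct$max_O, floor(rem_n / mO))
      if (o_hi < ct$min_O) next
      for (no in ct$min_O:o_hi) {
        base <- nc * mC + nn * mN + no * mO
        h_lo <- max(ct$min_H, ceiling((lo - base) / mH))
        h_hi <- min(ct$max_H, floor((hi - base) / mH))
        if (h_hi < h_lo) next
        for (nh in h_lo:h_hi) {
          mass <- base + nh * mH
          r <- nc - nh / 2 + nn / 2 + 1
          if (ct$parity_filter && (r < 0 || abs(r - round(r)) > 1e-9)) next
          if (!ct$parity_filter && r < 0) next
          k <- k + 1L
          out[[k]] <- c(nc, nh, nn, no, mass + PROTON_MASS)
        }
      }
    }
  }
  if (k == 0L)
    return(data.frame(formula = character(), C = integer(), H = integer(),
                      N = integer(), O = integer(), theoretical_mz = numeric(),
                      delta_ppm = numeric(), rdb = numeric()))
  m <- do.call(rbind, out[seq_len(k)])
  res <- data.frame(
    formula = apply(m, 1, function(x)
      format_formula(c(C = x[1], H = x[2], N = x[3], O = x[4]))),
    C = as.integer(m[, 1]), H = as.integer(m[, 2]),
    N = as.integer(m[, 3]), O = as.integer(m[, 4]),
    theoretical_mz = m[, 5],
    delta_ppm = ppm_error(target_mz, m[, 5]),
    rdb = m[, 1] - m[, 2] / 2 + m[, 3] / 2 + 1
  )
  res <- res[order(abs(res$delta_ppm)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate master-list entries with candidate formulas
#'
#' Runs [enumerate_compositions()] on each entry of a master list and
#' returns the ranked candidates in long form.
#'
#' @param master data.frame with columns `adduct_id` and `mz`.
#' @param constraints an [enum_constraints()] object.
#' @return data.frame `adduct_id`, `observed_mz`, `formula`, `theoretical_mz`,
#'   `delta_ppm`, `rdb`, `rank`.
#' @export
annotate_master <- function(master, constraints = enum_constraints()) {
  stopifnot(all(c("adduct_id", "mz") %in% names(master)))
  rows <- lapply(seq_len(nrow(master)), function(i) {
    cand <- enumerate_compositions(master$mz[i], constraints)
    if (nrow(cand) == 0) return(NULL)
    data.frame(adduct_id = master$adduct_id[i], observed_mz = master$mz[i],
               formula = cand$formula, theoretical_mz = cand$theoretical_mz,
               delta_ppm = cand$delta_ppm, rdb = cand$rdb,
               rank = seq_len(nrow(cand)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(adduct_id = character(), observed_mz = numeric(),
                      formula = character(), theoretical_mz = numeric(),
                      delta_ppm = numeric(), rdb = numeric(), rank = integer())
  rownames(out) <- NULL
  out
}
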