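#' Build a DIA isolation-window scheme
#'
#' Contiguous, non-overlapping half-open windows `[lo, lo+width)`, ...,
#' `[hi-width, hi)`. The acquisition used here divides 195--355 m/z into 16
#' windows and 347--607 m/z into 26 windows, both 10 m/z wide.
#'
#' @param lo,hi precursor range limits, m/z.
#' @param width isolation window width, m/z (default 10).
#' @return object of class `dia_scheme` with fields `precursor_lo`,
#'   `precursor_hi`, `window_width`, `n_windows`, `centers`.
#' @examples
#' build_dia_scheme(195, 355)  # 16 windows
#' build_dia_scheme(347, 607)  # 26 windows
#' @export
build_dia_scheme <- function(lo, hi, width = 10) {
  stopifnot(hi > lo, width > 0)
  n <- (hi - lo) / width
  if (abs(n - round(n)) > 1e-9)
    stop("precursor range (", lo, ", ", hi, ") is not divisible by width ", width)
  n <- as.integer(round(n))
  structure(list(
    precursor_lo = lo, precursor_hi = hi, window_width = width,
    n_windows = n, centers = lo + width * (seq_len(n) - 0.5)
  ), class = "dia_scheme")
}

#' @export
print.dia_scheme <- function(x, ...) {
  cat(sprintf("DIA scheme: %d windows of %g m/z covering [%g, %g)\n",
              x$n_windows, x$window_width, x$precursor_lo, x$precursor_hi))
  invisible(x)
}

#' Map an m/z to its DIA window
#'
#' Half-open convention: a boundary m/z belongs to the upper window.
#' Indices are 1-based (window 1 starts at `precursor_lo`).
#'
#' @param scheme a [build_dia_scheme()] object.
#' @param mz m/z value(s) in `[precursor_lo, precursor_hi)`.
#' @return integer window index (vectorised).
#' @export
window_for_mz <- function(scheme, mz) {
  stopifnot(inherits(scheme, "dia_scheme"))
  if (any(mz < scheme$precursor_lo | mz >= scheme$precursor_hi))
    stop("m/z outside DIA scheme [", scheme$precursor_lo, ", ",
         scheme$precursor_hi, ")")
  as.integer(floor((mz - scheme$precursor_lo) / scheme$window_width)) + 1L
}

# Window index for an observed isolation center, NA when it matches none.
.window_for_center <- function(scheme, center, tol = 1e-6) {
  idx <- match(TRUE, abs(scheme$centers - center) < tol)
  idx
}
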