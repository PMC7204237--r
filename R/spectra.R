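#' Informative milk mid-infrared regions
#'
#' The three wavenumber intervals (cm^-1) retaining the fat-, protein- and
#' lactose-associated bands while discarding the water-saturated and O-H
#' bending portions of the mid-infrared range: 968-1577, 1720-1808 and
#' 2564-2965 cm^-1.
#'
#' @return a list of length-2 numeric vectors (closed intervals, cm^-1).
#' @export
milk_info_regions <- function() {
  list(c(968, 1577), c(1720, 1808), c(2564, 2965))
}

#' Transmittance to absorbance
#'
#' `A = log10(1 / T)`, the decadic absorbance convention of mid-infrared
#' milk analysis.
#'
#' @param t transmittance vector or matrix (rows = spectra), values in (0, 1].
#' @return absorbance of the same shape, nonnegative.
#' @export
to_absorbance <- function(t) {
  if (!is.numeric(t)) stop("transmittance must be numeric", call. = FALSE)
  bad <- which(!is.finite(t) | t <= 0 | t > 1)
  if (length(bad) > 0L)
    stop(sprintf("transmittance outside (0, 1] at channel index %d (value %g)",
                 bad[1L], t[bad[1L]]), call. = FALSE)
  log10(1 / t)
}

#' Absorbance to transmittance
#'
#' Inverse of [to_absorbance()]: `T = 10^(-A)`, clipped into (0, 1].
#'
#' @param a absorbance vector or matrix.
#' @return transmittance of the same shape.
#' @export
to_transmittance <- function(a) {
  if (!is.numeric(a)) stop("absorbance must be numeric", call. = FALSE)
  pmin(10^(-a), 1)
}

check_regions <- function(regions) {
  if (!is.list(regions) || length(regions) == 0L)
    stop("regions must be a nonempty list of c(lower, upper) intervals", call. = FALSE)
  m <- t(vapply(regions, function(r) {
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stop("each region must be a finite interval with lower <= upper", call. = FALSE)
    r
  }, numeric(2)))
  o <- order(m[, 1])
  m <- m[o, , drop = FALSE]
  if (nrow(m) > 1L && any(m[-1L, 1] <= m[-nrow(m), 2]))
    stop("regions must be non-overlapping", call. = FALSE)
  m
}

#' Restrict spectra to wavenumber regions
#'
#' Keeps exactly the channels whose wavenumber lies in any of the closed
#' intervals, preserving channel order. Idempotent.
#'
#' @param grid strictly increasing wavenumber vector (cm^-1).
#' @param spectrum numeric vector aligned to `grid`, or a matrix with one
#'   spectrum per row and `length(grid)` columns.
#' @param regions list of closed intervals `c(lower, upper)` in cm^-1;
#'   default [milk_info_regions()].
#' @return list with elements `grid` (retained wavenumbers) and `spectrum`
#'   (retained channels, same shape convention as the input).
#' @export
select_regions <- function(grid, spectrum, regions = milk_info_regions()) {
  check_grid(grid)
  m <- check_regions(regions)
  keep <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(m)))
    keep <- keep | (grid >= m[i, 1] & grid <= m[i, 2])
  if (!any(keep)) stop("no channels retained", call. = FALSE)
  spec <- if (is.matrix(spectrum)) {
    if (ncol(spectrum) != length(grid))
      stop("spectrum matrix must have one column per grid channel", call. = FALSE)
    spectrum[, keep, drop = FALSE]
  } else {
    if (length(spectrum) != length(grid))
      stop("spectrum length must equal grid length", call. = FALSE)
    spectrum[keep]
  }
  list(grid = grid[keep], spectrum = spec)
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 1L || any(!is.finite(grid)) ||
      any(grid <= 0))
    stop("wavenumber grid must be positive and finite", call. = FALSE)
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop("wavenumber grid must be strictly increasing", call. = FALSE)
  invisible(grid)
}

#' Gap-difference derivative pre-treatment
#'
#' Finite gap differences of order 1 or 2 along the wavenumber axis, the
#' plain discrete analogue of first/second derivative pre-treatments. The
#' output is shorter than the input by `order * gap` channels. Off by
#' default in the modelling pipeline (derivatives brought no improvement on
#' raw milk spectra in this problem), but available via the run
#' configuration.
#'
#' @param spectrum numeric vector, or matrix with spectra in rows.
#' @param order derivative order, 1 or 2.
#' @param gap channel gap for the difference (>= 1).
#' @return differenced spectrum (vector or matrix).
#' @export
apply_derivative <- function(spectrum, order = 1L, gap = 1L) {
  if (!order %in% c(1L, 2L)) stop("derivative order must be 1 or 2", call. = FALSE)
  if (gap < 1L) stop("gap must be >= 1", call. = FALSE)
  len <- if (is.matrix(spectrum)) ncol(spectrum) else length(spectrum)
  if (len <= order * gap)
    stop("spectrum too short for the requested derivative", call. = FALSE)
  if (is.matrix(spectrum))
    t(apply(spectrum, 1L, function(x) diff(x, lag = gap, differences = order)))
  else diff(spectrum, lag = gap, differences = order)
}

combine_check <- function(a_am, a_pm) {
  if (!is.numeric(a_am) || !is.numeric(a_pm) || length(a_am) != length(a_pm))
    stop("AM and PM spectra must be numeric vectors on the same grid", call. = FALSE)
}

#' Fuse AM and PM absorbance spectra (scheme M1)
#'
#' Plain average of the morning and afternoon absorbance spectra; milk
#' yield is not used, so the fused spectrum carries milk composition
#' (energy density) only.
#'
#' @param a_am,a_pm absorbance vectors on the same grid.
#' @return fused spectrum `(a_am + a_pm) / 2`.
#' @export
combine_m1 <- function(a_am, a_pm) {
  combine_check(a_am, a_pm)
  (a_am + a_pm) / 2
}

#' Fuse AM and PM absorbance spectra with daily yield (scheme M2)
#'
#' Average spectrum multiplied by the daily milk yield, so the fused
#' spectrum scales with the quantity of milk produced:
#' `((a_am + a_pm)/2) * (y_am + y_pm)`.
#'
#' @param a_am,a_pm absorbance vectors on the same grid.
#' @param y_am,y_pm session milk yields in L (>= 0).
#' @return fused spectrum.
#' @export
combine_m2 <- function(a_am, a_pm, y_am, y_pm) {
  combine_check(a_am, a_pm)
  check_yields(y_am, y_pm)
  ((a_am + a_pm) / 2) * (y_am + y_pm)
}

#' Yield-weighted fusion of AM and PM absorbance spectra (scheme M3)
#'
#' Each session spectrum is multiplied by its own session yield and the two
#' products averaged: `(a_am * y_am + a_pm * y_pm) / 2`. The divisor is 2
#' (plain average of the yield-multiplied spectra), not the total yield, so
#' the fused spectrum retains yield magnitude; set `divisor = "total_yield"`
#' for the normalized weighted mean instead.
#'
#' @param a_am,a_pm absorbance vectors on the same grid.
#' @param y_am,y_pm session milk yields in L (>= 0).
#' @param divisor `"two"` (default) or `"total_yield"`.
#' @return fused spectrum.
#' @export
combine_m3 <- function(a_am, a_pm, y_am, y_pm, divisor = c("two", "total_yield")) {
  combine_check(a_am, a_pm)
  check_yields(y_am, y_pm)
  divisor <- match.arg(divisor)
  num <- a_am * y_am + a_pm * y_pm
  if (divisor == "two") num / 2
  else {
    if (y_am + y_pm <= 0) stop("total yield must be positive for divisor 'total_yield'",
                               call. = FALSE)
    num / (y_am + y_pm)
  }
}

check_yields <- function(y_am, y_pm) {
  if (!is.numeric(y_am) || !is.numeric(y_pm) || length(y_am) != 1L ||
      length(y_pm) != 1L || !is.finite(y_am) || !is.finite(y_pm) ||
      y_am < 0 || y_pm < 0)
    stop("session yields must be single nonnegative numbers (L)", call. = FALSE)
}
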