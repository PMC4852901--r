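#' Spectral chlorophyll-a calibration
#'
#' Linear calibration mapping the 650-700 nm chord-subtracted absorbance
#' peak area (nm x absorbance units) to sedimentary chlorophyll-a
#' (including diagenetic products), mg/g dry weight.  The default slope 1
#' and intercept 0 are placeholders: calibrations are instrument- and
#' study-specific and must be supplied for results in physical units.
#'
#' @param slope mg/g per nm-AU of peak area (> 0).
#' @param intercept mg/g.
#' @param detection_limit Reporting limit, mg/g dry weight (default
#'   0.01); inferred values below it are censored upward to the limit.
#' @return Object of class `chla_calibration`.
#' @export
chla_calibration <- function(slope = 1, intercept = 0, detection_limit = 0.01) {
  check_positive(slope, "slope")
  if (detection_limit < 0) stop_invalid("detection_limit must be >= 0")
  structure(list(slope = slope, intercept = intercept,
                 detection_limit = detection_limit),
            class = "chla_calibration")
}

#' Absorbance from reflectance
#'
#' \eqn{A(\lambda) = \log_{10}(1/R(\lambda))}.
#'
#' @param spectrum Data frame with `wavelength_nm` (strictly increasing)
#'   and `reflectance` in (0, 1].
#' @return Data frame `wavelength_nm`, `absorbance`.
#' @export
absorbance_from_reflectance <- function(spectrum) {
  wl <- spectrum$wavelength_nm
  r <- spectrum$reflectance
  if (any(diff(wl) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(r <= 0)) stop("reflectance must be > 0 (absorbance undefined)")
  data.frame(wavelength_nm = wl, absorbance = log10(1 / r))
}

#' Chord-subtracted absorbance peak area, 650-700 nm
#'
#' The baseline is the straight chord between the absorbance at 650 and
#' at 700 nm (linearly interpolated if those wavelengths are not sampled
#' exactly); the area is the trapezoidal integral of the positive part of
#' (absorbance - chord) over [650, 700].  Chord subtraction makes the
#' metric invariant to any linear-in-wavelength absorbance offset.
#'
#' @param absorbance Data frame `wavelength_nm`, `absorbance` (must cover
#'   650-700 nm with at least 3 points in the band).
#' @param band Integration band, nm (default `c(650, 700)`).
#' @return Peak area, nm x absorbance units (>= 0).
#' @export
peak_area_650_700 <- function(absorbance, band = c(650, 700)) {
  wl <- absorbance$wavelength_nm
  a <- absorbance$absorbance
  if (min(wl) > band[1] || max(wl) < band[2]) {
    stop("spectrum does not cover the ", band[1], "-", band[2], " nm band")
  }
  a_lo <- stats::approx(wl, a, xout = band[1])$y
  a_hi <- stats::approx(wl, a, xout = band[2])$y
  keep <- wl > band[1] & wl < band[2]
  if (sum(keep) + 2 < 3) stop("need at least 3 points in the band")
  x <- c(band[1], wl[keep], band[2])
  y <- c(a_lo, a[keep], a_hi)
  chord <- a_lo + (a_hi - a_lo) * (x - band[1]) / diff(band)
  resid <- pmax(y - chord, 0)
  sum(diff(x) * (resid[-1] + resid[-length(resid)]) / 2)
}

#' Infer chlorophyll-a from a peak area
#'
#' Applies the linear calibration `chla = slope * area + intercept`;
#' values below the detection limit are reported at the limit with a
#' censoring flag.
#'
#' @param area Peak area(s), nm-AU, >= 0.
#' @param calibration A [chla_calibration()].
#' @return Data frame `chla_mg_g`, `censored`.
#' @export
infer_chla <- function(area, calibration = chla_calibration()) {
  if (any(area < 0)) stop("peak area must be >= 0")
  chla <- calibration$slope * area + calibration$intercept
  censored <- chla < calibration$detection_limit
  chla[censored] <- calibration$detection_limit
  data.frame(chla_mg_g = chla, censored = censored)
}

#' Chlorophyll-a from a reflectance spectrum
#'
#' Convenience composition: reflectance to absorbance, 650-700 nm
#' chord-subtracted peak area, linear calibration with censoring.
#'
#' @inheritParams absorbance_from_reflectance
#' @inheritParams infer_chla
#' @return One-row data frame `chla_mg_g`, `censored`, `peak_area`.
#' @export
chla_from_spectrum <- function(spectrum, calibration = chla_calibration()) {
  area <- peak_area_650_700(absorbance_from_reflectance(spectrum))
  cbind(infer_chla(area, calibration), peak_area = area)
}

#' @export
print.chla_calibration <- function(x, ...) {
  cat("chl-a calibration: chla =", x$slope, "* area +", x$intercept,
      "mg/g (detection limit", x$detection_limit, "mg/g)\n")
  invisible(x)
}
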