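# Spectral fluence-rate correction between treatment wavelengths.
#
# When the treatment laser changes wavelength (e.g. 652 -> 670 nm) the
# photosensitizer absorbs a different fraction of the delivered light; to
# keep the absorbed dose rate matched, the new laser's fluence rate is
# multiplied by the ratio of absorption-weighted mean absorbances of the
# two laser lines.

#' Construct a spectral curve
#'
#' @param wavelengths nm, strictly increasing (>= 2 points).
#' @param values non-negative emission density or absorbance per nm.
#' @return a `spectral_curve` list.
#' @export
spectral_curve <- function(wavelengths, values) {
  if (length(wavelengths) < 2 || length(wavelengths) != length(values))
    stopf("spectrum needs >= 2 matched (wavelength, value) points")
  if (any(diff(wavelengths) <= 0))
    stopf("wavelengths must be strictly increasing")
  if (any(!is.finite(values)) || any(values < 0))
    stopf("spectrum values must be finite and non-negative")
  structure(list(wavelengths = as.numeric(wavelengths),
                 values = as.numeric(values)), class = "spectral_curve")
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Fluence-rate correction factor between two laser lines
#'
#' The multiplier to apply to `laser_b`'s fluence rate so that its
#' absorbed dose rate in `absorber` matches `laser_a`'s:
#' `factor = <A>_a / <A>_b`, where `<A>_l` is the emission-weighted mean
#' absorbance `(int l * A) / (int l)`, integrated trapezoidally on the
#' union wavelength grid of the overlap region.
#'
#' @param laser_a,laser_b emission [spectral_curve()]s.
#' @param absorber absorbance [spectral_curve()].
#' @return dimensionless correction factor.
#' @export
fluence_correction <- function(laser_a, laser_b, absorber) {
  weighted_absorbance <- function(laser) {
    lo <- max(min(laser$wavelengths), min(absorber$wavelengths))
    hi <- min(max(laser$wavelengths), max(absorber$wavelengths))
    if (lo >= hi) stopf("laser and absorber spectra do not overlap")
    grid <- sort(unique(c(
      laser$wavelengths[laser$wavelengths >= lo & laser$wavelengths <= hi],
      absorber$wavelengths[absorber$wavelengths >= lo &
                             absorber$wavelengths <= hi],
      lo, hi)))
    lv <- approx(laser$wavelengths, laser$values, xout = grid)$y
    av <- approx(absorber$wavelengths, absorber$values, xout = grid)$y
    denom <- trapz(grid, lv)
    if (denom <= 0) stopf("laser deposits no power in the overlap region")
    trapz(grid, lv * av) / denom
  }
  wa <- weighted_absorbance(laser_a)
  wb <- weighted_absorbance(laser_b)
  if (wb <= 0) stopf("laser_b absorbs no power in the absorber band")
  wa / wb
}
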