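# Ratiometric pH imaging from hyperspectral cubes.
#
# pH is computed from the ratio of the 570 and 650 nm emission bands of a
# ratiometric dye. Both bands are background-subtracted (histogram mode
# per band), low-signal pixels are masked, and the ratio is inverted
# through a calibration curve: either the parametric two-state form
# pH = pKa + log10(span_factor * (r_acid - R)/(R - r_base)), or monotone
# interpolation of a tabulated (ratio, pH) curve.

#' Extract one band plane from a hyperspectral cube
#'
#' @param cube a [hyperspectral_cube()].
#' @param center band-centre wavelength, nm; must lie exactly on the
#'   cube's band axis.
#' @return the 2-D intensity plane.
#' @export
extract_band <- function(cube, center) {
  k <- which(abs(cube$band_centers - center) < 1e-9)
  if (length(k) != 1L)
    stopf("band %g nm is not on the cube's band axis", center)
  cube$planes[, , k]
}

#' Band-ratio image with low-signal mask
#'
#' Computes `band570 / band650` after per-band modal background
#' subtraction. Pixels whose denominator band falls at or below
#' `low_signal_factor` times the band's background noise scale (a robust
#' MAD estimate) are masked.
#'
#' @param cube a [hyperspectral_cube()].
#' @param low_signal_factor dimensionless masking threshold.
#' @param bands numerator and denominator band centres, nm.
#' @return list with `ratio` (matrix, `NA` where masked) and `mask`
#'   (logical matrix, `TRUE` = masked out).
#' @export
ratio_image <- function(cube, low_signal_factor = 5,
                        bands = c(570, 650)) {
  num_raw <- extract_band(cube, bands[[1]])
  den_raw <- extract_band(cube, bands[[2]])
  num <- subtract_background(num_raw)
  den <- subtract_background(den_raw)
  # masking threshold: the coarse histogram mode can be off by up to half
  # a bin, so refine the background centre and noise scale from the
  # background-dominated pixels near the mode (bright foreground pixels,
  # which may dominate a tight field of view, are excluded)
  bg_mode <- estimate_background(den_raw)
  binw <- diff(range(den_raw)) / 256
  lower <- den_raw[den_raw <= bg_mode + 3 * binw]
  center <- median(lower)
  noise_scale <- 1.4826 * median(abs(lower - center))
  mask <- (den_raw - center) <= low_signal_factor * noise_scale
  ratio <- num / den
  ratio[mask] <- NA_real_
  list(ratio = ratio, mask = mask)
}

#' Construct a ratio-to-pH calibration curve
#'
#' @param kind `"parametric"` or `"tabulated"`.
#' @param r_acid,r_base ratio endpoints at the fully acid / fully base
#'   limits (parametric).
#' @param pka dye pKa (parametric).
#' @param span_factor denominator-band correction (acid/base emission at
#'   the denominator band; parametric).
#' @param table data.frame with columns `ratio` and `ph`, strictly
#'   monotone in ratio (tabulated).
#' @return a `calibration_curve` list.
#' @export
calibration_curve <- function(kind = c("parametric", "tabulated"),
                              r_acid = NULL, r_base = NULL, pka = NULL,
                              span_factor = NULL, table = NULL) {
  kind <- match.arg(kind)
  if (kind == "parametric") {
    for (v in list(r_acid, r_base, pka, span_factor))
      if (!is_scalar_num(v)) stopf("parametric calibration needs r_acid, r_base, pka, span_factor")
    if (r_acid == r_base) stopf("degenerate calibration: r_acid == r_base")
    structure(list(kind = kind, r_acid = r_acid, r_base = r_base,
                   pka = pka, span_factor = span_factor),
              class = "calibration_curve")
  } else {
    if (is.null(table) || !all(c("ratio", "ph") %in% names(table)))
      stopf("tabulated calibration needs a (ratio, ph) table")
    o <- order(table$ratio)
    table <- table[o, ]
    if (any(diff(table$ratio) <= 0) ||
        !(all(diff(table$ph) > 0) || all(diff(table$ph) < 0)))
      stopf("invalid calibration: tabulated curve must be strictly monotone")
    structure(list(kind = kind, table = table),
              class = "calibration_curve")
  }
}

#' Derive the parametric calibration implied by a dye model
#'
#' For the two-state emission model the band ratio at acid fraction
#' `alpha` is `(alpha a1 + (1-alpha) b1) / (alpha a2 + (1-alpha) b2)`;
#' the implied calibration endpoints are `r_acid = a1/a2`,
#' `r_base = b1/b2` and the denominator-band span factor is `a2/b2`.
#'
#' @param snarf a [snarf_model()].
#' @param bands numerator and denominator band centres, nm.
#' @return a parametric [calibration_curve()].
#' @export
derive_calibration <- function(snarf, bands = c(570, 650)) {
  k1 <- which(abs(snarf$band_centers - bands[[1]]) < 1e-9)
  k2 <- which(abs(snarf$band_centers - bands[[2]]) < 1e-9)
  if (!length(k1) || !length(k2))
    stopf("bands must lie on the dye model's band axis")
  a1 <- snarf$acid_spectrum[[k1]]; a2 <- snarf$acid_spectrum[[k2]]
  b1 <- snarf$base_spectrum[[k1]]; b2 <- snarf$base_spectrum[[k2]]
  calibration_curve("parametric", r_acid = a1 / a2, r_base = b1 / b2,
                    pka = snarf$pka, span_factor = a2 / b2)
}

#' Convert a ratio image to a pH image
#'
#' Parametric curves use
#' `pH = pKa + log10(span_factor * (r_acid - R) / (R - r_base))`; ratios
#' at or beyond the endpoints are masked as out-of-range. Tabulated
#' curves use monotone linear interpolation, masking outside the table's
#' ratio range. Defined pixels are clamped to the physically meaningful
#' pH window `[4, 9]`.
#'
#' @param ratio list from [ratio_image()] (or a bare ratio matrix).
#' @param cal a [calibration_curve()].
#' @return a `ph_image` list with `ph` (matrix, `NA` where undefined),
#'   `ratio`, and `mask_reason` (`"ok"`, `"low_signal"`,
#'   `"out_of_range"`).
#' @export
ratio_to_ph <- function(ratio, cal) {
  if (is.matrix(ratio)) ratio <- list(ratio = ratio,
                                      mask = is.na(ratio))
  R <- ratio$ratio
  reason <- matrix("ok", nrow(R), ncol(R))
  reason[ratio$mask] <- "low_signal"
  ph <- matrix(NA_real_, nrow(R), ncol(R))
  ok <- !ratio$mask & !is.na(R)
  if (cal$kind == "parametric") {
    lo <- min(cal$r_acid, cal$r_base)
    hi <- max(cal$r_acid, cal$r_base)
    inside <- ok & R > lo & R < hi
    reason[ok & !inside] <- "out_of_range"
    ph[inside] <- cal$pka +
      log10(cal$span_factor * (cal$r_acid - R[inside]) /
              (R[inside] - cal$r_base))
  } else {
    lo <- min(cal$table$ratio); hi <- max(cal$table$ratio)
    inside <- ok & R >= lo & R <= hi
    reason[ok & !inside] <- "out_of_range"
    ph[inside] <- approx(cal$table$ratio, cal$table$ph,
                         xout = R[inside])$y
  }
  out_window <- !is.na(ph) & (ph < 4 | ph > 9)
  reason[out_window] <- "out_of_range"
  ph[out_window] <- NA_real_
  structure(list(ph = ph, ratio = R, mask_reason = reason),
            class = "ph_image")
}

#' Radial pH profile of a single nodule
#'
#' Shell medians of defined pH over 10 equal-width normalized-radius
#' bins, plus core (`r < 0.33`) and edge (`r > 0.8`) medians. Radius is
#' normalized by the mask's equivalent radius.
#'
#' @param ph_img a `ph_image` from [ratio_to_ph()].
#' @param nodule_mask logical matrix, single nodule.
#' @param pixel_size um per pixel.
#' @param n_bins number of radial shells.
#' @return list with `profile` (data.frame `r_mid`, `median_ph`, `n`),
#'   `core_median`, `edge_median`.
#' @export
radial_ph_profile <- function(ph_img, nodule_mask, pixel_size = 2,
                              n_bins = 10L) {
  if (!any(nodule_mask)) stopf("empty nodule mask")
  idx <- which(nodule_mask)
  rows <- ((idx - 1L) %% nrow(nodule_mask)) + 1L
  cols <- ((idx - 1L) %/% nrow(nodule_mask)) + 1L
  cy <- mean(rows); cx <- mean(cols)
  r_eq <- sqrt(length(idx) / pi)
  rn <- sqrt((rows - cy)^2 + (cols - cx)^2) / r_eq
  ph <- ph_img$ph[idx]
  bins <- pmin(findInterval(rn, seq(0, 1, length.out = n_bins + 1L),
                            rightmost.closed = TRUE), n_bins)
  bins[bins < 1L] <- 1L
  med <- vapply(seq_len(n_bins), function(b) {
    v <- ph[bins == b & !is.na(ph)]
    if (length(v)) median(v) else NA_real_
  }, 0)
  n <- vapply(seq_len(n_bins), function(b)
    sum(bins == b & !is.na(ph)), 0L)
  profile <- data.frame(
    r_mid = (seq_len(n_bins) - 0.5) / n_bins, median_ph = med, n = n)
  core <- ph[rn < 0.33 & !is.na(ph)]
  edge <- ph[rn > 0.8 & !is.na(ph)]
  list(profile = profile,
       core_median = if (length(core)) median(core) else NA_real_,
       edge_median = if (length(edge)) median(edge) else NA_real_)
}
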