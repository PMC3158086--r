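# Radial pH profiles and hyperspectral SNARF rendering.
#
# Nodule interiors are acidic: anaerobic glycolysis in the hypoxic core
# drops the pH below 6 while the periphery stays near-neutral. The
# generator states this as a monotone radial profile
# pH(r) = ph_core + (ph_edge - ph_core) * r^exponent. The ratiometric dye
# is modelled as a two-state (acid/base) emitter with Henderson-
# Hasselbalch mixing: the acid fraction at a pixel is
# alpha = 1 / (1 + 10^(pH - pKa)).

#' Construct a radial pH profile
#'
#' @param ph_core pH at the nodule centre.
#' @param ph_edge pH at the nodule boundary.
#' @param exponent radial shape exponent (> 0).
#' @return a `ph_profile` list.
#' @export
ph_profile <- function(ph_core = 5.6, ph_edge = 7.2, exponent = 2) {
  if (!(ph_core >= 4 && ph_core <= ph_edge && ph_edge <= 8))
    stopf("need 4 <= ph_core <= ph_edge <= 8")
  if (exponent <= 0) stopf("exponent must be > 0")
  structure(list(ph_core = ph_core, ph_edge = ph_edge,
                 exponent = exponent), class = "ph_profile")
}

#' pH at normalized radius
#' @param ph a [ph_profile()].
#' @param r normalized radius in `[0, 1]` (vectorized).
#' @export
ph_at <- function(ph, r) {
  ph$ph_core + (ph$ph_edge - ph$ph_core) * pmin(pmax(r, 0), 1)^ph$exponent
}

#' Standard hyperspectral band axis
#'
#' Band centres 550-800 nm at 5 nm spacing (51 planes), 10 nm bandwidth,
#' matching the acquisition the pipeline expects.
#' @export
standard_band_centers <- function() seq(550, 800, by = 5)

#' Construct a two-state ratiometric dye emission model
#'
#' Acid and base emission spectra are Gaussians (unit peak) centred near
#' 580 and 640 nm, so the 570/650 nm band ratio is strictly monotone in
#' pH around the pKa.
#'
#' @param pka dye pKa (manufacturer's nominal 6.4 for SNARF-4F).
#' @param acid_peak,base_peak emission peak wavelengths, nm.
#' @param sigma Gaussian width, nm.
#' @param brightness emission intensity scale per pixel.
#' @param band_centers band axis, nm.
#' @return a `snarf_model` list with per-band weights `acid_spectrum`,
#'   `base_spectrum`.
#' @export
snarf_model <- function(pka = 6.4, acid_peak = 580, base_peak = 640,
                        sigma = 30, brightness = 2000,
                        band_centers = standard_band_centers()) {
  acid <- exp(-(band_centers - acid_peak)^2 / (2 * sigma^2))
  base <- exp(-(band_centers - base_peak)^2 / (2 * sigma^2))
  structure(list(pka = pka, band_centers = band_centers,
                 acid_spectrum = acid / max(acid),
                 base_spectrum = base / max(base),
                 brightness = brightness), class = "snarf_model")
}

#' Construct a hyperspectral cube
#'
#' @param planes 3-D array `[y, x, band]`.
#' @param band_centers band-centre wavelengths, nm (strictly increasing,
#'   uniform 5 nm spacing).
#' @param bandwidth band width, nm.
#' @param pixel_size um per pixel.
#' @return a `hyperspectral_cube` list.
#' @export
hyperspectral_cube <- function(planes, band_centers = standard_band_centers(),
                               bandwidth = 10, pixel_size = 2) {
  if (length(dim(planes)) != 3L || dim(planes)[[3]] != length(band_centers))
    stopf("planes must be a [y, x, band] array matching band_centers")
  d <- diff(band_centers)
  if (any(d <= 0) || max(abs(d - d[[1]])) > 1e-9)
    stopf("band_centers must be strictly increasing with uniform spacing")
  structure(list(planes = planes, band_centers = band_centers,
                 bandwidth = bandwidth, pixel_size = pixel_size),
            class = "hyperspectral_cube")
}

#' Render a hyperspectral cube of a single dye-loaded nodule
#'
#' Per-pixel spectrum: `brightness * (alpha * acid + (1 - alpha) * base)`
#' with `alpha = 1/(1 + 10^(pH(r) - pKa))`; pixels outside the nodule hold
#' background only. Camera noise is applied per plane.
#'
#' @param spec a [nodule_spec()].
#' @param ph a [ph_profile()].
#' @param snarf a [snarf_model()].
#' @param noise a [noise_model()].
#' @param pixel_size um per pixel.
#' @param seed integer seed.
#' @param field_size image extent, um; defaults to a tight box.
#' @return list with `cube` (a [hyperspectral_cube()]) and `mask`
#'   (ground-truth nodule mask).
#' @export
render_hyperspectral <- function(spec, ph = ph_profile(),
                                 snarf = snarf_model(),
                                 noise = noise_model(), pixel_size = 2,
                                 seed = 1L, field_size = NULL) {
  r_out <- spec$diameter / 2
  if (is.null(field_size)) {
    pad <- 10 * pixel_size
    field_size <- c(spec$diameter + 2 * pad, spec$diameter + 2 * pad)
    spec$center_xy <- field_size / 2
  }
  dims <- field_grid_dims(list(field_size = field_size), pixel_size)
  ras <- rasterize_nodule(spec, dims, pixel_size)
  mask <- matrix(FALSE, dims[["ny"]], dims[["nx"]])
  mask[ras$idx] <- TRUE
  alpha <- 1 / (1 + 10^(ph_at(ph, ras$radius / r_out) - snarf$pka))
  nb <- length(snarf$band_centers)
  planes <- array(0, c(dims[["ny"]], dims[["nx"]], nb))
  with_seed(seed, {
    for (k in seq_len(nb)) {
      plane <- matrix(0, dims[["ny"]], dims[["nx"]])
      plane[ras$idx] <- snarf$brightness *
        (alpha * snarf$acid_spectrum[[k]] +
           (1 - alpha) * snarf$base_spectrum[[k]])
      planes[, , k] <- apply_noise(plane, noise)
    }
  })
  list(cube = hyperspectral_cube(planes, snarf$band_centers,
                                 pixel_size = pixel_size),
       mask = mask)
}
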