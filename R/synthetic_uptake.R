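# Photosensitizer uptake: diffusion into a sphere and uptake-channel
# rendering.
#
# Two uptake archetypes are modelled. Periphery-localizing agents (BPD,
# carboplatin) stay near the nodule surface: intensity decays
# exponentially with depth from the boundary on a characteristic
# penetration length (~125 um for BPD in these cultures). The
# core-concentrating agent (EtNBS, a small cation) diffuses in rapidly
# and partitions along the acidic pH gradient, accumulating in the core;
# its kinetics follow classical diffusion into a sphere with the surface
# held at the bath concentration (nodules fill within ~5 h).

#' Concentration fraction for diffusion into a sphere
#'
#' Truncated classical series solution for diffusion into a sphere of
#' unit normalized radius with the surface held at concentration 1 and
#' zero initial interior concentration:
#' `C(r, t)/C_s = 1 + (2/(pi r)) * sum_n ((-1)^n / n) sin(n pi r)
#' exp(-n^2 pi^2 t / tau)`, with `tau = R^2 / D` the characteristic
#' diffusion time.
#'
#' @param r normalized radius in `[0, 1]` (vectorized).
#' @param t time, same units as `tau` (>= 0).
#' @param tau characteristic diffusion time `R^2/D` (> 0).
#' @param tol series truncation tolerance on the term magnitude.
#' @param n_max maximum number of series terms.
#' @return concentration fraction(s) in `[0, 1]`.
#' @export
sphere_diffusion_concentration <- function(r, t, tau, tol = 1e-10,
                                           n_max = 10000L) {
  if (any(r < 0) || any(r > 1)) stopf("r must be in [0, 1]")
  if (t < 0) stopf("t must be >= 0")
  if (tau <= 0) stopf("tau must be > 0")
  if (t == 0) return(ifelse(r < 1, 0, 1))
  a <- pi^2 * t / tau
  # terms decay like exp(-n^2 a)/n; stop once the envelope is below tol
  n_needed <- ceiling(sqrt(max(-log(tol), 1) / a))
  if (n_needed > n_max)
    stopf("series truncation tolerance not reachable within %d terms (t/tau too small)",
          n_max)
  n <- seq_len(max(n_needed, 3L))
  en <- exp(-n^2 * a)
  out <- vapply(r, function(ri) {
    if (ri < 1e-9) {
      1 + 2 * sum((-1)^n * en)  # r -> 0 limit
    } else {
      1 + (2 / (pi * ri)) * sum(((-1)^n / n) * sin(n * pi * ri) * en)
    }
  }, 0)
  pmin(pmax(out, 0), 1)
}

#' Time for the nodule centre to reach 90% of surface concentration
#'
#' @param diameter nodule diameter, um.
#' @param D diffusivity, um^2 per time unit.
#' @param level fill level (default 0.9).
#' @return fill time in the time units of `1/D`.
#' @export
nodule_fill_time <- function(diameter, D, level = 0.9) {
  tau <- (diameter / 2)^2 / D
  f <- function(t) sphere_diffusion_concentration(0, t, tau) - level
  uniroot(f, c(tau * 1e-4, tau * 10), tol = tau * 1e-8)$root
}

#' Render a photosensitizer uptake image of a single nodule
#'
#' @param spec a [nodule_spec()].
#' @param profile `"peripheral_decay"` (intensity
#'   `exp(-depth/decay_length)`) or `"core_concentrating"`
#'   (diffusion-filling concentration times the pH-partitioning weight
#'   `10^(s * (ph_edge - pH(r)))`, normalized to unit surface intensity at
#'   equilibrium).
#' @param params named list: `decay_length` (um) for peripheral decay;
#'   `tau` and `s` (trapping strength, >= 0) plus optionally `ph` (a
#'   [ph_profile()]) for core concentration.
#' @param t incubation time (same units as `tau`); only used by the
#'   core-concentrating profile.
#' @param noise a [noise_model()].
#' @param pixel_size um per pixel.
#' @param seed integer seed for the camera noise.
#' @param brightness peak intensity scale.
#' @param field_size image extent in um; defaults to a tight box around
#'   the nodule.
#' @return list with `image` (a [culture_image()] with channel `uptake`)
#'   and `mask` (logical ground-truth nodule mask).
#' @export
render_uptake <- function(spec, profile = c("peripheral_decay",
                                            "core_concentrating"),
                          params = list(), t = Inf,
                          noise = noise_free(), pixel_size = 2, seed = 1L,
                          brightness = 3000, field_size = NULL) {
  profile <- match.arg(profile)
  r_out <- spec$diameter / 2
  if (is.null(field_size)) {
    pad <- 10 * pixel_size
    field_size <- c(spec$diameter + 2 * pad, spec$diameter + 2 * pad)
    spec$center_xy <- field_size / 2
  }
  field <- list(field_size = field_size)
  dims <- field_grid_dims(field, pixel_size)
  ras <- rasterize_nodule(spec, dims, pixel_size)
  img <- matrix(0, dims[["ny"]], dims[["nx"]])
  mask <- matrix(FALSE, dims[["ny"]], dims[["nx"]])
  mask[ras$idx] <- TRUE
  if (profile == "peripheral_decay") {
    L <- params$decay_length %||% 125
    img[ras$idx] <- exp(-(r_out - ras$radius) / L)
  } else {
    tau <- params$tau %||% 1
    s <- params$s %||% 0
    if (s < 0) stopf("trapping strength s must be >= 0")
    ph <- params$ph %||% ph_profile()
    rn <- ras$radius / r_out
    conc <- if (is.infinite(t)) rep(1, length(rn)) else
      sphere_diffusion_concentration(rn, t, tau)
    weight <- 10^(s * (ph$ph_edge - ph_at(ph, rn)))
    # surface weight at equilibrium is 1 by construction (pH(1) = ph_edge)
    img[ras$idx] <- conc * weight
  }
  out <- with_seed(seed, apply_noise(img * brightness, noise))
  list(image = culture_image(list(uptake = out), pixel_size,
                             noise$background_level),
       mask = mask)
}
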