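# Synthetic nodule-culture generator: field geometry and live/dead
# rendering.
#
# The generator states a world the analysis pipeline can be tested
# against: circular equatorial sections of avascular nodules (50-600 um
# across in the source cultures), each with an acidic/hypoxic core region
# at a fixed radius fraction, laid out without overlap in a well. Survival
# under photodynamic treatment follows a logistic-in-log-dose family with
# the irradiance dependence of a dual Type I/Type II photosensitizer: the
# periphery's effective half-kill fluence grows with irradiance (oxygen
# depletion shuts the Type II channel off), the core's does not (Type I,
# oxygen-independent), and severe hypoxia inflates both.

#' Construct a nodule specification
#'
#' @param id positive integer label.
#' @param center_xy numeric length-2, nodule centre in um.
#' @param diameter nodule diameter in um.
#' @param core_fraction radius fraction of the acidic/hypoxic core, in
#'   `[0, 1]`.
#' @param seed per-nodule integer seed.
#' @return a `nodule_spec` list.
#' @export
nodule_spec <- function(id, center_xy, diameter, core_fraction = 0.55,
                        seed = 1L) {
  if (!is_scalar_num(diameter) || diameter <= 0)
    stopf("diameter must be positive")
  if (core_fraction < 0 || core_fraction > 1)
    stopf("core_fraction must be in [0, 1]")
  structure(list(id = as.integer(id), center_xy = as.numeric(center_xy),
                 diameter = as.numeric(diameter),
                 core_fraction = as.numeric(core_fraction),
                 seed = as.integer(seed)),
            class = "nodule_spec")
}

#' Sample a non-overlapping field of nodules
#'
#' Diameters are drawn log-uniformly over `diameter_range` (sizes span a
#' log axis in these cultures); centres uniformly, rejecting placements
#' that overlap an existing nodule or fall outside the field.
#'
#' @param n number of nodules (>= 0).
#' @param diameter_range length-2 numeric, min/max diameter in um.
#' @param field_size length-2 numeric, field extent in um.
#' @param seed integer seed; identical calls give identical fields.
#' @param core_fraction core radius fraction given to every spec.
#' @param min_gap minimum surface-to-surface separation in um.
#' @param max_attempts rejection-sampling budget per nodule.
#' @return list of [nodule_spec()] objects.
#' @export
sample_nodule_field <- function(n, diameter_range = c(50, 600),
                                field_size = c(5000, 5000), seed = 1L,
                                core_fraction = 0.55, min_gap = 4,
                                max_attempts = 1000L) {
  if (n < 0) stopf("n must be >= 0")
  if (n == 0L) return(list())
  if (diameter_range[[2]] > min(field_size))
    stopf("diameter_range must fit inside the field")
  with_seed(seed, {
    # draw all diameters up front so the log-uniform size marginal is not
    # skewed by packing rejections, then place largest-first with
    # position-only retries
    diam <- exp(runif(n, log(diameter_range[[1]]), log(diameter_range[[2]])))
    ord <- order(diam, decreasing = TRUE)
    cx <- numeric(0); cy <- numeric(0); rad <- numeric(0)
    specs <- vector("list", n)
    for (i in ord) {
      r <- diam[[i]] / 2
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        x <- runif(1, r, field_size[[1]] - r)
        y <- runif(1, r, field_size[[2]] - r)
        ok <- !length(cx) ||
          all(sqrt((cx - x)^2 + (cy - y)^2) > rad + r + min_gap)
        if (ok) {
          cx <- c(cx, x); cy <- c(cy, y); rad <- c(rad, r)
          specs[[i]] <- nodule_spec(i, c(x, y), diam[[i]], core_fraction,
                                    seed = derive_seed(seed, i))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stopf("infeasible packing: could not place a %.0f um nodule in %d attempts",
              diam[[i]], max_attempts)
    }
    specs
  })
}

#' Construct a culture field
#'
#' @param nodules list of [nodule_spec()] objects.
#' @param condition `"NT"` (no treatment), `"LO"` (light only),
#'   `"EO"` (photosensitizer only, no light) or `"treated"`.
#' @param dose fluence in J/cm^2 (ignored for control conditions).
#' @param irradiance irradiance in mW/cm^2.
#' @param atmosphere `"normoxic"` or `"hypoxic"` (100% N2).
#' @param agent `"EtNBS"` (core-concentrating), `"BPD"` or
#'   `"carboplatin"` (periphery-localizing), or `"none"`.
#' @param field_size field extent in um.
#' @return a `culture_field` list.
#' @export
culture_field <- function(nodules, condition = "NT", dose = 0,
                          irradiance = 0, atmosphere = "normoxic",
                          agent = "EtNBS", field_size = c(1500, 1500)) {
  condition <- match.arg(condition, c("NT", "LO", "EO", "treated"))
  atmosphere <- match.arg(atmosphere, c("normoxic", "hypoxic"))
  agent <- match.arg(agent, c("EtNBS", "BPD", "carboplatin", "none"))
  if (dose < 0 || irradiance < 0)
    stopf("dose and irradiance must be >= 0")
  structure(list(nodules = nodules, condition = condition, dose = dose,
                 irradiance = irradiance, atmosphere = atmosphere,
                 agent = agent, field_size = as.numeric(field_size)),
            class = "culture_field")
}

#' Construct the generator's dose-response model
#'
#' Survival is logistic in log-dose, `S(D) = 1 / (1 + (D/d50_eff)^hill)`.
#' For the periphery `d50_eff` is inflated by the irradiance factor
#' `1 + (irradiance/irr_scale)^irr_hill` (Type II shut-off at high
#' irradiance); for the core it is irradiance-free (Type I) and, for the
#' core-concentrating agent, divided by the size-sensitization factor
#' `(diameter/size_ref)^size_gamma` (larger nodules have larger, more
#' acidic cores that accumulate more photosensitizer). Hypoxia multiplies
#' every effective d50 by `hypoxia_factor`.
#'
#' @param cfg a `pdt_config`, or `NULL` for the packaged default.
#' @return a `dose_response_model` list.
#' @export
dose_response_model <- function(cfg = NULL) {
  if (is.null(cfg)) cfg <- load_config()
  dr <- cfg$dose_response
  structure(list(d50 = dr$d50_J_cm2, hill = dr$hill,
                 irr_scale = dr$irr_scale_mW_cm2, irr_hill = dr$irr_hill,
                 core_efficiency = dr$core_efficiency,
                 hypoxia_factor = dr$hypoxia_factor,
                 size_ref = dr$size_ref_um %||% 200,
                 size_gamma = dr$size_gamma %||% 0,
                 penetration_depth = dr$penetration_depth_um %||% 125),
            class = "dose_response_model")
}

#' Survival probability of a nodule region under treatment
#'
#' @param model a [dose_response_model()].
#' @param dose fluence, J/cm^2 (>= 0).
#' @param irradiance irradiance, mW/cm^2 (>= 0).
#' @param region `"core"` or `"periphery"`.
#' @param atmosphere `"normoxic"` or `"hypoxic"`.
#' @param diameter optional nodule diameter in um; enables the core
#'   size-sensitization term. `NULL` (default) disables it.
#' @return survival probability in `[0, 1]`; monotone non-increasing in
#'   dose, and for the periphery monotone non-decreasing in irradiance.
#' @export
survival_probability <- function(model, dose, irradiance = 0,
                                 region = c("periphery", "core"),
                                 atmosphere = "normoxic", diameter = NULL) {
  region <- match.arg(region)
  if (any(dose < 0) || any(irradiance < 0))
    stopf("dose and irradiance must be >= 0")
  d50 <- model$d50
  if (atmosphere == "hypoxic") d50 <- d50 * model$hypoxia_factor
  if (region == "periphery") {
    d50 <- d50 * (1 + (irradiance / model$irr_scale)^model$irr_hill)
    s <- 1 / (1 + (dose / d50)^model$hill)
  } else {
    if (!is.null(diameter) && model$size_gamma > 0)
      d50 <- d50 / (diameter / model$size_ref)^model$size_gamma
    s_log <- 1 / (1 + (dose / d50)^model$hill)
    s <- 1 - model$core_efficiency * (1 - s_log)
  }
  pmin(pmax(s, 0), 1)
}

# --- rasterization ---------------------------------------------------------

field_grid_dims <- function(field, pixel_size) {
  c(ny = as.integer(ceiling(field$field_size[[2]] / pixel_size)),
    nx = as.integer(ceiling(field$field_size[[1]] / pixel_size)))
}

# pixel-centred physical coordinates (0-based indexing convention: pixel
# [i, j] is centred at ((j - 0.5) * px, (i - 0.5) * px))
pixel_centers <- function(npix, pixel_size) (seq_len(npix) - 0.5) * pixel_size

# per-nodule raster: indices into the field matrices plus geometric
# radius (um from centre) for each covered pixel
rasterize_nodule <- function(spec, dims, pixel_size) {
  r <- spec$diameter / 2
  xs <- pixel_centers(dims[["nx"]], pixel_size)
  ys <- pixel_centers(dims[["ny"]], pixel_size)
  jx <- which(abs(xs - spec$center_xy[[1]]) <= r)
  iy <- which(abs(ys - spec$center_xy[[2]]) <= r)
  if (!length(jx) || !length(iy))
    return(list(idx = integer(0), radius = numeric(0)))
  dx <- xs[jx] - spec$center_xy[[1]]
  dy <- ys[iy] - spec$center_xy[[2]]
  dist <- sqrt(outer(dy^2, dx^2, `+`))
  keep <- dist <= r
  ii <- rep(iy, times = length(jx))[keep]
  jj <- rep(jx, each = length(iy))[keep]
  list(idx = (jj - 1L) * dims[["ny"]] + ii, radius = dist[keep])
}

#' Construct a camera noise model
#'
#' Photon shot noise is Poisson on `photon_scale * signal` (rescaled back
#' to intensity units), read noise Gaussian, and a constant background
#' offset is added inside the shot-noise term (the background is itself
#' light). `photon_scale = Inf` together with `read_sigma = 0` gives a
#' noise-free render.
#'
#' @param photon_scale photons per intensity unit (larger = less noisy).
#' @param read_sigma Gaussian read-noise standard deviation, intensity
#'   units.
#' @param background_level constant background offset, intensity units.
#' @return a `noise_model` list.
#' @export
noise_model <- function(photon_scale = 10, read_sigma = 3,
                        background_level = 100) {
  if (read_sigma < 0 || background_level < 0)
    stopf("read_sigma and background_level must be >= 0")
  structure(list(photon_scale = photon_scale, read_sigma = read_sigma,
                 background_level = background_level),
            class = "noise_model")
}

#' Noise-free render switch
#' @return a [noise_model()] with no shot or read noise and zero
#'   background.
#' @export
noise_free <- function(background_level = 0) {
  noise_model(photon_scale = Inf, read_sigma = 0,
              background_level = background_level)
}

# apply the camera model to a clean signal matrix; caller provides seeded
# RNG context
apply_noise <- function(signal, noise) {
  x <- signal + noise$background_level
  if (is.finite(noise$photon_scale))
    x <- matrix(rpois(length(x), noise$photon_scale * x) /
                  noise$photon_scale, nrow = nrow(x))
  if (noise$read_sigma > 0)
    x <- x + matrix(rnorm(length(x), 0, noise$read_sigma), nrow = nrow(x))
  clip0(x)
}

#' Construct a multi-channel culture image
#'
#' @param channels named list of same-shaped non-negative matrices.
#' @param pixel_size um per pixel.
#' @param background_level nominal background offset.
#' @return a `culture_image` list.
#' @export
culture_image <- function(channels, pixel_size, background_level = 0) {
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L)
    stopf("all channels must share one geometry")
  if (pixel_size <= 0) stopf("pixel_size must be positive")
  structure(list(channels = channels, pixel_size = pixel_size,
                 background_level = background_level),
            class = "culture_image")
}

# per-pixel survival probabilities for one nodule under the field's
# treatment; radius is the geometric distance of each pixel from the
# nodule centre (um)
pixel_survival <- function(spec, radius, field, model) {
  if (field$condition != "treated" || field$agent == "none" ||
      field$dose == 0)
    return(rep(1, length(radius)))
  r_out <- spec$diameter / 2
  if (field$agent %in% c("BPD", "carboplatin")) {
    # periphery-localizing agents: kill probability decays with depth
    # from the nodule boundary on the agent's penetration length scale
    s_edge <- survival_probability(model, field$dose, field$irradiance,
                                   "periphery", field$atmosphere)
    depth <- r_out - radius
    1 - (1 - s_edge) * exp(-depth / model$penetration_depth)
  } else {
    core <- radius < spec$core_fraction * r_out
    s <- numeric(length(radius))
    s[core] <- survival_probability(model, field$dose, field$irradiance,
                                    "core", field$atmosphere,
                                    diameter = spec$diameter)
    s[!core] <- survival_probability(model, field$dose, field$irradiance,
                                     "periphery", field$atmosphere)
    s
  }
}

#' Render a live/dead image of a culture field
#'
#' Each nodule pixel is assigned live or dead by a Bernoulli draw from the
#' survival probability of its region; live pixels light the live channel,
#' dead pixels the dead channel, and the camera noise model is applied to
#' both. Ground truth (label map and per-nodule true viabilities) is
#' returned alongside the image.
#'
#' @param field a [culture_field()].
#' @param model a [dose_response_model()].
#' @param noise a [noise_model()].
#' @param pixel_size um per pixel.
#' @param seed integer seed (bit-identical output for identical inputs).
#' @param brightness per-pixel signal of a stained cell, intensity units.
#' @return list with `image` (a [culture_image()] with channels `live`,
#'   `dead`), `labels` (integer matrix, 0 = background), and `truth`
#'   (data.frame: id, centre, diameter, per-region and overall true
#'   viability before noise).
#' @export
render_livedead <- function(field, model, noise, pixel_size = 2,
                            seed = 1L, brightness = 3000) {
  dims <- field_grid_dims(field, pixel_size)
  live <- matrix(0, dims[["ny"]], dims[["nx"]])
  dead <- matrix(0, dims[["ny"]], dims[["nx"]])
  labels <- matrix(0L, dims[["ny"]], dims[["nx"]])
  truth <- vector("list", length(field$nodules))
  with_seed(seed, {
    for (k in seq_along(field$nodules)) {
      spec <- field$nodules[[k]]
      ras <- rasterize_nodule(spec, dims, pixel_size)
      if (!length(ras$idx)) next
      p <- pixel_survival(spec, ras$radius, field, model)
      alive <- runif(length(p)) < p
      live[ras$idx[alive]] <- brightness
      dead[ras$idx[!alive]] <- brightness
      labels[ras$idx] <- spec$id
      core <- ras$radius < spec$core_fraction * spec$diameter / 2
      truth[[k]] <- data.frame(
        id = spec$id, x = spec$center_xy[[1]], y = spec$center_xy[[2]],
        diameter = spec$diameter,
        viability = mean(alive),
        core_viability = if (any(core)) mean(alive[core]) else NA_real_,
        periphery_viability = if (any(!core)) mean(alive[!core]) else NA_real_,
        n_pixels = length(p))
    }
    img <- culture_image(list(live = apply_noise(live, noise),
                              dead = apply_noise(dead, noise)),
                         pixel_size, noise$background_level)
    list(image = img, labels = labels, truth = do.call(rbind, truth))
  })
}

#' Render a paired PI / apoTRACE image
#'
#' Dead pixels (from the same Bernoulli survival draw as
#' [render_livedead()]) are PI-positive; each dead pixel is additionally
#' apoTRACE-positive with probability `apoptotic_fraction`. Live pixels
#' are negative in both channels.
#'
#' @inheritParams render_livedead
#' @param apoptotic_fraction probability in `[0, 1]` that a dead pixel
#'   died by apoptosis.
#' @return list with `image` (channels `pi`, `apotrace`), `pi_mask`,
#'   `apotrace_mask` (logical ground-truth matrices) and `labels`.
#' @export
render_apoptosis_pair <- function(field, model, apoptotic_fraction = 0.97,
                                  noise = noise_model(), pixel_size = 2,
                                  seed = 1L, brightness = 3000) {
  if (apoptotic_fraction < 0 || apoptotic_fraction > 1)
    stopf("apoptotic_fraction must be in [0, 1]")
  dims <- field_grid_dims(field, pixel_size)
  pi_m <- matrix(FALSE, dims[["ny"]], dims[["nx"]])
  apo_m <- matrix(FALSE, dims[["ny"]], dims[["nx"]])
  labels <- matrix(0L, dims[["ny"]], dims[["nx"]])
  with_seed(seed, {
    for (spec in field$nodules) {
      ras <- rasterize_nodule(spec, dims, pixel_size)
      if (!length(ras$idx)) next
      p <- pixel_survival(spec, ras$radius, field, model)
      dead <- runif(length(p)) >= p
      apo <- dead & (runif(length(p)) < apoptotic_fraction)
      pi_m[ras$idx[dead]] <- TRUE
      apo_m[ras$idx[apo]] <- TRUE
      labels[ras$idx] <- spec$id
    }
    img <- culture_image(
      list(pi = apply_noise(pi_m * brightness, noise),
           apotrace = apply_noise(apo_m * brightness, noise)),
      pixel_size, noise$background_level)
    list(image = img, pi_mask = pi_m, apotrace_mask = apo_m,
         labels = labels)
  })
}
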