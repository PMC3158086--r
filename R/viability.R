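# Well-level live/dead viability assay.
#
# Well viability is the ratio of total (background-subtracted) live
# intensity to total live plus dead intensity. Background is the modal
# intensity of each channel's histogram; subtraction clips at zero since
# intensities are physical. All viabilities are normalized to the mean of
# the no-treatment (NT) control wells, and group comparisons use the
# classical pooled-variance Student's t-test.

#' Estimate the background intensity of a channel
#'
#' The modal intensity of a 256-bin histogram over the channel's observed
#' range (bin centre of the maximal bin, earliest on ties). Images are
#' dominated by background pixels, so the histogram mode tracks the
#' camera offset.
#'
#' @param channel numeric matrix (or vector) of intensities.
#' @param nbins number of histogram bins.
#' @return scalar background intensity.
#' @export
estimate_background <- function(channel, nbins = 256L) {
  x <- as.numeric(channel)
  if (!length(x)) stopf("empty channel")
  lo <- min(x); hi <- max(x)
  if (hi - lo <= 0) return(lo)  # constant image: mode is the constant
  breaks <- seq(lo, hi, length.out = nbins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = nbins)
  k <- which.max(counts)
  (breaks[[k]] + breaks[[k + 1L]]) / 2
}

#' Background-subtract a channel (clipped at zero)
#' @inheritParams estimate_background
#' @return matrix of the same shape.
#' @export
subtract_background <- function(channel, nbins = 256L) {
  clip0(channel - estimate_background(channel, nbins))
}

#' Well-level viability from a live/dead image pair
#'
#' @param live,dead numeric matrices of equal shape.
#' @return list with `live_total`, `dead_total` (background-subtracted
#'   intensity sums) and `viability = live_total / (live_total +
#'   dead_total)`.
#' @export
well_viability <- function(live, dead) {
  if (!identical(dim(live), dim(dead)))
    stopf("live and dead channels must share one shape")
  lt <- sum(subtract_background(live))
  dt <- sum(subtract_background(dead))
  if (lt + dt <= 0)
    stopf("empty well: both totals are zero after background subtraction")
  list(live_total = lt, dead_total = dt, viability = lt / (lt + dt))
}

#' Normalize well viabilities to the no-treatment controls
#'
#' @param wells data.frame with at least `condition` and `viability`
#'   columns.
#' @return `wells` with a `normalized_viability` column; the NT group
#'   mean of the normalized values is exactly 1.
#' @export
normalize_viability <- function(wells) {
  nt <- wells$viability[wells$condition == "NT"]
  if (!length(nt)) stopf("no NT control wells: cannot normalize")
  wells$normalized_viability <- wells$viability / mean(nt)
  wells
}

#' Pooled-variance Student's t-test
#'
#' Classical two-sample Student's t with pooled variance and a two-sided
#' p-value on `n_a + n_b - 2` degrees of freedom. A Welch option is
#' available behind `welch = TRUE`.
#'
#' @param group_a,group_b numeric vectors (each >= 2 values).
#' @param welch use the Welch (unequal-variance) statistic instead.
#' @return list with `t_statistic`, `degrees_of_freedom`, `p_value`.
#' @export
student_t_test <- function(group_a, group_b, welch = FALSE) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stopf("each group needs at least 2 values")
  ma <- mean(group_a); mb <- mean(group_b)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (welch) {
    se2 <- va / na + vb / nb
    if (se2 <= 0) stopf("degenerate input: zero variance in both groups")
    t <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 <= 0) stopf("degenerate input: zero pooled variance")
    t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  list(t_statistic = t, degrees_of_freedom = df,
       p_value = 2 * pt(-abs(t), df))
}

#' Interpolated half-kill light dose (LD50)
#'
#' Mean normalized viability is computed per dose and the dose at which
#' the linear interpolation of these means crosses 0.5 is returned (the
#' lowest crossing if there are several).
#'
#' @param doses fluences, J/cm^2 (one per well).
#' @param normalized_viabilities matching normalized viabilities.
#' @return the LD50 in J/cm^2.
#' @export
estimate_ld50 <- function(doses, normalized_viabilities) {
  if (length(unique(doses)) < 2) stopf("need at least 2 distinct doses")
  m <- tapply(normalized_viabilities, doses, mean)
  d <- as.numeric(names(m))
  o <- order(d)
  d <- d[o]; v <- as.numeric(m)[o]
  for (i in seq_len(length(d) - 1L)) {
    if (v[[i]] == 0.5) return(d[[i]])
    if ((v[[i]] - 0.5) * (v[[i + 1L]] - 0.5) < 0) {
      return(d[[i]] + (0.5 - v[[i]]) * (d[[i + 1L]] - d[[i]]) /
               (v[[i + 1L]] - v[[i]]))
    }
  }
  if (v[[length(v)]] == 0.5) return(d[[length(d)]])
  stopf("viability never crosses 0.5 over the tested doses (out of range)")
}

#' Summarize an irradiance series at fixed fluence
#'
#' @param wells data.frame with `irradiance` and `normalized_viability`
#'   columns (>= 3 irradiance levels).
#' @param plateau_tol plateau tolerance in viability units (default 0.02,
#'   i.e. two percentage points).
#' @return list with `table` (per-irradiance mean/sd/n),
#'   `argmin_irradiance` (lowest mean viability) and `plateau_onset`
#'   (smallest irradiance whose mean is within `plateau_tol` of the
#'   highest-irradiance mean).
#' @export
summarize_irradiance_series <- function(wells, plateau_tol = 0.02) {
  irr <- sort(unique(wells$irradiance))
  if (length(irr) < 3) stopf("need at least 3 irradiance levels")
  m <- vapply(irr, function(i)
    mean(wells$normalized_viability[wells$irradiance == i]), 0)
  s <- vapply(irr, function(i)
    sd(wells$normalized_viability[wells$irradiance == i]), 0)
  n <- vapply(irr, function(i) sum(wells$irradiance == i), 0L)
  tab <- data.frame(irradiance = irr, mean_viability = m,
                    sd_viability = s, n = n)
  top <- m[[length(m)]]
  onset <- irr[[min(which(m >= top - plateau_tol))]]
  list(table = tab, argmin_irradiance = irr[[which.min(m)]],
       plateau_onset = onset)
}

#' Simulate a viability experiment through the full image pipeline
#'
#' For each design row, renders `n_wells` live/dead well images with the
#' generator and scores them with the image pipeline
#' ([well_viability()]), then normalizes to the NT wells. This is the
#' generator-to-pipeline loop used for end-to-end validation.
#'
#' @param design data.frame with columns `condition`, `dose`,
#'   `irradiance`, `atmosphere` and `n_wells`.
#' @param cfg a `pdt_config` (default: packaged calibrated defaults).
#' @param seed master integer seed; each well gets a derived seed.
#' @return data.frame of well records with `normalized_viability`.
#' @export
simulate_viability_experiment <- function(design, cfg = NULL, seed = 1L) {
  if (is.null(cfg)) cfg <- load_config()
  model <- dose_response_model(cfg)
  noise <- noise_model(cfg$noise$photon_scale, cfg$noise$read_sigma,
                       cfg$noise$background_level)
  rows <- list()
  widx <- 0L
  for (i in seq_len(nrow(design))) {
    for (w in seq_len(design$n_wells[[i]])) {
      widx <- widx + 1L
      wseed <- derive_seed(seed, widx)
      specs <- sample_nodule_field(cfg$nodules_per_well,
                                   cfg$diameter_range_um,
                                   cfg$field_size_um, seed = wseed,
                                   core_fraction = cfg$core_fraction,
                                   min_gap = cfg$min_gap_um %||% 4)
      agent <- if ("agent" %in% names(design)) design$agent[[i]] else "EtNBS"
      field <- culture_field(specs, design$condition[[i]],
                             design$dose[[i]], design$irradiance[[i]],
                             design$atmosphere[[i]], agent = agent,
                             field_size = cfg$field_size_um)
      ren <- render_livedead(field, model, noise, cfg$pixel_size_um,
                             seed = derive_seed(wseed, 1L),
                             brightness = cfg$brightness$live)
      wv <- well_viability(ren$image$channels$live,
                           ren$image$channels$dead)
      rows[[widx]] <- data.frame(
        well_id = sprintf("W%03d", widx),
        condition = design$condition[[i]], dose = design$dose[[i]],
        irradiance = design$irradiance[[i]],
        atmosphere = design$atmosphere[[i]],
        live_total = wv$live_total, dead_total = wv$dead_total,
        viability = wv$viability,
        true_viability = sum(ren$truth$viability * ren$truth$n_pixels) /
          sum(ren$truth$n_pixels))
    }
  }
  normalize_viability(do.call(rbind, rows))
}
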