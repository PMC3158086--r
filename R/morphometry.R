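# Per-nodule segmentation and morphometry.
#
# The two fluorescence channels are background-subtracted, summed into a
# single intensity image, thresholded with Otsu's method, and the binary
# mask decomposed into 8-connected components. Component equivalent
# diameters, spherical volumes and per-nodule viabilities are tabulated,
# and the live:dead ratio is fitted against volume as a power law on
# log-log axes.

#' Otsu threshold of an intensity image or histogram
#'
#' Exhaustive search over all candidate histogram cuts for the threshold
#' minimizing the within-class intensity variance (equivalently,
#' maximizing the between-class variance); ties break to the lowest
#' threshold.
#'
#' @param values numeric matrix/vector of intensities, or a list
#'   `list(mids =, counts =)` giving a precomputed histogram.
#' @param nbins number of histogram bins when `values` are intensities.
#' @return the threshold intensity; pixels strictly above it are
#'   foreground.
#' @export
otsu_threshold <- function(values, nbins = 256L) {
  if (is.list(values) && !is.null(values$counts)) {
    mids <- as.numeric(values$mids)
    counts <- as.numeric(values$counts)
  } else {
    x <- as.numeric(values)
    lo <- min(x); hi <- max(x)
    if (hi - lo <= 0) stopf("constant input cannot be thresholded")
    breaks <- seq(lo, hi, length.out = nbins + 1L)
    counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                       nbins = nbins)
    mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  }
  if (sum(counts > 0) < 2) stopf("constant input cannot be thresholded")
  w <- counts / sum(counts)
  mu <- sum(w * mids)
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  k <- seq_len(length(mids) - 1L)  # cut after bin k
  valid <- cw[k] > 0 & cw[k] < 1
  between <- rep(-Inf, length(k))
  between[valid] <- (mu * cw[k][valid] - cm[k][valid])^2 /
    (cw[k][valid] * (1 - cw[k][valid]))
  kbest <- which.max(between)  # which.max returns the first (lowest) tie
  (mids[[kbest]] + mids[[kbest + 1L]]) / 2
}

#' Segment nodules from a live/dead image pair
#'
#' @param live,dead numeric matrices of equal shape.
#' @param pixel_size um per pixel.
#' @param min_diameter smallest equivalent diameter kept, um (debris
#'   filter).
#' @return integer label matrix (background 0, labels 1..K in scan
#'   order).
#' @export
segment_nodules <- function(live, dead, pixel_size = 2, min_diameter = 30) {
  if (!identical(dim(live), dim(dead)))
    stopf("live and dead channels must share one shape")
  total <- subtract_background(live) + subtract_background(dead)
  thr <- otsu_threshold(total)
  mask <- total > thr
  lab <- .cc_label8(mask)
  if (max(lab) == 0L) return(lab)
  area_px <- tabulate(lab[lab > 0L], nbins = max(lab))
  eqd <- 2 * sqrt(area_px * pixel_size^2 / pi)
  keep <- which(eqd >= min_diameter)
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0L
  out[nz] <- remap[lab[nz]]
  out
}

#' Per-nodule morphometry and viability
#'
#' Applies the label map to the background-subtracted channels.
#' Equivalent diameter is that of the circle with the component's area;
#' volume assumes a sphere of that diameter. Components touching the
#' image border are excluded (their geometry is truncated) and reported
#' in the `border_labels` attribute.
#'
#' @param labels integer label matrix from [segment_nodules()].
#' @param live,dead numeric matrices aligned with `labels`.
#' @param pixel_size um per pixel.
#' @param ratio_eps intensity floor added to a zero dead sum so the
#'   live:dead ratio stays finite (flagged in `ratio_flagged`).
#' @return data.frame of nodule records: `label`, `area`,
#'   `equivalent_diameter`, `volume`, `live_sum`, `dead_sum`,
#'   `live_dead_ratio`, `viability`, `centroid_x`, `centroid_y`,
#'   `ratio_flagged`.
#' @export
nodule_metrics <- function(labels, live, dead, pixel_size = 2,
                           ratio_eps = 1) {
  if (!identical(dim(labels), dim(live)) ||
      !identical(dim(labels), dim(dead)))
    stopf("labels and channels must be aligned")
  nlab <- max(labels)
  if (nlab == 0L)
    return(structure(data.frame(), border_labels = integer(0)))
  lsub <- subtract_background(live)
  dsub <- subtract_background(dead)
  idx <- which(labels > 0L)
  l <- labels[idx]
  area_px <- tabulate(l, nbins = nlab)
  if (any(area_px == 0L)) stopf("label map has missing labels")
  rows <- ((idx - 1L) %% nrow(labels)) + 1L
  cols <- ((idx - 1L) %/% nrow(labels)) + 1L
  on_border <- rows == 1L | rows == nrow(labels) |
    cols == 1L | cols == ncol(labels)
  border_labels <- sort(unique(l[on_border]))
  live_sum <- vapply(seq_len(nlab), function(k) sum(lsub[idx[l == k]]), 0)
  dead_sum <- vapply(seq_len(nlab), function(k) sum(dsub[idx[l == k]]), 0)
  cx <- vapply(seq_len(nlab), function(k) mean(cols[l == k]), 0)
  cy <- vapply(seq_len(nlab), function(k) mean(rows[l == k]), 0)
  area <- area_px * pixel_size^2
  eqd <- 2 * sqrt(area / pi)
  flag <- dead_sum <= 0
  rec <- data.frame(
    label = seq_len(nlab), area = area, equivalent_diameter = eqd,
    volume = pi / 6 * eqd^3, live_sum = live_sum, dead_sum = dead_sum,
    live_dead_ratio = live_sum / ifelse(flag, dead_sum + ratio_eps,
                                        dead_sum),
    viability = live_sum / (live_sum + dead_sum),
    centroid_x = (cx - 0.5) * pixel_size,
    centroid_y = (cy - 0.5) * pixel_size,
    ratio_flagged = flag)
  rec <- rec[!(rec$label %in% border_labels), , drop = FALSE]
  attr(rec, "border_labels") <- border_labels
  rec
}

#' Power-law fit of live:dead ratio against nodule volume
#'
#' Ordinary least squares of `log(ratio)` on `log(volume)`:
#' `ratio = prefactor * volume^exponent`.
#'
#' @param volumes nodule volumes (> 0).
#' @param ratios live:dead ratios (> 0).
#' @return list with `prefactor`, `exponent`, `r_squared`, `n`.
#' @export
fit_powerlaw <- function(volumes, ratios) {
  if (length(volumes) < 3) stopf("need at least 3 points")
  if (any(volumes <= 0) || any(ratios <= 0))
    stopf("power-law fitting needs strictly positive values")
  fit <- lm(log(ratios) ~ log(volumes))
  y <- log(ratios)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  list(prefactor = exp(unname(coef(fit)[[1]])),
       exponent = unname(coef(fit)[[2]]),
       r_squared = r2, n = length(volumes))
}

#' Penetration depth of an uptake profile into a nodule
#'
#' Mean background-subtracted intensity is profiled in 1-pixel-wide
#' Euclidean distance shells from the mask boundary; the returned depth
#' is where the profile first falls below `1/e` of the boundary-shell
#' value (linear interpolation between shells). If it never does, the
#' nodule is flagged fully penetrated and the maximum depth (the inradius
#' of the mask) is returned.
#'
#' @param uptake numeric intensity matrix.
#' @param nodule_mask logical matrix, a single connected nodule.
#' @param pixel_size um per pixel.
#' @return list with `depth_um`, `full_penetration` (logical) and
#'   `profile` (data.frame of shell depth and mean intensity).
#' @export
penetration_depth <- function(uptake, nodule_mask, pixel_size = 2) {
  if (!identical(dim(uptake), dim(nodule_mask)))
    stopf("uptake and mask must share one shape")
  if (!any(nodule_mask)) stopf("empty nodule mask")
  sub <- subtract_background(uptake)
  d_px <- sqrt(.edt_sq(nodule_mask))  # distance to nearest background px
  shell <- round(d_px[nodule_mask])   # 1-px shells, boundary shell = 1
  shell[shell < 1] <- 1L
  vals <- sub[nodule_mask]
  ks <- sort(unique(shell))
  prof <- vapply(ks, function(k) mean(vals[shell == k]), 0)
  # shell k collects pixels ~k px from the nearest outside pixel centre;
  # the physical boundary lies half a pixel in, so depth = (k - 0.5) px
  depth_axis <- (ks - 0.5) * pixel_size
  profile <- data.frame(depth_um = depth_axis, mean_intensity = prof)
  target <- prof[[1]] / exp(1)
  below <- which(prof < target)
  if (!length(below)) {
    return(list(depth_um = max(depth_axis), full_penetration = TRUE,
                profile = profile))
  }
  i <- below[[1]]
  if (i == 1L) {
    depth <- depth_axis[[1]]
  } else {
    depth <- depth_axis[[i - 1L]] +
      (prof[[i - 1L]] - target) / (prof[[i - 1L]] - prof[[i]]) *
        (depth_axis[[i]] - depth_axis[[i - 1L]])
  }
  list(depth_um = depth, full_penetration = FALSE, profile = profile)
}
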