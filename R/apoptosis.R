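# Apoptosis co-localization mapping.
#
# Dead cells take up propidium iodide; apoptotic cells stain with
# apoTRACE. Each channel is background-subtracted and Otsu-thresholded
# independently, and the bitwise AND of the two binary masks marks the
# pixels that died by apoptosis. The apoptotic fraction is the share of
# PI-positive pixels that are also apoTRACE-positive.

#' Apoptosis co-localization map from a PI / apoTRACE image pair
#'
#' @param pi,apotrace numeric matrices of equal shape.
#' @param min_object_px optional small-object removal: components of the
#'   apoptotic mask smaller than this pixel count are dropped (0 = off,
#'   the default; the source analysis applies no morphological cleanup).
#' @return list with logical `pi_mask`, `apotrace_mask`,
#'   `apoptotic_mask` (their AND) and `apoptotic_fraction` (`NA` with a
#'   warning if no pixel is PI-positive).
#' @export
apoptosis_map <- function(pi, apotrace, min_object_px = 0L) {
  if (!identical(dim(pi), dim(apotrace)))
    stopf("pi and apotrace channels must share one shape")
  pim <- binarize_channel(pi)
  apm <- binarize_channel(apotrace)
  apo <- pim & apm
  if (min_object_px > 0L && any(apo)) {
    lab <- .cc_label8(apo)
    sz <- tabulate(lab[lab > 0L], nbins = max(lab))
    drop <- which(sz < min_object_px)
    if (length(drop)) apo[lab %in% drop] <- FALSE
  }
  frac <- if (any(pim)) sum(apo) / sum(pim) else {
    warning("PI mask is empty: apoptotic fraction undefined")
    NA_real_
  }
  list(pi_mask = pim, apotrace_mask = apm, apoptotic_mask = apo,
       apoptotic_fraction = frac)
}

binarize_channel <- function(channel) {
  sub <- subtract_background(channel)
  thr <- otsu_threshold(sub)
  sub > thr
}
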