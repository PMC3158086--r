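# Pipeline orchestration: file-level stages behind the command-line
# interface. Every run writes its resolved configuration and a log into
# the output directory; identical configuration and seed give identical
# outputs.

#' Write a hyperspectral cube as multi-page TIFF plus band-axis sidecar
#'
#' @param cube a [hyperspectral_cube()].
#' @param path output TIFF path; the sidecar CSV takes the same stem with
#'   `_bands.csv` appended.
#' @export
write_hyperspectral <- function(cube, path) {
  pages <- lapply(seq_along(cube$band_centers),
                  function(k) cube$planes[, , k])
  write_tiff(pages, path, bits = 16L,
             descriptions = sprintf("band_%gnm", cube$band_centers))
  sidecar <- sub("\\.tiff?$", "", path)
  write.csv(data.frame(band_center_nm = cube$band_centers,
                       bandwidth_nm = cube$bandwidth),
            paste0(sidecar, "_bands.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a hyperspectral cube written by [write_hyperspectral()]
#' @param path TIFF path (sidecar `<stem>_bands.csv` must exist).
#' @param pixel_size um per pixel.
#' @export
read_hyperspectral <- function(path, pixel_size = 2) {
  pages <- read_tiff(path)
  sidecar <- paste0(sub("\\.tiff?$", "", path), "_bands.csv")
  if (!file.exists(sidecar)) stopf("missing band-axis sidecar: %s", sidecar)
  bands <- read.csv(sidecar)
  planes <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) planes[, , k] <- pages[[k]]
  hyperspectral_cube(planes, bands$band_center_nm,
                     bandwidth = bands$bandwidth_nm[[1]],
                     pixel_size = pixel_size)
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                 sprintf(fmt, ...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run a pipeline stage
#'
#' @param command one of `"simulate"`, `"viability"`, `"nodules"`,
#'   `"ph"`, `"apoptosis"`, `"all"`, `"calibrate"`.
#' @param out output directory (created if needed).
#' @param cfg a `pdt_config` (default: packaged calibrated defaults).
#' @param seed master integer seed.
#' @param inputs named list of stage inputs: `plate` (plate-layout CSV)
#'   for the analysis stages, `cube` for `ph`, `pi`/`apotrace` for
#'   `apoptosis`; `simulate`/`all` need none.
#' @param simulate_args overrides for the simulated plate: `doses`,
#'   `irradiances`, `condition`, `atmosphere`, `agent`, `n_wells`.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(command = c("simulate", "viability", "nodules",
                                     "ph", "apoptosis", "all",
                                     "calibrate"),
                         out, cfg = NULL, seed = 1L, inputs = list(),
                         simulate_args = list()) {
  command <- match.arg(command)
  if (is.null(cfg)) cfg <- load_config()
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) stopf("cannot create output directory %s", out)
  logcon <- file(file.path(out, "run.log"), "a")
  on.exit(close(logcon))
  save_config(cfg, file.path(out, "resolved_config.json"))
  writeLines(sprintf("seed: %d", as.integer(seed)),
             file.path(out, "seed.txt"))
  log_line(logcon, "command=%s seed=%d out=%s", command, seed, out)
  switch(command,
         simulate = stage_simulate(cfg, out, seed, simulate_args, logcon),
         viability = stage_viability(cfg, out, inputs, logcon),
         nodules = stage_nodules(cfg, out, inputs, logcon),
         ph = stage_ph(cfg, out, inputs, logcon),
         apoptosis = stage_apoptosis(cfg, out, inputs, logcon),
         calibrate = {
           cfg <- calibrate_dose_response(cfg)
           save_config(cfg, file.path(out, "calibrated_config.json"))
           log_line(logcon, "calibrated d50 = %.4f J/cm^2",
                    cfg$dose_response$d50_J_cm2)
         },
         all = {
           stage_simulate(cfg, out, seed, simulate_args, logcon)
           inputs$plate <- file.path(out, "plate.csv")
           stage_viability(cfg, out, inputs, logcon)
           stage_nodules(cfg, out, inputs, logcon)
         })
  invisible(out)
}

stage_simulate <- function(cfg, out, seed, args, logcon) {
  doses <- args$doses %||% c(0, 5, 10, 15, 20, 25, 30)
  irradiances <- args$irradiances %||%
    cfg$dose_response$reference_irradiance
  n_wells <- args$n_wells %||% cfg$wells_per_condition %||% 3
  atmosphere <- args$atmosphere %||% "normoxic"
  agent <- args$agent %||% "EtNBS"
  model <- dose_response_model(cfg)
  noise <- noise_model(cfg$noise$photon_scale, cfg$noise$read_sigma,
                       cfg$noise$background_level)
  design <- rbind(
    data.frame(condition = "NT", dose = 0, irradiance = 0),
    expand.grid(condition = "treated", dose = doses,
                irradiance = irradiances, stringsAsFactors = FALSE))
  plate <- list()
  widx <- 0L
  truths <- list()
  for (i in seq_len(nrow(design))) {
    for (w in seq_len(n_wells)) {
      widx <- widx + 1L
      wid <- sprintf("W%03d", widx)
      wseed <- derive_seed(seed, widx)
      specs <- sample_nodule_field(cfg$nodules_per_well,
                                   cfg$diameter_range_um,
                                   cfg$field_size_um, seed = wseed,
                                   core_fraction = cfg$core_fraction,
                                   min_gap = cfg$min_gap_um %||% 4)
      field <- culture_field(specs, design$condition[[i]],
                             design$dose[[i]], design$irradiance[[i]],
                             atmosphere, agent, cfg$field_size_um)
      ren <- render_livedead(field, model, noise, cfg$pixel_size_um,
                             seed = derive_seed(wseed, 1L),
                             brightness = cfg$brightness$live)
      img_path <- file.path(out, paste0(wid, "_livedead.tif"))
      write_tiff(list(ren$image$channels$live, ren$image$channels$dead),
                 img_path, descriptions = c("live", "dead"))
      write_tiff(ren$labels, file.path(out, paste0(wid, "_labels.tif")))
      truth <- ren$truth
      truth$well_id <- wid
      truths[[widx]] <- truth
      plate[[widx]] <- data.frame(
        well_id = wid, condition = design$condition[[i]],
        dose = design$dose[[i]], irradiance = design$irradiance[[i]],
        atmosphere = atmosphere, live_path = img_path,
        dead_path = img_path, live_page = 1L, dead_page = 2L)
    }
  }
  write.csv(do.call(rbind, plate), file.path(out, "plate.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, truths), file.path(out, "ground_truth.csv"),
            row.names = FALSE)
  log_line(logcon, "simulated %d wells", widx)
}

read_plate <- function(inputs) {
  plate_path <- inputs$plate
  if (is.null(plate_path) || !file.exists(plate_path %||% ""))
    stopf("missing input: plate-layout CSV (inputs$plate)")
  read.csv(plate_path, stringsAsFactors = FALSE)
}

read_well_channels <- function(row) {
  pages <- read_tiff(row$live_path)
  live <- pages[[row$live_page %||% 1L]]
  pages_d <- if (identical(row$dead_path, row$live_path)) pages else
    read_tiff(row$dead_path)
  dead <- pages_d[[row$dead_page %||% 2L]]
  list(live = live, dead = dead)
}

stage_viability <- function(cfg, out, inputs, logcon) {
  plate <- read_plate(inputs)
  recs <- lapply(seq_len(nrow(plate)), function(i) {
    ch <- read_well_channels(plate[i, ])
    wv <- well_viability(ch$live, ch$dead)
    data.frame(well_id = plate$well_id[[i]],
               condition = plate$condition[[i]],
               dose = plate$dose[[i]],
               irradiance = plate$irradiance[[i]],
               atmosphere = plate$atmosphere[[i]],
               live_total = wv$live_total, dead_total = wv$dead_total,
               viability = wv$viability)
  })
  wells <- normalize_viability(do.call(rbind, recs))
  write.csv(wells, file.path(out, "wells.csv"), row.names = FALSE)
  # pairwise Student's t of each treated group against the NT controls
  nt <- wells$normalized_viability[wells$condition == "NT"]
  groups <- unique(wells[wells$condition != "NT",
                         c("condition", "dose", "irradiance")])
  cmp <- list()
  if (length(nt) >= 2 && nrow(groups)) {
    for (g in seq_len(nrow(groups))) {
      sel <- wells$condition == groups$condition[[g]] &
        wells$dose == groups$dose[[g]] &
        wells$irradiance == groups$irradiance[[g]]
      v <- wells$normalized_viability[sel]
      if (length(v) < 2) next
      tt <- tryCatch(student_t_test(v, nt), error = function(e) NULL)
      if (is.null(tt)) next
      cmp[[length(cmp) + 1L]] <- data.frame(
        condition = groups$condition[[g]], dose = groups$dose[[g]],
        irradiance = groups$irradiance[[g]], n = length(v),
        t_statistic = tt$t_statistic,
        degrees_of_freedom = tt$degrees_of_freedom,
        p_value = tt$p_value)
    }
  }
  if (length(cmp))
    write.csv(do.call(rbind, cmp), file.path(out, "comparisons.csv"),
              row.names = FALSE)
  log_line(logcon, "scored %d wells", nrow(wells))
}

stage_nodules <- function(cfg, out, inputs, logcon) {
  plate <- read_plate(inputs)
  px <- cfg$pixel_size_um
  min_d <- cfg$pipeline$min_diameter_um %||% 30
  recs <- list()
  for (i in seq_len(nrow(plate))) {
    ch <- read_well_channels(plate[i, ])
    labels <- segment_nodules(ch$live, ch$dead, px, min_d)
    write_tiff(labels, file.path(out, paste0(plate$well_id[[i]],
                                             "_seglabels.tif")))
    if (max(labels) == 0L) next
    met <- nodule_metrics(labels, ch$live, ch$dead, px)
    if (!nrow(met)) next
    met$well_id <- plate$well_id[[i]]
    met$condition <- plate$condition[[i]]
    recs[[length(recs) + 1L]] <- met
  }
  nod <- do.call(rbind, recs)
  if (is.null(nod) || !nrow(nod)) {
    log_line(logcon, "no nodules found")
    return(invisible(NULL))
  }
  write.csv(nod, file.path(out, "nodules.csv"), row.names = FALSE)
  ok <- nod$volume > 0 & nod$live_dead_ratio > 0
  if (sum(ok) >= 3) {
    fit <- fit_powerlaw(nod$volume[ok], nod$live_dead_ratio[ok])
    jsonlite::write_json(fit, file.path(out, "powerlaw.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  log_line(logcon, "measured %d nodules", nrow(nod))
}

stage_ph <- function(cfg, out, inputs, logcon) {
  if (is.null(inputs$cube) || !file.exists(inputs$cube %||% ""))
    stopf("missing input: hyperspectral cube TIFF (inputs$cube)")
  cube <- read_hyperspectral(inputs$cube, cfg$pixel_size_um)
  cal <- if (!is.null(inputs$calibration)) {
    tab <- read.csv(inputs$calibration)
    calibration_curve("tabulated", table = tab)
  } else {
    derive_calibration(snarf_model(
      pka = cfg$snarf$pka, acid_peak = cfg$snarf$acid_peak_nm,
      base_peak = cfg$snarf$base_peak_nm, sigma = cfg$snarf$sigma_nm,
      brightness = cfg$snarf$brightness))
  }
  rat <- ratio_image(cube, cfg$pipeline$low_signal_factor %||% 5)
  phi <- ratio_to_ph(rat, cal)
  ph_out <- phi$ph
  ph_out[is.na(ph_out)] <- -1
  write_tiff(ph_out, file.path(out, "ph_map.tif"), bits = 32L,
             descriptions = "ph")
  write_tiff((phi$mask_reason != "ok") * 1, file.path(out, "ph_mask.tif"))
  # nodule mask: largest connected component of defined pixels
  defined <- !is.na(phi$ph)
  if (any(defined)) {
    lab <- .cc_label8(defined)
    big <- which.max(tabulate(lab[lab > 0L], nbins = max(lab)))
    prof <- radial_ph_profile(phi, lab == big, cfg$pixel_size_um)
    out_tab <- prof$profile
    out_tab$core_median <- prof$core_median
    out_tab$edge_median <- prof$edge_median
    write.csv(out_tab, file.path(out, "ph_radial_profile.csv"),
              row.names = FALSE)
  }
  log_line(logcon, "pH map written (%d defined pixels)", sum(!is.na(phi$ph)))
}

stage_apoptosis <- function(cfg, out, inputs, logcon) {
  for (nm in c("pi", "apotrace"))
    if (is.null(inputs[[nm]]) || !file.exists(inputs[[nm]] %||% ""))
      stopf("missing input: %s channel TIFF (inputs$%s)", nm, nm)
  pi_img <- read_tiff(inputs$pi)[[1]]
  ap_img <- read_tiff(inputs$apotrace)[[1]]
  res <- apoptosis_map(pi_img, ap_img)
  write_tiff(res$pi_mask * 1, file.path(out, "pi_mask.tif"))
  write_tiff(res$apotrace_mask * 1, file.path(out, "apotrace_mask.tif"))
  write_tiff(res$apoptotic_mask * 1, file.path(out, "apoptotic_mask.tif"))
  write.csv(data.frame(pi_pixels = sum(res$pi_mask),
                       apotrace_pixels = sum(res$apotrace_mask),
                       apoptotic_pixels = sum(res$apoptotic_mask),
                       apoptotic_fraction = res$apoptotic_fraction),
            file.path(out, "apoptosis_summary.csv"), row.names = FALSE)
  log_line(logcon, "apoptotic fraction = %.4f", res$apoptotic_fraction)
}
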