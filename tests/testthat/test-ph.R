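make_cal <- function() derive_calibration(snarf_model())

test_that("extract_band does exact axis arithmetic", {
  planes <- array(0, c(4, 4, 51))
  for (k in 1:51) planes[, , k] <- k
  cube <- hyperspectral_cube(planes)
  expect_equal(extract_band(cube, 570)[1, 1], 5)   # plane index 5 (550 + 4*5)
  expect_equal(extract_band(cube, 650)[1, 1], 21)  # plane index 21
  expect_error(extract_band(cube, 571), "band")
})

test_that("ratio_image: subtraction, masking, uniformity", {
  sp <- nodule_spec(1, c(300, 300), 300)
  hs <- render_hyperspectral(sp, ph_profile(6.5, 6.5, 1), snarf_model(),
                             noise_free(), 2, seed = 1,
                             field_size = c(600, 600))
  ri <- ratio_image(hs$cube)
  # background-only pixels are masked
  expect_true(all(ri$mask[!hs$mask]))
  # nodule pixels are defined and uniform at uniform pH
  vals <- ri$ratio[hs$mask]
  expect_true(all(!is.na(vals)))
  expect_lt(max(vals) - min(vals), 1e-10)
  # equal bands after subtraction give ratio one
  planes <- array(100, c(8, 8, 51))
  planes[, , 5] <- 100; planes[, , 21] <- 100
  planes[3, 3, ] <- 600  # one bright pixel in every band
  cube <- hyperspectral_cube(planes)
  r2 <- ratio_image(cube)
  expect_equal(r2$ratio[3, 3], 1)
})

test_that("ratio_to_ph: midpoint, endpoints, round trip", {
  cal <- make_cal()
  mid_R <- (cal$span_factor * cal$r_acid + cal$r_base) /
    (1 + cal$span_factor)  # ratio at alpha = 0.5
  r <- matrix(c(mid_R, cal$r_base, cal$r_acid, 0.5), 2, 2)
  phi <- ratio_to_ph(list(ratio = r, mask = matrix(FALSE, 2, 2)), cal)
  expect_equal(phi$ph[1, 1], cal$pka, tolerance = 1e-10)
  expect_true(is.na(phi$ph[2, 1]))  # base endpoint saturates
  expect_equal(phi$mask_reason[2, 1], "out_of_range")
  expect_true(is.na(phi$ph[1, 2]))  # acid endpoint saturates

  # forward-inverse consistency at pH 6.5, noise-free
  sp <- nodule_spec(1, c(300, 300), 300)
  hs <- render_hyperspectral(sp, ph_profile(6.5, 6.5, 1), snarf_model(),
                             noise_free(), 2, seed = 1,
                             field_size = c(600, 600))
  phu <- ratio_to_ph(ratio_image(hs$cube), cal)
  expect_equal(median(phu$ph[hs$mask], na.rm = TRUE), 6.5,
               tolerance = 0.05)

  # tabulated curves interpolate and reject non-monotone tables
  tab <- calibration_curve("tabulated",
                           table = data.frame(ratio = c(0.2, 1, 5),
                                              ph = c(7.5, 6.4, 5)))
  pht <- ratio_to_ph(list(ratio = matrix(1, 1, 1),
                          mask = matrix(FALSE, 1, 1)), tab)
  expect_equal(pht$ph[1, 1], 6.4)
  expect_error(calibration_curve("tabulated",
                                 table = data.frame(ratio = c(1, 2, 3),
                                                    ph = c(5, 7, 6))),
               "monotone")
})

test_that("recovered pH is monotone and accurate across the range", {
  cal <- make_cal()
  sp <- nodule_spec(1, c(250, 250), 250)
  phs <- seq(5.0, 7.5, by = 0.5)
  rec_clean <- rec_noisy <- numeric(length(phs))
  for (i in seq_along(phs)) {
    hs <- render_hyperspectral(sp, ph_profile(phs[i], phs[i], 1),
                               snarf_model(), noise_free(), 2, seed = 1,
                               field_size = c(500, 500))
    rec_clean[i] <- median(ratio_to_ph(ratio_image(hs$cube),
                                       cal)$ph[hs$mask], na.rm = TRUE)
    hn <- render_hyperspectral(sp, ph_profile(phs[i], phs[i], 1),
                               snarf_model(), noise_model(), 2,
                               seed = i, field_size = c(500, 500))
    rec_noisy[i] <- median(ratio_to_ph(ratio_image(hn$cube),
                                       cal)$ph[hn$mask], na.rm = TRUE)
  }
  expect_true(all(diff(rec_clean) > 0))
  expect_true(all(abs(rec_clean - phs) <= 0.05))
  expect_true(all(diff(rec_noisy) > 0))
  expect_true(all(abs(rec_noisy - phs) <= 0.15))
})

test_that("mask correctness and gain invariance", {
  cal <- make_cal()
  sp <- nodule_spec(1, c(300, 300), 350)
  hs <- render_hyperspectral(sp, ph_profile(), snarf_model(),
                             noise_model(), 2, seed = 5,
                             field_size = c(600, 600))
  ri <- ratio_image(hs$cube)
  expect_true(all(ri$mask[!hs$mask]))   # every background pixel masked
  interior <- hs$mask & !ri$mask
  expect_gt(mean(!ri$mask[hs$mask]), 0.999)  # interior pixels defined

  phi <- ratio_to_ph(ri, cal)
  gained <- hs$cube
  gained$planes <- gained$planes * 2.5
  phi2 <- ratio_to_ph(ratio_image(gained), cal)
  expect_equal(phi2$ph, phi$ph, tolerance = 1e-9)
})

test_that("radial profile: uniform and acidic-core nodules", {
  cal <- make_cal()
  sp <- nodule_spec(1, c(300, 300), 300)
  hs <- render_hyperspectral(sp, ph_profile(7, 7, 1), snarf_model(),
                             noise_free(), 2, seed = 1,
                             field_size = c(600, 600))
  phi <- ratio_to_ph(ratio_image(hs$cube), cal)
  pr <- radial_ph_profile(phi, hs$mask, 2)
  expect_equal(pr$core_median, 7, tolerance = 0.02)
  expect_equal(pr$edge_median, 7, tolerance = 0.02)

  # default acidic-core nodule, 400 um: sub-6 core, near-neutral edge
  sp4 <- nodule_spec(1, c(300, 300), 400)
  hs4 <- render_hyperspectral(sp4, ph_profile(), snarf_model(),
                              noise_model(), 2, seed = 2,
                              field_size = c(600, 600))
  phi4 <- ratio_to_ph(ratio_image(hs4$cube), cal)
  pr4 <- radial_ph_profile(phi4, hs4$mask, 2)
  expect_lt(pr4$core_median, pr4$edge_median)
  expect_lt(pr4$core_median, 6.0)
  expect_gte(pr4$edge_median, 6.8)
  # shell medians decrease monotonically toward the core
  m <- pr4$profile$median_ph
  expect_true(all(diff(m[!is.na(m)]) > 0))
})
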