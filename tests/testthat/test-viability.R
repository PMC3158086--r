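test_that("estimate_background finds the histogram mode", {
  expect_equal(estimate_background(matrix(100, 10, 10)), 100)

  set.seed(1)
  x <- c(rep(50, 900), rep(4000, 100))
  expect_equal(estimate_background(matrix(x, 40, 25)), 50,
               tolerance = 4000 / 256)

  # render with a known camera offset
  nz <- noise_model(photon_scale = 10, read_sigma = 5,
                    background_level = 200)
  ren <- render_well("NT", cfg = small_cfg, seed = 6, noise = nz)
  est <- estimate_background(ren$image$channels$dead)
  expect_equal(est, 200, tolerance = 5)
})

test_that("well_viability scores live/dead pairs", {
  set.seed(2)
  bg <- function() matrix(rnorm(2500, 100, 3), 50, 50)
  live <- bg(); live[10:20, 10:20] <- 3000
  expect_equal(well_viability(live, bg())$viability, 1, tolerance = 0.02)

  # equal totals give 0.5 (identical channels)
  both <- bg(); both[30:40, 5:15] <- 2000
  expect_equal(well_viability(both, both)$viability, 0.5)

  expect_error(well_viability(matrix(7, 5, 5), matrix(7, 5, 5)), "empty")

  # synthetic NT well at default noise
  ren <- render_well("NT", cfg = small_cfg, seed = 9)
  wv <- well_viability(ren$image$channels$live, ren$image$channels$dead)
  expect_gte(wv$viability, 0.98)
})

test_that("viability is invariant to common gain and common offset", {
  ren <- render_well("treated", dose = 15, irradiance = 25,
                     cfg = small_cfg, seed = 21)
  live <- ren$image$channels$live
  dead <- ren$image$channels$dead
  v0 <- well_viability(live, dead)$viability
  v_gain <- well_viability(3.7 * live, 3.7 * dead)$viability
  expect_equal(v_gain, v0, tolerance = 1e-10)
  v_off <- well_viability(live + 500, dead + 500)$viability
  expect_equal(v_off, v0, tolerance = 0.01)
})

test_that("normalize_viability pins the NT mean at one", {
  wells <- data.frame(condition = c("NT", "NT", "NT", "treated"),
                      viability = c(0.9, 1.0, 0.95, 0.475))
  out <- normalize_viability(wells)
  expect_equal(out$normalized_viability[[4]], 0.5)
  expect_equal(mean(out$normalized_viability[out$condition == "NT"]), 1)

  same <- data.frame(condition = c("NT", "NT", "treated"),
                     viability = rep(0.81, 3))
  expect_equal(normalize_viability(same)$normalized_viability, rep(1, 3))

  set.seed(5)
  rnd <- data.frame(condition = sample(c("NT", "treated"), 40, TRUE),
                    viability = runif(40, 0.2, 1))
  rnd$condition[1:2] <- "NT"
  out <- normalize_viability(rnd)
  expect_equal(mean(out$normalized_viability[out$condition == "NT"]), 1,
               tolerance = 1e-12)

  expect_error(normalize_viability(data.frame(condition = "treated",
                                              viability = 0.4)), "NT")
})

test_that("student_t_test matches the closed form", {
  same <- c(1, 2, 3)
  r <- student_t_test(same, rev(same))
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)

  a <- c(0.1, 0.12, 0.11, 0.09)
  b <- c(0.9, 0.88, 0.91, 0.93)
  got <- student_t_test(a, b)
  # independent oracle: stats::t.test with pooled variance
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(got$t_statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(got$degrees_of_freedom, unname(ref$parameter))
  # symmetry in group order
  expect_equal(student_t_test(b, a)$p_value, got$p_value)

  expect_error(student_t_test(c(1, 1), c(1, 1)), "degenerate")

  welch <- student_t_test(a, c(b, 2, 3), welch = TRUE)
  refw <- t.test(a, c(b, 2, 3))
  expect_equal(welch$p_value, refw$p.value, tolerance = 1e-10)
})

test_that("estimate_ld50 interpolates the half-kill crossing", {
  expect_equal(estimate_ld50(c(10, 30), c(0.6, 0.4)), 20)
  expect_error(estimate_ld50(c(5, 10, 20), c(0.9, 0.8, 0.7)), "cross")
  # multiple crossings: lowest is reported
  d <- c(0, 10, 20, 30, 40)
  v <- c(1.0, 0.4, 0.6, 0.45, 0.2)
  expect_equal(estimate_ld50(d, v), 10 * (1 - 0.5) / (1 - 0.4) + 0)
})

test_that("summarize_irradiance_series edge behaviors", {
  w <- data.frame(irradiance = rep(c(25, 100, 300), each = 3),
                  normalized_viability = rep(c(0.4, 0.6, 0.9), each = 3))
  s <- summarize_irradiance_series(w)
  expect_equal(s$argmin_irradiance, 25)
  expect_equal(s$plateau_onset, 300)

  flat <- data.frame(irradiance = rep(c(25, 100, 300), each = 2),
                     normalized_viability = 0.7)
  s2 <- summarize_irradiance_series(flat)
  expect_equal(s2$plateau_onset, 25)
  expect_equal(s2$argmin_irradiance, 25)
})

test_that("dose monotonicity on a noise-free synthetic series", {
  cfg <- small_cfg
  doses <- c(0, 5, 10, 15, 20, 30)
  v <- vapply(doses, function(D) {
    ren <- render_well("treated", dose = D, irradiance = 25, cfg = cfg,
                       seed = 31, noise = noise_free())
    sum(ren$truth$viability * ren$truth$n_pixels) / sum(ren$truth$n_pixels)
  }, 0)
  expect_true(all(diff(v) <= 0.005))
})

test_that("dark toxicity is oxygen-independent in the generator", {
  # EO wells under normoxia and hypoxia come from the same distribution;
  # the paired t-test should be non-significant in >= 90% of replicates
  nrep <- 30
  ps <- vapply(seq_len(nrep), function(k) {
    v_norm <- vapply(1:4, function(w) {
      ren <- render_well("EO", atmosphere = "normoxic", cfg = small_cfg,
                         seed = 1000 + 10 * k + w)
      well_viability(ren$image$channels$live,
                     ren$image$channels$dead)$viability
    }, 0)
    v_hyp <- vapply(1:4, function(w) {
      ren <- render_well("EO", atmosphere = "hypoxic", cfg = small_cfg,
                         seed = 5000 + 10 * k + w)
      well_viability(ren$image$channels$live,
                     ren$image$channels$dead)$viability
    }, 0)
    student_t_test(v_norm, v_hyp)$p_value
  }, 0)
  expect_gte(mean(ps > 0.05), 0.9)
})
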