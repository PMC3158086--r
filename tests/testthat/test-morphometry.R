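test_that("otsu_threshold separates a perfectly bimodal input", {
  x <- c(rep(0, 100), rep(10, 100))
  thr <- otsu_threshold(x)
  expect_gt(thr, 0)
  expect_lt(thr, 10)
  lab <- x > thr
  # zero within-class variance on either side
  expect_equal(var(x[lab]), 0)
  expect_equal(var(x[!lab]), 0)
  expect_error(otsu_threshold(matrix(5, 4, 4)), "constant")
})

test_that("otsu_threshold equals the brute-force oracle on random histograms", {
  set.seed(42)
  for (rep in 1:60) {
    nb <- sample(c(16, 64, 256), 1)
    mids <- seq(0, 1, length.out = nb)
    counts <- rpois(nb, lambda = sample(c(2, 20), nb, replace = TRUE))
    if (sum(counts > 0) < 2) next
    got <- otsu_threshold(list(mids = mids, counts = counts))
    want <- otsu_oracle(mids, counts)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("segment_nodules recovers synthetic fields", {
  # blank image: nothing survives the size filter
  set.seed(3)
  bg <- matrix(rnorm(250 * 250, 100, 4), 250, 250)
  blank <- segment_nodules(bg, bg, 2, 30)
  expect_equal(max(blank), 0)

  # 20 nodules >= 50 um, default noise: 20 labels, centroids on target
  specs <- sample_nodule_field(20, c(60, 250), c(2500, 2500), seed = 8)
  field <- culture_field(specs, "NT", field_size = c(2500, 2500))
  ren <- render_livedead(field, dose_response_model(default_cfg),
                         noise_model(), 2, seed = 8)
  labs <- segment_nodules(ren$image$channels$live,
                          ren$image$channels$dead, 2, 30)
  expect_equal(max(labs), 20)
  met <- nodule_metrics(labs, ren$image$channels$live,
                        ren$image$channels$dead, 2)
  for (i in seq_len(nrow(met))) {
    dd <- sqrt((met$centroid_x[[i]] - ren$truth$x)^2 +
                 (met$centroid_y[[i]] - ren$truth$y)^2)
    expect_lt(min(dd), 2.5)  # within ~one pixel of a generator centre
  }

  # two tangent-but-separated blobs stay distinct under 8-connectivity
  live <- matrix(0, 60, 60)
  live[10:20, 10:20] <- 3000
  live[10:20, 24:34] <- 3000
  live <- live + matrix(rnorm(3600, 100, 2), 60, 60)
  dead <- matrix(rnorm(3600, 100, 2), 60, 60)
  labs2 <- segment_nodules(live, dead, 2, 10)
  expect_equal(max(labs2), 2)
})

test_that("segmentation count matches the generator across seeds", {
  for (s in 1:20) {
    specs <- sample_nodule_field(5, c(60, 200), c(800, 800), seed = s)
    field <- culture_field(specs, "NT", field_size = c(800, 800))
    ren <- render_livedead(field, dose_response_model(default_cfg),
                           noise_model(), 2, seed = s + 100)
    labs <- segment_nodules(ren$image$channels$live,
                            ren$image$channels$dead, 2, 30)
    expect_equal(max(labs), 5)
  }
})

test_that("nodule_metrics geometry formulas and viability recovery", {
  # hand-built circular mask of known area
  labels <- matrix(0L, 80, 80)
  live <- matrix(0, 80, 80)
  dead <- matrix(0, 80, 80)
  # 25 px at 2 um/px -> area 100 um^2
  labels[cbind(c(40, 40, 40, 40, 40, 39, 39, 39, 39, 39, 41, 41, 41, 41,
                 41, 38, 38, 38, 38, 38, 42, 42, 42, 42, 42),
               rep(38:42, 5))] <- 1L
  live[labels == 1L] <- 1000
  live[1, 1] <- 1  # avoid constant-channel degeneracies in the mode
  dead[2, 2] <- 1
  met <- nodule_metrics(labels, live, dead, 2)
  expect_equal(met$area, 100)
  expect_equal(met$equivalent_diameter, 2 * sqrt(100 / pi),
               tolerance = 1e-12)
  # volume formula at 200 um equivalent diameter
  expect_equal((pi / 6) * 200^3, 4188790.2, tolerance = 1e-6)
  expect_equal(met$volume, (pi / 6) * met$equivalent_diameter^3)
  expect_true(met$ratio_flagged)

  # ground-truth viability recovery on a noise-free render
  specs <- sample_nodule_field(6, c(100, 250), c(1200, 1200), seed = 14)
  field <- culture_field(specs, "treated", 25, 25,
                         field_size = c(1200, 1200))
  ren <- render_livedead(field, dose_response_model(default_cfg),
                         noise_free(), 2, seed = 14)
  met2 <- nodule_metrics(ren$labels, ren$image$channels$live,
                         ren$image$channels$dead, 2)
  truth <- ren$truth[match(met2$label, ren$truth$id), ]
  expect_equal(met2$viability, truth$viability, tolerance = 0.02)
})

test_that("border-touching nodules are excluded and flagged", {
  labels <- matrix(0L, 40, 40)
  labels[1:6, 10:15] <- 1L    # touches the top border
  labels[20:26, 20:26] <- 2L  # interior
  live <- matrix(0, 40, 40); live[labels > 0L] <- 500; live[40, 40] <- 1
  dead <- matrix(0, 40, 40); dead[labels > 0L] <- 500; dead[40, 1] <- 1
  met <- nodule_metrics(labels, live, dead, 2)
  expect_equal(met$label, 2L)
  expect_equal(attr(met, "border_labels"), 1L)
})

test_that("per-nodule sums never exceed the whole-image total", {
  ren <- render_well("treated", dose = 15, irradiance = 25,
                     cfg = small_cfg, seed = 17)
  live <- ren$image$channels$live
  dead <- ren$image$channels$dead
  labs <- segment_nodules(live, dead, 2, 30)
  met <- nodule_metrics(labs, live, dead, 2)
  expect_lte(sum(met$live_sum), sum(subtract_background(live)))
  expect_lte(sum(met$dead_sum), sum(subtract_background(dead)))
})

test_that("fit_powerlaw recovers exact and noisy power laws", {
  v <- exp(seq(log(1e4), log(1e8), length.out = 20))
  r <- 2 * v^0.5
  fit <- fit_powerlaw(v, r)
  expect_equal(fit$prefactor, 2, tolerance = 1e-10)
  expect_equal(fit$exponent, 0.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  flat <- fit_powerlaw(v, rep(3, 20))
  expect_equal(flat$exponent, 0, tolerance = 1e-12)

  set.seed(7)
  v2 <- exp(runif(1000, log(1e4), log(1e8)))
  r2 <- 1.5 * v2^0.7 * exp(rnorm(1000, 0, 0.1))
  fit2 <- fit_powerlaw(v2, r2)
  expect_equal(fit2$exponent, 0.7, tolerance = 0.05)

  expect_error(fit_powerlaw(c(1, 2, -3), c(1, 1, 1)), "positive")
})

test_that("power-law exponents discriminate core- from periphery-kill", {
  # matched fields treated at 10 J/cm^2 with the core-concentrating agent
  # (EtNBS-like) versus the periphery-localizing agent (BPD-like); the
  # periphery-kill exponent must be strictly larger
  collect <- function(agent) {
    out <- list()
    for (s in 1:3) {
      specs <- sample_nodule_field(8, c(80, 500), c(2500, 2500),
                                   seed = 50 + s)
      field <- culture_field(specs, "treated", 10, 25, agent = agent,
                             field_size = c(2500, 2500))
      ren <- render_livedead(field, dose_response_model(default_cfg),
                             noise_model(), 2, seed = 60 + s)
      labs <- segment_nodules(ren$image$channels$live,
                              ren$image$channels$dead, 2, 30)
      met <- nodule_metrics(labs, ren$image$channels$live,
                            ren$image$channels$dead, 2)
      out[[s]] <- met
    }
    do.call(rbind, out)
  }
  etnbs <- collect("EtNBS")
  bpd <- collect("BPD")
  fe <- fit_powerlaw(etnbs$volume, etnbs$live_dead_ratio)
  fb <- fit_powerlaw(bpd$volume, bpd$live_dead_ratio)
  expect_gt(fb$exponent, fe$exponent)
})

test_that("penetration_depth implements the 1/e shell rule", {
  sp <- nodule_spec(1, c(0, 0), 600)
  # uniform uptake: full penetration, depth = inradius
  uni <- render_uptake(sp, "core_concentrating", list(tau = 1, s = 0),
                       t = Inf, noise = noise_free(), pixel_size = 2)
  pd_u <- penetration_depth(uni$image$channels$uptake, uni$mask, 2)
  expect_true(pd_u$full_penetration)
  expect_equal(pd_u$depth_um, 300, tolerance = 5)

  for (L in c(125, 40)) {
    up <- render_uptake(sp, "peripheral_decay", list(decay_length = L),
                        noise = noise_free(), pixel_size = 2)
    pd <- penetration_depth(up$image$channels$uptake, up$mask, 2)
    expect_false(pd$full_penetration)
    expect_equal(pd$depth_um, L, tolerance = 3)
  }
})
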