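# Shared fixtures: everything is generated in code at test time.

default_cfg <- nodulePDT::load_config()

# a small, fast configuration for pipeline smoke tests
small_cfg <- local({
  cfg <- default_cfg
  cfg$field_size_um <- c(600, 600)
  cfg$nodules_per_well <- 4
  cfg$diameter_range_um <- c(60, 200)
  cfg
})

# brute-force Otsu oracle: minimize the weighted within-class variance
# over every histogram cut
otsu_oracle <- function(mids, counts) {
  w <- counts / sum(counts)
  best <- Inf
  best_k <- NA_integer_
  for (k in seq_len(length(mids) - 1L)) {
    w0 <- sum(w[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(w[1:k] * mids[1:k]) / w0
    m1 <- sum(w[(k + 1):length(mids)] * mids[(k + 1):length(mids)]) / w1
    v0 <- sum(w[1:k] * (mids[1:k] - m0)^2) / w0
    v1 <- sum(w[(k + 1):length(mids)] * (mids[(k + 1):length(mids)] - m1)^2) / w1
    within <- w0 * v0 + w1 * v1
    if (within < best - 1e-12) {
      best <- within
      best_k <- k
    }
  }
  (mids[[best_k]] + mids[[best_k + 1L]]) / 2
}

# finite-difference oracle for diffusion into a sphere: solves u = r*C on
# u_t = D u_rr with u(0) = 0, u(R) = R, u(r, 0) = 0, explicit Euler
fd_sphere_oracle <- function(r_eval, times, nr = 81) {
  R <- 1; D <- 1  # tau = R^2/D = 1
  dr <- R / (nr - 1)
  dt <- 0.4 * dr^2 / D
  r <- seq(0, R, length.out = nr)
  u <- numeric(nr)
  u[nr] <- R
  t_now <- 0
  out <- numeric(length(times))
  times_ord <- order(times)
  for (k in times_ord) {
    t_target <- times[[k]]
    while (t_now < t_target) {
      step <- min(dt, t_target - t_now)
      lap <- c(0, diff(u, differences = 2), 0) / dr^2
      u[2:(nr - 1)] <- u[2:(nr - 1)] + step * D * lap[2:(nr - 1)]
      t_now <- t_now + step
    }
    ci <- u / r
    ci[1] <- u[2] / r[2]  # r -> 0 limit
    out[[k]] <- approx(r, ci, xout = r_eval)$y
  }
  out
}

# render one well and score it (shared by several tests)
render_well <- function(condition = "NT", dose = 0, irradiance = 0,
                        atmosphere = "normoxic", agent = "EtNBS",
                        cfg = small_cfg, seed = 1, noise = NULL) {
  if (is.null(noise))
    noise <- noise_model(cfg$noise$photon_scale, cfg$noise$read_sigma,
                         cfg$noise$background_level)
  specs <- sample_nodule_field(cfg$nodules_per_well, cfg$diameter_range_um,
                               cfg$field_size_um, seed = seed,
                               core_fraction = cfg$core_fraction)
  field <- culture_field(specs, condition, dose, irradiance, atmosphere,
                         agent, cfg$field_size_um)
  render_livedead(field, dose_response_model(cfg), noise,
                  cfg$pixel_size_um, seed = seed + 1000L,
                  brightness = cfg$brightness$live)
}
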