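test_that("cycle dwell times are exponential with the state exit rate", {
  d <- simulate_cycle_dwells(c(loop = 2), n_cycles = 1e4, seed = 1)
  se <- 0.5 / sqrt(1e4)
  expect_lt(abs(mean(d$dwell_s) - 0.5), 3 * se)
})

test_that("mean cycle time converges to the analytic 1/kcat", {
  # serial rates chosen so sum(1/r) = 1/1.57 s (the fastest construct's cycle)
  r <- c(a = 5, b = 6, c = 8)
  r <- c(r, d = 1 / (1 / 1.57 - sum(1 / r)))
  expect_equal(sum(1 / r), 1 / 1.57, tolerance = 1e-12)
  d <- simulate_cycle_dwells(r, n_cycles = 1e4, seed = 2)
  percyc <- tapply(d$dwell_s, d$cycle, sum)
  se <- stats::sd(percyc) / sqrt(length(percyc))
  expect_lt(abs(mean(percyc) - 0.637), 3 * se + 1e-3)
  expect_equal(attr(d, "t_cycle_analytic"), 1 / 1.57, tolerance = 1e-12)
})

test_that("cycle simulation is deterministic under a seed and rejects absorbing states", {
  a <- simulate_cycle_dwells(c(x = 1, y = 3), 1, seed = 7)
  b <- simulate_cycle_dwells(c(x = 1, y = 3), 1, seed = 7)
  expect_identical(a, b)
  expect_error(simulate_cycle_dwells(c(x = 1, y = 0), 10, seed = 1), "absorbing")
})

test_that("rate scheme validates its invariants", {
  expect_error(rate_scheme(p_srx = 1.2), "p_srx")
  expect_error(rate_scheme(k_hyd = -1), ">= 0")
  expect_error(rate_scheme(K_ADP = 17, k_plusADP = 2, k_minusADP = 100),
               "inconsistent")
  sc <- rate_scheme(K_ADP = 50, k_plusADP = 2, k_minusADP = 100)
  expect_s3_class(sc, "rate_scheme")
})

test_that("ATPase plate wells follow the Michaelis-Menten slope law", {
  kcat <- 0.8; Km <- 35.9; basal <- 0.02
  pl <- make_atpase_plate(kcat, Km, basal, actin_concs = c(10, Km, 100),
                          noise_sd = 0, seed = 1)
  gt <- pl$ground_truth
  # half-saturation identity and basal-only well
  expect_equal(unname(gt$rate_s[2]), basal + kcat / 2, tolerance = 1e-12)
  expect_equal(unname(gt$rate_s[4]), basal, tolerance = 1e-12)
  # closed-form slope oracle: A340 slope = -rate * nmol_myosin / conv
  nmol_myo <- pl$myosin_conc * pl$well_volume_uL / 1000
  expect_equal(unname(gt$slope_AU_s),
               unname(-gt$rate_s * nmol_myo / gt$conv_nmol_per_AU),
               tolerance = 1e-12)
  expect_error(make_atpase_plate(0.8, 35.9, actin_concs = c(-5, 10)),
               "nonnegative")
})

test_that("dissociation transients store the hyperbolic k_obs", {
  K1 <- 1 / 79.8; k2 <- 520.7
  tr <- make_dissociation_transients(K1, k2, atp_list = c(1 / K1, 1e7),
                                     noise_sd = 0, seed = 1)
  expect_equal(trace_meta(tr[[1]])$k_obs_true, k2 / 2, tolerance = 1e-12)
  expect_equal(trace_meta(tr[[2]])$k_obs_true, k2, tolerance = 1e-3)
  expect_error(make_dissociation_transients(K1, k2, numeric(0)), "at least one")
})

test_that("ADP competition transients follow k0/(1 + [ADP]/K_ADP)", {
  tr <- make_adp_competition_transients(100, 120.7, adp_list = c(0, 120.7),
                                        noise_sd = 0, seed = 1)
  expect_equal(trace_meta(tr[[1]])$k_obs_true, 100)
  expect_equal(trace_meta(tr[[2]])$k_obs_true, 50)
  expect_error(make_adp_competition_transients(100, -1, c(0, 10)), "K_ADP")
})

test_that("turnover decay reduces to a single exponential and integrates analytically", {
  tr <- make_turnover_decay(1, 0.003, 0.03, noise_sd = 0, seed = 1)
  post <- tr$time >= 60
  expect_equal(tr$signal[post], exp(-0.003 * (tr$time[post] - 60)),
               tolerance = 1e-12)
  p <- 0.464; ks <- 0.003; kf <- 0.03
  tr2 <- make_turnover_decay(p, ks, kf, duration_s = 8000, noise_sd = 0, seed = 1)
  post <- tr2$time >= 60
  tp <- tr2$time[post] - 60; yp <- tr2$signal[post]
  integral <- sum((yp[-1] + yp[-length(yp)]) / 2 * diff(tp))
  analytic <- p / ks + (1 - p) / kf
  expect_equal(integral, analytic, tolerance = 1e-2)
  expect_error(make_turnover_decay(0.5, 0.03, 0.003), "k_slow")
})

test_that("trap traces have the configured bound variance and null case", {
  cfg <- trap_sim_config(event_rate = 0)
  rec <- make_trap_trace(cfg, 2, seed = 1)
  expect_equal(nrow(rec$events), 0)
  expect_equal(length(rec$position), 2 * cfg$sample_rate)
  # long bound segment: empirical variance close to bound_variance
  cfg2 <- trap_sim_config(event_rate = 50, detach_rate = 0.08)
  rec2 <- make_trap_trace(cfg2, 12, seed = 3)
  ev <- rec2$events[1, ]
  fs <- rec2$sample_rate
  i0 <- floor((ev$start_s + ev$substep_delay_s) * fs) + 10
  i1 <- floor(ev$end_s * fs) - 10
  expect_gt((i1 - i0) / fs, 8)   # at least ~10 s bound
  v <- stats::var(rec2$position[i0:i1])
  expect_lt(abs(v - cfg2$bound_variance) / cfg2$bound_variance, 0.05)
  expect_error(trap_sim_config(bound_variance = 200, free_variance = 100),
               "bound_variance")
  expect_error(trap_sim_config(sample_rate = 10000, filter_cutoff = 10000),
               "Nyquist")
})

test_that("trap event durations are exponential at the detachment rate", {
  cfg <- trap_sim_config(detach_rate = 3.7, event_rate = 3)
  durs <- c()
  s <- 0
  while (length(durs) < 500) {
    s <- s + 1
    rec <- make_trap_trace(cfg, 60, seed = 100 + s)
    durs <- c(durs, rec$events$duration_s[rec$events$end_s < 60])
  }
  durs <- durs[1:500]
  se <- stats::sd(durs) / sqrt(500)
  expect_lt(abs(mean(durs) - 1 / 3.7), 3 * se)
})

test_that("motility movie ground truth obeys the configured kinematics", {
  cfg <- movie_sim_config(speed_um_s = 0, filament_count = 3,
                          image_size = c(128, 128), frame_count = 5)
  mov <- make_motility_movie(cfg, seed = 1)
  sp <- split(mov$truth, mov$truth$filament)
  for (tr in sp) {
    expect_equal(stats::sd(tr$x_px), 0)
    expect_equal(stats::sd(tr$y_px), 0)
  }
  cfg2 <- movie_sim_config(speed_um_s = 0.5, pixel_size = 0.1,
                           frame_interval = 1, filament_count = 3,
                           image_size = c(256, 256), frame_count = 5)
  mov2 <- make_motility_movie(cfg2, seed = 2)
  tr <- mov2$truth[mov2$truth$filament == 1, ]
  step <- sqrt(diff(tr$x_px)^2 + diff(tr$y_px)^2)
  expect_equal(step, rep(5, 4), tolerance = 1e-9)
  expect_error(movie_sim_config(frame_count = 1), "frame_count")
})

test_that("state trajectories reproduce the sampling matrix", {
  T_id <- diag(2)
  s <- make_state_trajectory(T_id, 100, seed = 1)
  expect_equal(length(unique(as.integer(s))), 1)
  T2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  s2 <- make_state_trajectory(T2, 1e5, seed = 2)
  # closed-form stationary distribution (p21, p12)/(p12 + p21) = (2/3, 1/3)
  frac1 <- mean(s2 == 1)
  se <- sqrt(2 / 3 * 1 / 3 / 1e5) * 3  # inflated for autocorrelation
  expect_lt(abs(frac1 - 2 / 3), 3 * se * 3)
  expect_identical(as.integer(make_state_trajectory(T2, 100, seed = 9)),
                   as.integer(make_state_trajectory(T2, 100, seed = 9)))
  expect_error(make_state_trajectory(matrix(c(0.5, 0.4, 0.2, 0.8), 2), 10, 1),
               "sum to 1")
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- make_atpase_plate(0.8, 35.9, seed = 5)
  b <- make_atpase_plate(0.8, 35.9, seed = 5)
  expect_identical(a$absorbance, b$absorbance)
  t1 <- make_turnover_decay(0.5, 0.003, 0.03, seed = 5)
  t2 <- make_turnover_decay(0.5, 0.003, 0.03, seed = 5)
  expect_identical(t1$signal, t2$signal)
  r1 <- make_trap_trace(trap_sim_config(), 1, seed = 5)
  r2 <- make_trap_trace(trap_sim_config(), 1, seed = 5)
  expect_identical(r1$position, r2$position)
})
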