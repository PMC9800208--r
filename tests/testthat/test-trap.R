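test_that("power-spectrum calibration recovers corner frequency and stiffness", {
  cfg <- trap_sim_config(event_rate = 0, corner_freq = 2000, stiffness = 0.04)
  rec <- make_trap_trace(cfg, 10, seed = 1)
  st <- calibrate_stiffness(rec)
  expect_false(st$unidentifiable)
  expect_lt(abs(st$corner_freq - 2000) / 2000, 0.05)
  # variance from the fitted spectrum matches equipartition at the true kappa
  expect_lt(abs(st$variance_nm2 - cfg$free_variance) / cfg$free_variance, 0.1)

  # doubling the stiffness halves the variance and doubles the fitted kappa
  cfg2 <- trap_sim_config(event_rate = 0, corner_freq = 2000, stiffness = 0.08)
  st2 <- calibrate_stiffness(make_trap_trace(cfg2, 10, seed = 2))
  expect_lt(abs(st2$stiffness / st$stiffness - 2), 0.25)

  # white noise has no corner in band
  set.seed(3)
  wn <- stats::rnorm(1e5)
  stw <- calibrate_stiffness(wn, sample_rate = 2e4)
  expect_true(stw$unidentifiable)
  expect_error(calibrate_stiffness(rnorm(100), sample_rate = 2e4), "5 s")
})

test_that("event detection has high recall/precision and a quiet null", {
  # pure noise: fewer than 1 false event per 100 s
  rec0 <- make_trap_trace(trap_sim_config(event_rate = 0), 100, seed = 4)
  expect_lt(nrow(detect_events(rec0)), 1)

  cfg <- trap_sim_config(detach_rate = 9.9, event_rate = 2)
  rec <- make_trap_trace(cfg, 120, seed = 5)
  ev <- detect_events(rec)
  deadtime <- attr(ev, "deadtime_s")
  m <- match_events(ev, rec$events)
  long_truth <- which(rec$events$duration_s >= 2 * deadtime)
  recall <- sum(stats::na.omit(m) %in% long_truth) / length(long_truth)
  precision <- mean(!is.na(m))
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
  # bound variance drops as designed
  expect_lt(stats::median(ev$variance_ratio), 0.5)
})

test_that("detected mean duration matches the slow python-like detachment", {
  cfg <- trap_sim_config(detach_rate = 3.7, event_rate = 1)
  rec <- make_trap_trace(cfg, 200, seed = 6)
  fit <- fit_detachment_from_events(detect_events(rec), n_boot = 500)
  expect_gt(fit$ci[2], 3.7)
  expect_lt(fit$ci[1], 3.7)
})

test_that("deadtime-truncated MLE equals its closed form and the likelihood optimum", {
  set.seed(7)
  d <- 0.005 + stats::rexp(500, 9.9)
  fit <- fit_detachment_rate(d, deadtime = 0.005)
  # closed form
  expect_identical(fit$rate, 1 / (mean(d) - 0.005))
  # independent oracle: direct numeric maximization of the log-likelihood
  nll <- function(k) -sum(log(k) - k * (d - 0.005))
  opt <- stats::optimize(nll, c(1e-3, 1e3), tol = 1e-10)
  expect_equal(fit$rate, opt$minimum, tolerance = 1e-6)
  # zero dead time reduces to 1/mean
  fit0 <- fit_detachment_rate(d, deadtime = 0)
  expect_identical(fit0$rate, 1 / mean(d))
  # bootstrap CI brackets the estimate and the truth here
  expect_true(fit$ci[1] < fit$rate && fit$rate < fit$ci[2])
  expect_true(fit$ci[1] < 9.9 && 9.9 < fit$ci[2])
  expect_error(fit_detachment_rate(c(0.001, d), deadtime = 0.005), "dead time")
  expect_error(fit_detachment_rate(d[1:5]), "at least 10")
})

test_that("reported rate is robust to halving the sampling rate", {
  cfg <- trap_sim_config(detach_rate = 9.9, event_rate = 2)
  rec <- make_trap_trace(cfg, 120, seed = 8)
  r1 <- fit_detachment_from_events(detect_events(rec), n_boot = 100)$rate
  # anti-alias by pair averaging, then analyze at 10 kHz
  x2 <- colMeans(matrix(rec$position, nrow = 2))
  ev2 <- detect_events(x2, sample_rate = rec$sample_rate / 2)
  r2 <- fit_detachment_from_events(ev2, n_boot = 100)$rate
  expect_lt(abs(r2 - r1) / r1, 0.02)
})

test_that("step summary recovers the programmed working stroke", {
  # fast second substep: every event completes the full 5.3 nm stroke
  cfg <- trap_sim_config(detach_rate = 9.9, event_rate = 2, d1 = 3.3, d2 = 2,
                         substep_delay_rate = 500)
  rec <- make_trap_trace(cfg, 150, seed = 9)
  ss <- summarize_steps(detect_events(rec))
  expect_gt(ss$n, 200)
  expect_lt(abs(ss$mean_nm - 5.3), 0.4)
  # zero-step motor: mean indistinguishable from zero
  cfg0 <- trap_sim_config(detach_rate = 9.9, event_rate = 2, d1 = 1e-9,
                          d2 = 1e-9)
  ss0 <- summarize_steps(detect_events(make_trap_trace(cfg0, 60, seed = 10)),
                         orient = FALSE)
  expect_lt(abs(ss0$mean_nm), 3 * ss0$sem_nm)
  expect_warning(summarize_steps(data.frame(step_nm = c(1, 2))), "fewer than 10")
})

test_that("ensemble averaging resolves the two-substep working stroke", {
  cfg <- trap_sim_config(detach_rate = 3.7, event_rate = 1, d1 = 4, d2 = 2,
                         substep_delay_rate = 200)
  rec <- make_trap_trace(cfg, 150, seed = 8)
  ea <- ensemble_average(rec, detect_events(rec))
  expect_lt(abs(ea$d2 - 2), max(3 * ea$d2_se, 0.2))
  expect_true(ea$two_substep)
  expect_equal(ea$d1 + ea$d2, ea$d_total, tolerance = 0.2)
  # near-noiseless ground-truth alignment: d_total approaches d1 + d2
  cfgq <- trap_sim_config(detach_rate = 3.7, event_rate = 1, d1 = 4, d2 = 2,
                          substep_delay_rate = 200,
                          free_variance = 1e-4, bound_variance = 1e-5)
  recq <- make_trap_trace(cfgq, 150, seed = 9)
  eaq <- ensemble_average(recq, recq$events, sample_rate = recq$sample_rate)
  expect_lt(abs(eaq$d_total - 6), 0.35)
  expect_lt(abs(eaq$d2 - 2), 0.35)
})

test_that("a single-step motor shows no substep structure", {
  cfg <- trap_sim_config(detach_rate = 3.7, event_rate = 1, d1 = 5, d2 = 1e-9)
  rec <- make_trap_trace(cfg, 120, seed = 10)
  ea <- ensemble_average(rec, detect_events(rec))
  expect_false(ea$two_substep)
  expect_lt(abs(ea$d2), 0.3)
  expect_error(ensemble_average(rec, rec$events[1:3, ],
                                sample_rate = rec$sample_rate), "at least 50")
})
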