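test_that("NADH standard curve fits an exact line and noisy dilution series", {
  conc <- c(0.1, 0.2, 0.4, 0.8)
  vol <- 30
  abs_exact <- conc * vol / 250          # conversion factor 250 nmol/AU
  st <- fit_nadh_standard(conc, abs_exact, well_volume_uL = vol)
  expect_equal(st$conversion_factor, 250, tolerance = 1e-9)
  expect_equal(st$r_squared, 1, tolerance = 1e-9)

  # protocol series: 2-fold dilutions from 1 mM down to 0.008 mM, 1% noise
  conc2 <- 1 / 2^(0:7)
  expect_equal(min(conc2), 0.0078125, tolerance = 1e-3)
  set.seed(42)
  abs2 <- conc2 * vol / 9.65 * (1 + stats::rnorm(8, 0, 0.01))
  expect_silent(st2 <- fit_nadh_standard(conc2, abs2, well_volume_uL = vol))
  expect_lt(abs(st2$conversion_factor - 9.65) / 9.65, 0.03)

  expect_error(fit_nadh_standard(c(0.1, 0.2), c(1, 2)), "at least 3")
  expect_error(fit_nadh_standard(conc, rep(1, 4)), "rank-deficient")
})

test_that("rate extraction recovers exact slopes and tracks the initial segment", {
  pl <- make_atpase_plate(0.8, 35.9, actin_concs = 35.9, noise_sd = 0, seed = 1)
  wm <- pl$well_map
  st <- fit_nadh_standard(wm$nadh_mM[wm$role == "standard"],
                          colMeans(pl$absorbance[, wm$role == "standard"]),
                          pl$well_volume_uL)
  r <- extract_rate(pl$time, pl$absorbance[, 1], st, pl$myosin_conc,
                    pl$well_volume_uL)
  truth <- unname(pl$ground_truth$rate_s[1])
  expect_false(r$rejected)
  expect_lt(abs(r$rate_s - truth) / truth, 1e-3)

  # substrate depletion: late-time curvature must not bias the initial slope
  pl2 <- make_atpase_plate(1.57, 93.4, actin_concs = 100, noise_sd = 0, seed = 1)
  r2 <- extract_rate(pl2$time, pl2$absorbance[, 1], st, pl2$myosin_conc,
                     pl2$well_volume_uL)
  truth2 <- unname(pl2$ground_truth$rate_s[1])
  # NADH runs out well before the end of the hour here
  consumed <- truth2 * pl2$myosin_conc * pl2$well_volume_uL / 1000 * 3600
  expect_gt(consumed, 1 * pl2$well_volume_uL)
  expect_lt(abs(r2$rate_s - truth2) / truth2, 1e-3)

  expect_error(extract_rate(1:5, 1:5, st, 0.4), "at least 10")
})

test_that("basal subtraction is exact arithmetic applied once", {
  pts <- data.frame(actin_uM = c(10, 50), rate_s = c(0.5, 0.9))
  out <- subtract_basal(pts, 0.1)
  expect_equal(out$rate_s, c(0.4, 0.8))
  expect_true(all(out$basal_subtracted))
  expect_error(subtract_basal(out, 0.1), "already subtracted")
  expect_equal(subtract_basal(pts, 0)$rate_s, pts$rate_s)
})

test_that("Michaelis-Menten fit recovers noiseless parameters and the grid optimum", {
  a <- c(10, 20, 40, 80, 160)
  v <- 0.60 * a / (79.3 + a)
  fit <- fit_michaelis_menten(data.frame(actin_uM = a, rate_s = v))
  expect_lt(abs(fit$kcat - 0.60) / 0.60, 1e-3)
  expect_lt(abs(fit$Km - 79.3) / 79.3, 1e-3)
  expect_false(fit$rejected)
  # definitional identity: fitted rate at [actin] = Km equals kcat/2
  expect_equal(fit$kcat * fit$Km / (fit$Km + fit$Km), fit$kcat / 2)
  expect_equal(fit$t_cycle, 1 / fit$kcat)

  # brute-force grid oracle on a noisy 5-point toy set
  set.seed(3)
  v2 <- 0.8 * a / (40 + a) + stats::rnorm(5, 0, 0.02)
  fit2 <- fit_michaelis_menten(data.frame(actin_uM = a, rate_s = v2))
  grid <- expand.grid(kcat = seq(0.5, 1.2, by = 0.005),
                      Km = seq(10, 120, by = 0.5))
  sse <- mapply(function(kc, km) sum((v2 - kc * a / (km + a))^2),
                grid$kcat, grid$Km)
  gbest <- grid[which.min(sse), ]
  expect_lt(abs(fit2$kcat - gbest$kcat), 0.01)
  expect_lt(abs(fit2$Km - gbest$Km), 1)

  expect_error(fit_michaelis_menten(data.frame(actin_uM = c(1, 2, 3),
                                               rate_s = c(1, 2, 3))),
               "at least 4")
})

test_that("ambiguous fits are flagged, not silently reported", {
  # all points far below Km: kcat/Km identifiable, kcat alone is not
  a <- c(1, 2, 3, 4, 5)
  set.seed(1)
  v <- 0.01 * a + stats::rnorm(5, 0, 0.003)
  fit <- fit_michaelis_menten(data.frame(actin_uM = a, rate_s = v))
  expect_true(fit$rejected)
})

test_that("plate analysis recovers parameters across seeded noisy plates", {
  errs <- cov <- numeric(20)
  for (s in seq_len(20)) {
    pl <- make_atpase_plate(0.8, 35.9, noise_sd = 0.002, seed = s)
    f <- analyze_atpase_plate(pl)$fit
    errs[s] <- abs(f$kcat - 0.8) / 0.8
    cov[s] <- f$kcat_ci[1] <= 0.8 && 0.8 <= f$kcat_ci[2]
  }
  expect_lt(stats::median(errs), 0.05)
  expect_gte(mean(cov), 0.9)
})

test_that("extracted rates are invariant to consistent unit rescaling", {
  pl1 <- make_atpase_plate(0.8, 35.9, myosin_conc = 0.4, well_volume_uL = 30,
                           noise_sd = 0, seed = 1)
  pl2 <- make_atpase_plate(0.8, 35.9, myosin_conc = 0.8, well_volume_uL = 60,
                           noise_sd = 0, seed = 1)
  f1 <- analyze_atpase_plate(pl1)$fit
  f2 <- analyze_atpase_plate(pl2)$fit
  expect_equal(f1$kcat, f2$kcat, tolerance = 1e-3)
  expect_equal(f1$Km, f2$Km, tolerance = 1e-3)
})

test_that("derived cycle metrics match the printed comparisons", {
  fits <- data.frame(construct = c("beta", "human", "python"),
                     kcat = c(1.57, 0.80, 0.60),
                     Km = c(93.4, 35.9, 79.3))
  cm <- derive_cycle_metrics(fits)
  expect_equal(round(cm$metrics$t_cycle[1], 1), 0.6)
  expect_equal(cm$metrics$t_cycle[1], 0.637, tolerance = 1e-3)
  pw <- cm$pairwise
  bh <- pw[pw$reference == "beta" & pw$other == "human", ]
  expect_equal(round(bh$pct_kcat_decrease), 49)
  expect_equal(round(bh$pct_Km_decrease), 62)
  # identical fits: zero difference, unit ratio
  cm2 <- derive_cycle_metrics(data.frame(construct = c("a", "b"),
                                         kcat = c(1, 1), Km = c(50, 50)))
  expect_equal(cm2$pairwise$pct_kcat_decrease, 0)
  expect_equal(cm2$pairwise$kcat_ratio, 1)
  expect_error(derive_cycle_metrics(data.frame(construct = "a", kcat = 0,
                                               Km = 10)), "positive")
})
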