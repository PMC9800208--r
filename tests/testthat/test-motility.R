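test_that("a straight filament is detected with sub-pixel midpoint accuracy", {
  f <- list(cx = 64.3, cy = 60.7, phi = 0.4, L = 30)
  img <- render_frame(list(f))
  det <- detect_filaments(img)
  expect_equal(nrow(det), 1)
  expect_lt(sqrt((det$x_mid - f$cx)^2 + (det$y_mid - f$cy)^2), 1)
  expect_gt(det$length_px, 20)
})

test_that("midpoint localization RMSE stays below 1 px on noiseless renders", {
  errs <- sapply(1:10, function(i) {
    set.seed(i)
    f <- list(cx = runif(1, 40, 90), cy = runif(1, 40, 90),
              phi = runif(1, 0, pi), L = runif(1, 15, 35))
    det <- detect_filaments(render_frame(list(f)))
    if (nrow(det) != 1) return(NA)
    sqrt((det$x_mid - f$cx)^2 + (det$y_mid - f$cy)^2)
  })
  expect_true(all(!is.na(errs)))
  expect_lt(sqrt(mean(errs^2)), 1)
})

test_that("objects outside the width band are rejected", {
  blob <- render_frame(list(list(cx = 64, cy = 64, phi = 0, L = 30)),
                       sigma = 12 / 2.355)
  det <- detect_filaments(blob)
  expect_equal(nrow(det), 0)
  # empty frame is an empty detection, not an error
  flat <- matrix(100, 64, 64)
  expect_equal(nrow(detect_filaments(flat)), 0)
})

test_that("crossing filaments are pruned to a simple path", {
  # a cross-shaped mask: its raw skeleton necessarily contains a branch pixel
  mask <- matrix(FALSE, 41, 41)
  mask[19:23, 3:39] <- TRUE        # horizontal bar
  mask[8:34, 19:23] <- TRUE        # vertical bar (shorter)
  skel <- skeletonize_mask(mask)
  p <- prune_skeleton(skel)
  # a simple path: no repeated pixels, consecutive vertices 8-adjacent
  expect_false(any(duplicated(paste(p$x, p$y))))
  expect_true(all(pmax(abs(diff(p$x)), abs(diff(p$y))) == 1))
  # pruning kept the longest run (the horizontal bar), dropping side branches
  expect_gt(nrow(p), 30)
  expect_gt(diff(range(p$x)), diff(range(p$y)))
  # the detector also survives two crossing filaments in one image
  img <- render_frame(list(list(cx = 54, cy = 64, phi = 0.15, L = 40),
                           list(cx = 74, cy = 64, phi = 1.75, L = 40)))
  det <- detect_filaments(img, width_slack = 3)
  paths <- attr(det, "paths")
  expect_gte(length(paths), 1)
  for (p in paths) {
    expect_false(any(duplicated(paste(p$x, p$y))))
    expect_true(all(pmax(abs(diff(p$x)), abs(diff(p$y))) == 1))
  }
})

test_that("the assignment solver matches exhaustive enumeration", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    cost <- matrix(stats::runif(n * n), n)
    sol <- solve_lap(cost)
    expect_equal(sol$cost, brute_force_lap(cost), tolerance = 1e-12)
  }
  # rectangular case
  cost <- matrix(stats::runif(12), 3, 4)
  expect_equal(solve_lap(cost)$cost, brute_force_lap(cost), tolerance = 1e-12)
})

test_that("linking keeps parallel movers apart and handles births/deaths", {
  # two well-separated filaments moving in parallel: two clean tracks
  det <- do.call(rbind, lapply(1:10, function(f)
    data.frame(frame = f, x = c(10 + 3 * f, 10 + 3 * f),
               y = c(20, 80))))
  trk <- link_tracks(det, gate_px = 10)
  expect_equal(length(unique(trk$track)), 2)
  for (tr in split(trk, trk$track))
    expect_equal(stats::sd(tr$y), 0)   # no identity swaps

  # stationary filament over 30 frames: a single full-length track
  det2 <- data.frame(frame = 1:30, x = 50, y = 50)
  trk2 <- link_tracks(det2, gate_px = 10)
  expect_equal(length(unique(trk2$track)), 1)
  expect_equal(nrow(trk2), 30)

  # a jump beyond the gate kills the track and births a new one
  det3 <- data.frame(frame = 1:10, x = c(rep(10, 5), rep(90, 5)), y = 10)
  trk3 <- link_tracks(det3, gate_px = 10)
  expect_equal(length(unique(trk3$track)), 2)
})

test_that("velocity computation is exact on ideal tracks", {
  trk <- data.frame(track = 1, frame = 1:10, x = 5 * (1:10), y = 7)
  vs <- compute_velocities(trk, pixel_size = 0.1, frame_interval = 1)
  expect_equal(vs$mean_um_s, 0.5)
  trk0 <- data.frame(track = 1, frame = 1:10, x = 3, y = 7)
  expect_equal(compute_velocities(trk0, 0.1, 1)$mean_um_s, 0)
  expect_error(compute_velocities(trk[1:3, ], 0.1, 1), "minimum length")
})

test_that("a full video round trip recovers the gliding speed within 3%", {
  r <- run_roundtrip("motility", seed = 3, speed_um_s = 0.597,
                     filament_count = 10, image_size = c(384, 384))
  truth <- 0.597
  expect_lt(abs(r$estimate$mean_um_s - truth) / truth, 0.03)
  expect_gte(r$estimate$n_tracks, 5)
})

test_that("recovered speed is invariant to scene rotation", {
  base <- list(list(cx = 40, cy = 64, phi = 0, L = 25),
               list(cx = 64, cy = 110, phi = 0, L = 25))
  speed_of <- function(rot) {
    det <- do.call(rbind, lapply(1:12, function(f) {
      fils <- lapply(base, function(b) {
        # advance along the (rotated) axis by 5 px/frame
        ang <- b$phi + rot
        cx <- b$cx + 5 * (f - 1) * cos(ang)
        cy <- b$cy + 5 * (f - 1) * sin(ang)
        list(cx = cx, cy = cy, phi = ang, L = b$L)
      })
      d <- detect_filaments(render_frame(fils, ny = 200, nx = 200,
                                         noisy = TRUE, seed = 100 + f))
      if (nrow(d) == 0) return(NULL)
      data.frame(frame = f, x = d$x_mid, y = d$y_mid)
    }))
    vs <- compute_velocities(link_tracks(det, gate_px = 10), 1, 1)
    vs$mean_um_s
  }
  v0 <- speed_of(0)
  v37 <- speed_of(37 * pi / 180)
  expect_lt(abs(v37 - v0) / v0, 0.02)
})
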